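# Small fully assembled pair-scoring model for gradient and scoring tests.
toy_model <- function(nd = 5, nm = 5, f = 6, npairs = 12,
                      variant = "dw_raw_gat_fc", lambda = 5e-4, seed = 31,
                      heads = 2, hidden = c(6, 4)) {
  set.seed(seed)
  X <- matrix(rnorm((nd + nm) * f), nd + nm, f)
  A <- matrix(rbinom(nm * nd, 1L, 0.4), nm, nd)
  A[1, 1] <- 1L
  nz <- which(A == 1L, arr.ind = TRUE)
  edges <- cbind(nz[, 2], nd + nz[, 1])
  SD <- hgmda:::sanitize_similarity(matrix(runif(nd * nd), nd, nd), FALSE)
  SM <- hgmda:::sanitize_similarity(matrix(runif(nm * nm), nm, nm), FALSE)
  pairs <- data.frame(di = sample(nd, npairs, TRUE),
                      mi = sample(nm, npairs, TRUE),
                      y = rbinom(npairs, 1, 0.5))
  ctl <- hgmda_control(feature_size = f, gat_heads = heads, fc_hidden = hidden,
                       lambda = lambda, epochs = 100, patience = 100,
                       variant = variant)
  model <- hgmda:::make_pair_model(X, edges, SD, SM, pairs, ctl, seed = seed)
  list(model = model, ctl = ctl, pairs = pairs)
}

# Finite-difference gradient of a model loss at theta (central differences).
fd_gradient <- function(model, theta, eps = 1e-5) {
  tv <- unlist(theta, use.names = FALSE)
  vapply(seq_along(tv), function(i) {
    tp <- tv; tp[i] <- tp[i] + eps
    lp <- model$loss_grads(hgmda:::unflatten(tp, theta),
                           want_grads = FALSE)$loss
    tm <- tv; tm[i] <- tm[i] - eps
    lm <- model$loss_grads(hgmda:::unflatten(tm, theta),
                           want_grads = FALSE)$loss
    (lp - lm) / (2 * eps)
  }, 0)
}

# Planted-recovery cross-validations shared by the end-to-end acceptance
# checks: one 40 x 40 two-block dataset and CV per seed, cached so the full
# pipeline and its ablation reuse the same runs.
planted_cv_cache <- new.env(parent = emptyenv())
planted_cv <- function(variant, seeds = 1:3) {
  key <- paste(variant, paste(seeds, collapse = "-"))
  if (is.null(planted_cv_cache[[key]])) {
    runs <- lapply(seeds, function(s) {
      sim <- simulate_mda(n_mirna = 40, n_disease = 40, n_blocks = 2,
                          p_within = 0.8, p_between = 0.05, seed = s)
      ablation_run(sim$assoc, sim$dags, sim$fs, variant = variant,
                   control = hgmda_control(), k = 5, seed = s)
    })
    planted_cv_cache[[key]] <- runs
  }
  planted_cv_cache[[key]]
}

cv_mean_metric <- function(runs, metric) {
  mean(vapply(runs, function(cv) cv$metrics["mean", metric], 0))
}
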