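test_that("negative sampling avoids known positives and honours the ratio", {
  sim <- small_sim(seed = 8, n = 15)
  neg <- sample_negative_pairs(sim$assoc, ratio = 1, seed = 5)
  expect_identical(nrow(neg), sum(sim$assoc == 1L))
  expect_true(all(sim$assoc[cbind(neg$mirna_index, neg$disease_index)] == 0L))
  expect_identical(neg, sample_negative_pairs(sim$assoc, ratio = 1, seed = 5))
  sparse <- simulate_mda(n_mirna = 15, n_disease = 15, p_within = 0.3,
                         p_between = 0.05, seed = 8)
  neg2 <- sample_negative_pairs(sparse$assoc, ratio = 2, seed = 5)
  expect_identical(nrow(neg2), 2L * sum(sparse$assoc == 1L))
})

test_that("negative sampling on a 2x2 matrix recovers exactly the zero cells", {
  A <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
              dimnames = list(c("m1", "m2"), c("d1", "d2")))
  neg <- sample_negative_pairs(A, ratio = 1, seed = 1)
  got <- sort(paste(neg$mirna, neg$disease))
  expect_identical(got, c("m1 d2", "m2 d1"))
  expect_error(sample_negative_pairs(A, ratio = 2, seed = 1), "not enough")
})

test_that("excluded pairs are never sampled as negatives", {
  sim <- small_sim(seed = 9, n = 12)
  excl <- data.frame(mirna = rownames(sim$assoc),
                     disease = colnames(sim$assoc)[1])
  excl <- excl[sim$assoc[, 1] == 0L, ]
  neg <- sample_negative_pairs(sim$assoc, ratio = 1, seed = 2, exclude = excl)
  expect_false(any(neg$disease == colnames(sim$assoc)[1]))
})

test_that("pair representation widths follow the accumulation mode", {
  tm_c <- toy_model(f = 6)
  expect_identical(ncol(tm_c$model$theta$fc$fc1$W), 4L * 6L)  # concat: 2*(2F)
  set.seed(31)
  X <- matrix(rnorm(10 * 6), 10, 6)
  SD <- hgmda:::sanitize_similarity(matrix(runif(25), 5, 5), FALSE)
  SM <- hgmda:::sanitize_similarity(matrix(runif(25), 5, 5), FALSE)
  pairs <- data.frame(di = c(1, 2), mi = c(1, 3), y = c(1, 0))
  ctl <- hgmda_control(feature_size = 6, gat_heads = 2, fc_hidden = c(6, 4),
                       accumulation = "sum")
  m_sum <- hgmda:::make_pair_model(X, cbind(1:3, 5 + 1:3), SD, SM, pairs,
                                   ctl, seed = 1)
  expect_identical(ncol(m_sum$theta$fc$fc1$W), 2L * 6L)       # sum: 2*F
})

test_that("scores are probabilities and zero predictor weights give 0.5", {
  tm <- toy_model()
  res <- tm$model$loss_grads(tm$model$theta, want_grads = FALSE)
  expect_true(all(res$scores > 0 & res$scores < 1))
  th0 <- tm$model$theta
  for (l in seq_along(th0$fc)) {
    th0$fc[[l]]$W[] <- 0; th0$fc[[l]]$b[] <- 0
  }
  res0 <- tm$model$loss_grads(th0, want_grads = FALSE)
  expect_equal(unname(res0$scores), rep(0.5, nrow(tm$pairs)))
})

test_that("cross-entropy loss matches closed forms", {
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), 2 * log(2))
  # near-perfect predictions drive the loss to zero
  expect_lt(bce_loss(c(1 - 1e-9, 1e-9), c(1, 0)), 1e-6)
  # additive L2 penalty: one parameter of value 1, lambda 0.5
  expect_equal(bce_loss(0.5, 1, theta_norm_sq = 1, lambda = 0.5),
               log(2) + 0.5, tolerance = 1e-12)
  expect_warning(l <- bce_loss(c(0, 1), c(0, 1)), "clamped")
  expect_true(is.finite(l))
})

test_that("analytic gradients match central finite differences", {
  for (variant in c("dw_raw_gat_fc", "dw_gat_dot")) {
    tm <- toy_model(variant = variant, npairs = 10)
    theta <- tm$model$theta
    ga <- unlist(tm$model$loss_grads(theta)$grads, use.names = FALSE)
    gn <- fd_gradient(tm$model, theta)
    rel <- abs(ga - gn) / pmax(abs(ga) + abs(gn), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("training reduces the loss on a planted toy dataset", {
  for (s in 1:5) {
    sim <- simulate_mda(n_mirna = 12, n_disease = 12, seed = s)
    ctl <- small_control(epochs = 200, patience = 200)
    fit <- hgmda(sim$assoc, sim$dags, sim$fs, control = ctl, seed = s)
    expect_lt(fit$loss_log[fit$epochs], fit$loss_log[1])
  }
})

test_that("training is reproducible given the seed", {
  sim <- small_sim(seed = 10, n = 12)
  ctl <- small_control(epochs = 15)
  f1 <- hgmda(sim$assoc, sim$dags, sim$fs, control = ctl, seed = 4)
  f2 <- hgmda(sim$assoc, sim$dags, sim$fs, control = ctl, seed = 4)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$loss_log, f2$loss_log)
})

test_that("stronger L2 penalties shrink the learned parameters", {
  sim <- small_sim(seed = 11, n = 12)
  norms <- vapply(c(0, 0.005, 0.05), function(lam) {
    ctl <- small_control(epochs = 120, lambda = lam)
    fit <- hgmda(sim$assoc, sim$dags, sim$fs, control = ctl, seed = 6)
    hgmda:::theta_sqnorm(fit$theta)
  }, 0)
  expect_true(all(diff(norms) <= 0))
})

test_that("scores are invariant to a consistent miRNA relabelling", {
  sim <- small_sim(seed = 12, n = 12)
  ctl <- small_control(epochs = 25)
  fit <- hgmda(sim$assoc, sim$dags, sim$fs, control = ctl, seed = 2)
  nm <- length(fit$mirnas)
  base <- hgmda:::score_pairs_idx(fit, rep(1, nm), seq_len(nm))
  perm <- sample(nm)
  fit_p <- fit
  nd <- length(fit$diseases)
  fit_p$H[nd + seq_len(nm), ] <- fit$H[nd + perm, ]
  fit_p$Pm <- fit$Pm[perm, , drop = FALSE]
  scores_p <- hgmda:::score_pairs_idx(fit_p, rep(1, nm), seq_len(nm))
  expect_equal(scores_p, base[perm], tolerance = 1e-12)
})

test_that("predict() scores named pairs and full matrices consistently", {
  sim <- small_sim(seed = 13, n = 10)
  ctl <- small_control(epochs = 20)
  fit <- hgmda(sim$assoc, sim$dags, sim$fs, control = ctl, seed = 2)
  M <- predict(fit)
  expect_identical(dim(M), dim(sim$assoc))
  nd <- data.frame(mirna = rownames(sim$assoc)[c(1, 3)],
                   disease = colnames(sim$assoc)[c(2, 2)])
  expect_equal(predict(fit, nd), M[cbind(c(1, 3), c(2, 2))])
  expect_error(predict(fit, data.frame(mirna = "nope", disease = "disease001")),
               "unknown miRNA")
  expect_equal(fitted(fit), fit$train_scores)
  expect_equal(residuals(fit), fit$pairs$y - fitted(fit))
})
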