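#' Control parameters for model fitting
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the reference study conditions: decay 0.5 for DAG semantic
#' contributions; unit GIP reference bandwidth; walk length 20 and window
#' 5 with 64-dimensional embeddings; a 2-layer, 16-head GAT; a three-layer
#' fully connected predictor; Adam with learning rate 0.001 and weight
#' decay 5e-5; explicit L2 penalty 5e-4; negative sampling ratio 1.
#'
#' @param delta semantic contribution decay per DAG generation, in (0, 1].
#' @param gamma_prime GIP reference bandwidth.
#' @param feature_size embedding dimension F.
#' @param window skip-gram window.
#' @param walk_length nodes per random walk.
#' @param walks_per_node walks started per node.
#' @param sg_epochs skip-gram passes over the walk corpus.
#' @param sg_alpha initial skip-gram learning rate.
#' @param gat_layers number of attention layers.
#' @param gat_heads attention heads per layer.
#' @param attn_slope LeakyReLU slope inside the attention scorer.
#' @param act_slope LeakyReLU slope of layer/predictor activations.
#' @param accumulation how node features and projected raw features are
#'   combined per side: `"concat"` (default) or `"sum"`.
#' @param fc_hidden hidden widths of the fully connected predictor.
#' @param learning_rate Adam learning rate.
#' @param weight_decay Adam weight decay (L2 term added to the gradient).
#' @param lambda explicit L2 penalty coefficient in the loss.
#' @param epochs maximum training epochs (full-batch).
#' @param patience early-stopping patience on the training-loss plateau.
#' @param negative_ratio negatives sampled per known positive.
#' @param variant architecture variant, see [hgmda_variants()].
#' @return a list of class `hgmda_control`.
#' @export
hgmda_control <- function(delta = 0.5, gamma_prime = 1, feature_size = 64,
                          window = 5, walk_length = 20, walks_per_node = 10,
                          sg_epochs = 5, sg_alpha = 0.025, gat_layers = 2,
                          gat_heads = 16, attn_slope = 0.02, act_slope = 0.2,
                          accumulation = c("concat", "sum"),
                          fc_hidden = c(128, 64), learning_rate = 0.001,
                          weight_decay = 5e-5, lambda = 5e-4, epochs = 500,
                          patience = 50, negative_ratio = 1,
                          variant = "dw_raw_gat_fc") {
  accumulation <- match.arg(accumulation)
  variant_flags(variant)  # validates
  stopifnot(delta > 0, delta <= 1, gamma_prime > 0, feature_size >= 1,
            window >= 1, walk_length >= 2, walks_per_node >= 1,
            sg_epochs >= 1, gat_layers >= 1, gat_heads >= 1,
            learning_rate > 0, weight_decay >= 0, lambda >= 0,
            epochs >= 1, patience >= 1, negative_ratio > 0)
  structure(as.list(environment()), class = "hgmda_control")
}

make_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Align a square named similarity matrix to a requested name order.
align_similarity <- function(S, names, what) {
  S <- sanitize_similarity(S, warn_clip = FALSE)
  if (is.null(rownames(S))) {
    if (nrow(S) != length(names))
      stop(what, " similarity dimension does not match entity count")
    dimnames(S) <- list(names, names)
    return(S)
  }
  ord <- match(names, rownames(S))
  if (anyNA(ord))
    stop(what, " similarity is missing entries for: ",
         paste(head(names[is.na(ord)], 3), collapse = ", "))
  S[ord, ord, drop = FALSE]
}

# Shared by hgmda() and hgmda_cv(): per-A similarity integration, node
# features and bipartite edge list (diseases first, then miRNAs).
build_feature_inputs <- function(A, SS, FS, control, flags, seeds) {
  KD <- gip_kernel(A, "disease", control$gamma_prime)
  KM <- gip_kernel(A, "mirna", control$gamma_prime)
  SD <- integrate_similarity(SS, KD)
  SM <- integrate_similarity(FS, KM)
  Nd <- ncol(A)
  if (flags$features == "embedding") {
    embed_side <- function(S, s) {
      corpus <- sample_walks(transition_matrix(S), control$walks_per_node,
                             control$walk_length, seed = s)
      embed_nodes(corpus, control$feature_size, control$window,
                  control$sg_epochs, control$sg_alpha, seed = s)
    }
    X <- rbind(embed_side(SD, seeds[1]), embed_side(SM, seeds[2]))
  } else {                               # raw similarity rows as features
    if (nrow(SD) != nrow(SM))
      stop("raw-feature variants need equally many miRNAs and diseases ",
           "(feature widths must match); have ", nrow(SM), " vs ", nrow(SD))
    X <- rbind(SD, SM)
  }
  nz <- which(A == 1L, arr.ind = TRUE)
  edges <- cbind(nz[, 2], Nd + nz[, 1])  # (disease index, global miRNA index)
  list(SD = SD, SM = SM, X = X, edges = edges)
}

#' Fit the heterogeneous-graph association model
#'
#' Fits the full pipeline on a known-association matrix: integrates DAG
#' semantic (or user-supplied) disease similarity and miRNA functional
#' similarity with GIP kernels, learns weighted-walk node embeddings,
#' refines them with a multi-head GAT over the bipartite association graph,
#' and trains the pair scorer on the known associations plus uniformly
#' sampled negative pairs by full-batch Adam.
#'
#' @param assoc binary association matrix (miRNAs x diseases) with
#'   dimnames, e.g. from [read_association_pairs()] or [simulate_mda()].
#' @param dags named list of disease DAGs from [build_disease_dags()];
#'   required unless `ss` is given.
#' @param fs miRNA functional similarity matrix (aligned or named).
#' @param ss optional precomputed disease semantic similarity matrix;
#'   overrides `dags`.
#' @param control a [hgmda_control()] object.
#' @param seed integer seed governing negative sampling, walks, embedding
#'   training and parameter initialization.
#' @param exclude_negatives optional data.frame with columns `mirna` and
#'   `disease`: unknown pairs that must not be drawn as negatives (used by
#'   the per-disease case-study protocol, which excludes the target
#'   disease's candidate pairs from negative sampling).
#' @return an object of class `hgmda`.
#' @export
hgmda <- function(assoc, dags = NULL, fs = NULL, ss = NULL,
                  control = hgmda_control(), seed = 1,
                  exclude_negatives = NULL) {
  stopifnot(inherits(control, "hgmda_control"))
  rownames(assoc) <- canonicalize_names(rownames(assoc))
  colnames(assoc) <- canonicalize_names(colnames(assoc))
  validate_assoc(assoc)
  mirnas <- rownames(assoc); diseases <- colnames(assoc)
  flags <- variant_flags(control$variant)

  if (is.null(ss)) {
    if (is.null(dags)) stop("provide either disease DAGs or a precomputed ss matrix")
    ss <- semantic_similarity(dags, control$delta)
  }
  SS <- align_similarity(ss, diseases, "disease semantic")
  if (is.null(fs)) stop("miRNA functional similarity fs is required")
  FS <- align_similarity(fs, mirnas, "miRNA functional")

  seeds <- make_seeds(seed, 4)
  neg <- sample_negative_pairs(assoc, control$negative_ratio,
                               seed = seeds[1], exclude = exclude_negatives)
  pos <- which(assoc == 1L, arr.ind = TRUE)
  pairs <- data.frame(
    di = c(pos[, 2], neg$disease_index),
    mi = c(pos[, 1], neg$mirna_index),
    y = c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  )
  inputs <- build_feature_inputs(assoc, SS, FS, control, flags,
                                 seeds = seeds[2:3])
  model <- make_pair_model(inputs$X, inputs$edges, inputs$SD, inputs$SM,
                           pairs, control, seed = seeds[4])
  fitres <- train_pair_model(model, control)

  gat <- model$gat
  if (!is.null(gat) && flags$gat == "trained") gat$theta <- fitres$theta$gat
  structure(list(
    call = match.call(), control = control, seed = seed, flags = flags,
    mirnas = mirnas, diseases = diseases, assoc = assoc,
    SS = SS, FS = FS, SD = inputs$SD, SM = inputs$SM, X = inputs$X,
    edges = inputs$edges, theta = fitres$theta, gat = gat,
    H = fitres$final$H, Pd = fitres$final$Pd, Pm = fitres$final$Pm,
    loss_log = fitres$loss_log, epochs = fitres$epochs,
    pairs = pairs, train_scores = fitres$final$scores
  ), class = "hgmda")
}

# Score arbitrary (disease index, miRNA index) pairs with a fitted model.
score_pairs_idx <- function(object, di, mi) {
  Nd <- length(object$diseases)
  Hd <- object$H[seq_len(Nd), , drop = FALSE]
  Hm <- object$H[Nd + seq_along(object$mirnas), , drop = FALSE]
  Ud <- pair_repr(Hd, object$Pd, di, object$control$accumulation)
  Um <- pair_repr(Hm, object$Pm, mi, object$control$accumulation)
  z <- if (object$flags$predictor == "fc") {
    fc_forward(cbind(Ud, Um), object$theta$fc, object$control$act_slope)$z
  } else {
    rowSums(Ud * Um)
  }
  unname(plogis(z))
}

#' Predict association scores
#'
#' @param object a fitted `hgmda` model.
#' @param newdata optional data.frame with character columns `mirna` and
#'   `disease` (names are canonicalized before matching). When omitted, the
#'   full miRNA x disease score matrix is returned.
#' @param ... unused.
#' @return numeric vector of scores in (0, 1), or the full score matrix.
#' @export
predict.hgmda <- function(object, newdata = NULL, ...) {
  Nd <- length(object$diseases); Nm <- length(object$mirnas)
  if (is.null(newdata)) {
    out <- matrix(NA_real_, Nm, Nd,
                  dimnames = list(object$mirnas, object$diseases))
    for (j in seq_len(Nd)) {   # chunked by disease to bound memory
      out[, j] <- score_pairs_idx(object, rep(j, Nm), seq_len(Nm))
    }
    return(out)
  }
  stopifnot(is.data.frame(newdata), all(c("mirna", "disease") %in% names(newdata)))
  mi <- match(canonicalize_names(newdata$mirna), object$mirnas)
  di <- match(canonicalize_names(newdata$disease), object$diseases)
  if (anyNA(mi)) stop("unknown miRNA name(s): ",
                      paste(head(unique(newdata$mirna[is.na(mi)]), 3), collapse = ", "))
  if (anyNA(di)) stop("unknown disease name(s): ",
                      paste(head(unique(newdata$disease[is.na(di)]), 3), collapse = ", "))
  score_pairs_idx(object, di, mi)
}

#' @export
print.hgmda <- function(x, ...) {
  cat("Heterogeneous-graph miRNA-disease association model\n")
  cat("  variant:   ", x$control$variant, "\n", sep = "")
  cat("  entities:  ", length(x$mirnas), " miRNAs x ", length(x$diseases),
      " diseases, ", sum(x$assoc), " known associations\n", sep = "")
  cat("  training:  ", nrow(x$pairs), " pairs, ", x$epochs, " epochs",
      if (x$epochs > 0) sprintf(", final loss %.4f", tail_loss(x)) else "",
      "\n", sep = "")
  invisible(x)
}

tail_loss <- function(x) x$loss_log[length(x$loss_log)]

#' @export
summary.hgmda <- function(object, ...) {
  scores <- object$train_scores
  y <- object$pairs$y
  s <- list(
    model = object,
    n_params = length(unlist(object$theta, use.names = FALSE)),
    train_metrics = c(binary_metrics(scores, y),
                      auc = roc_auc(scores, y), aupr = pr_auc(scores, y))
  )
  class(s) <- "summary.hgmda"
  s
}

#' @export
print.summary.hgmda <- function(x, ...) {
  print(x$model)
  cat("  trainable parameters: ", x$n_params, "\n", sep = "")
  cat("  training-set metrics (threshold 0.5):\n")
  print(round(x$train_metrics, 4))
  invisible(x)
}

#' @export
coef.hgmda <- function(object, ...) object$theta

#' @export
fitted.hgmda <- function(object, ...) object$train_scores

#' @export
residuals.hgmda <- function(object, ...) object$pairs$y - object$train_scores

#' Plot the training loss curve
#'
#' @param x a fitted `hgmda` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hgmda <- function(x, ...) {
  if (length(x$loss_log) < 2) {
    warning("no training trajectory to plot (untrained variant)")
    return(invisible(x))
  }
  graphics::plot(seq_along(x$loss_log), x$loss_log, type = "l",
                 xlab = "epoch", ylab = "training loss", ...)
  invisible(x)
}
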