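#' Sample negative (unknown) miRNA-disease pairs
#'
#' Uniform sample without replacement from the zero cells of the
#' association matrix, excluding any pairs in `exclude`. The sample size is
#' `round(ratio * #positives)`.
#'
#' @param A binary association matrix (miRNAs x diseases, with dimnames).
#' @param ratio negatives per known positive (default 1).
#' @param seed optional integer seed; the sample is deterministic given it.
#' @param exclude optional data.frame with columns `mirna`, `disease`
#'   (names) or a two-column index matrix `(mirna_index, disease_index)` of
#'   pairs that must not be drawn.
#' @return data.frame with columns `mirna_index`, `disease_index`,
#'   `mirna`, `disease`, `label` (all 0).
#' @export
sample_negative_pairs <- function(A, ratio = 1, seed = NULL, exclude = NULL) {
  validate_assoc(A)
  stopifnot(ratio > 0)
  npos <- sum(A == 1L)
  zero <- which(A == 0L)
  if (!is.null(exclude)) {
    if (is.data.frame(exclude)) {
      mi <- match(canonicalize_names(exclude$mirna), rownames(A))
      di <- match(canonicalize_names(exclude$disease), colnames(A))
      if (anyNA(mi) || anyNA(di)) stop("exclude refers to unknown names")
    } else {
      mi <- exclude[, 1]; di <- exclude[, 2]
    }
    zero <- setdiff(zero, (di - 1L) * nrow(A) + mi)
  }
  n_neg <- round(ratio * npos)
  if (n_neg > length(zero))
    stop("not enough unknown pairs to sample ", n_neg, " negatives (",
         length(zero), " available)")
  if (!is.null(seed)) set.seed(seed)
  cells <- zero[sample.int(length(zero), n_neg)]
  mirna_index <- ((cells - 1L) %% nrow(A)) + 1L
  disease_index <- ((cells - 1L) %/% nrow(A)) + 1L
  data.frame(mirna_index = mirna_index, disease_index = disease_index,
             mirna = rownames(A)[mirna_index],
             disease = colnames(A)[disease_index],
             label = 0)
}

#' Five-fold cross-validation of the association model
#'
#' Samples negatives at the configured ratio, shuffles positives and
#' negatives together, splits them into `k` near-equal folds, and for each
#' fold trains on the remainder and scores the held-out samples. With
#' `mask_test_edges = TRUE` (the default) the held-out positives are
#' removed from the association matrix before the GIP kernels, integrated
#' similarities, embeddings and the attention graph are built for that
#' fold, so no test label leaks into graph construction; setting it to
#' `FALSE` builds everything from the full matrix (the protocol most
#' published comparisons appear to use).
#'
#' @inheritParams hgmda
#' @param k number of folds (default 5).
#' @param mask_test_edges rebuild fold inputs from the training fold only?
#' @return object of class `hgmda_cv`: per-fold metric table with mean and
#'   standard-deviation rows, plus fold details.
#' @export
hgmda_cv <- function(assoc, dags = NULL, fs = NULL, ss = NULL, k = 5,
                     seed = 1, control = hgmda_control(),
                     mask_test_edges = TRUE) {
  stopifnot(inherits(control, "hgmda_control"))
  rownames(assoc) <- canonicalize_names(rownames(assoc))
  colnames(assoc) <- canonicalize_names(colnames(assoc))
  validate_assoc(assoc)
  flags <- variant_flags(control$variant)
  if (is.null(ss)) {
    if (is.null(dags)) stop("provide either disease DAGs or a precomputed ss matrix")
    ss <- semantic_similarity(dags, control$delta)
  }
  SS <- align_similarity(ss, colnames(assoc), "disease semantic")
  if (is.null(fs)) stop("miRNA functional similarity fs is required")
  FS <- align_similarity(fs, rownames(assoc), "miRNA functional")

  seeds <- make_seeds(seed, 2 + 3 * k)
  neg <- sample_negative_pairs(assoc, control$negative_ratio, seed = seeds[1])
  pos <- which(assoc == 1L, arr.ind = TRUE)
  samples <- data.frame(
    di = c(pos[, 2], neg$disease_index),
    mi = c(pos[, 1], neg$mirna_index),
    y = c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  )
  fold <- kfold_split(nrow(samples), k, seed = seeds[2])

  metric_names <- c("accuracy", "precision", "recall", "f1", "auc", "aupr")
  per_fold <- matrix(NA_real_, k, length(metric_names),
                     dimnames = list(paste0("fold", seq_len(k)), metric_names))
  details <- vector("list", k)
  for (f in seq_len(k)) {
    test <- samples[fold == f, ]
    train <- samples[fold != f, ]
    A_fold <- assoc
    if (mask_test_edges) {
      tp <- test[test$y == 1, ]
      A_fold[cbind(tp$mi, tp$di)] <- 0L
      if (sum(A_fold) == 0) stop("masking removed every association; fold too large")
    }
    inputs <- build_feature_inputs(A_fold, SS, FS, control, flags,
                                   seeds = seeds[2 + c(f, k + f)])
    model <- make_pair_model(inputs$X, inputs$edges, inputs$SD, inputs$SM,
                             train, control, seed = seeds[2 + 2 * k + f])
    fitres <- train_pair_model(model, control)
    shim <- list(diseases = colnames(assoc), mirnas = rownames(assoc),
                 H = fitres$final$H, Pd = fitres$final$Pd,
                 Pm = fitres$final$Pm, theta = fitres$theta,
                 flags = flags, control = control)
    test_scores <- score_pairs_idx(shim, test$di, test$mi)
    per_fold[f, ] <- all_metrics(test_scores, test$y)
    details[[f]] <- list(
      test_positives = test[test$y == 1, c("mi", "di")],
      edges = inputs$edges, epochs = fitres$epochs,
      final_loss = fitres$loss_log[length(fitres$loss_log)],
      scores = test_scores, labels = test$y
    )
  }
  metrics <- rbind(per_fold,
                   mean = colMeans(per_fold),
                   sd = apply(per_fold, 2, sd))
  structure(list(metrics = as.data.frame(metrics), k = k, seed = seed,
                 samples = samples, fold = fold,
                 mask_test_edges = mask_test_edges,
                 control = control, details = details),
            class = "hgmda_cv")
}

#' @export
print.hgmda_cv <- function(x, digits = 4, ...) {
  cat(x$k, "-fold cross-validation (variant '", x$control$variant, "', ",
      if (x$mask_test_edges) "test edges masked" else "full-graph (unmasked)",
      ")\n", sep = "")
  print(round(x$metrics, digits))
  invisible(x)
}

#' Run an architecture ablation
#'
#' Cross-validates one of the predefined architecture variants (see
#' [hgmda_variants()]) under the same protocol as [hgmda_cv()].
#'
#' @inheritParams hgmda_cv
#' @param variant variant identifier.
#' @param ... passed on to [hgmda_cv()].
#' @return an `hgmda_cv` object.
#' @export
ablation_run <- function(assoc, dags = NULL, fs = NULL, variant,
                         control = hgmda_control(), ...) {
  control$variant <- variant
  variant_flags(variant)
  hgmda_cv(assoc, dags = dags, fs = fs, control = control, ...)
}
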