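#' Simulate a planted-block miRNA-disease dataset
#'
#' Generates the three inputs of the pipeline with a matched latent block
#' structure: miRNAs and diseases are partitioned into `n_blocks` paired
#' blocks; an association is Bernoulli(`p_within`) when the miRNA's and
#' disease's blocks match and Bernoulli(`p_between`) otherwise. Disease
#' DAGs are random tree-number chains that share prefixes within a block
#' (so DAG semantic similarity is high within blocks and zero across), and
#' the miRNA functional similarity is the block indicator plus Gaussian
#' noise, symmetrized, unit diagonal, clipped to `[0, 1]`. All-zero rows or
#' columns of the association matrix are resampled (bounded retries). The
#' output is fully reproducible from `seed`.
#'
#' @param n_mirna,n_disease entity counts (default 40 each).
#' @param n_blocks number of matched latent blocks (default 2).
#' @param p_within association probability inside matched blocks
#'   (default 0.8).
#' @param p_between association probability across blocks (default 0.05);
#'   must not exceed `p_within`.
#' @param dag_depth maximum tree-number chain depth (default 4).
#' @param noise_sd standard deviation of the functional-similarity noise
#'   (default 0.1).
#' @param seed integer seed.
#' @return list of class `mda_sim` with `assoc` (binary matrix), `dags`
#'   (list of [disease_dag()]), `fs` (functional similarity), `blocks`
#'   (latent block labels) and `config`.
#' @export
simulate_mda <- function(n_mirna = 40, n_disease = 40, n_blocks = 2,
                         p_within = 0.8, p_between = 0.05, dag_depth = 4,
                         noise_sd = 0.1, seed = 1) {
  stopifnot(n_mirna >= 1, n_disease >= 1, n_blocks >= 1,
            p_between >= 0, p_within <= 1, p_between <= p_within,
            dag_depth >= 1, noise_sd >= 0)
  set.seed(seed)
  mirnas <- sprintf("mirna%03d", seq_len(n_mirna))
  diseases <- sprintf("disease%03d", seq_len(n_disease))
  block_m <- sort(rep_len(seq_len(n_blocks), n_mirna))
  block_d <- sort(rep_len(seq_len(n_blocks), n_disease))

  pmat <- ifelse(outer(block_m, block_d, `==`), p_within, p_between)
  A <- matrix(rbinom(length(pmat), 1L, pmat), n_mirna, n_disease,
              dimnames = list(mirnas, diseases))
  for (try in seq_len(100)) {
    zr <- which(rowSums(A) == 0); zc <- which(colSums(A) == 0)
    if (!length(zr) && !length(zc)) break
    for (i in zr) A[i, ] <- rbinom(n_disease, 1L, pmat[i, ])
    for (j in zc) A[, j] <- rbinom(n_mirna, 1L, pmat[, j])
  }
  if (any(rowSums(A) == 0) || any(colSums(A) == 0))
    stop("could not sample an association matrix without empty rows/columns; ",
         "raise p_between or the entity counts")
  storage.mode(A) <- "integer"

  # Per block: one random trunk chain of tree-number segments; each disease
  # uses a random-length prefix of its block's trunk, optionally extended by
  # a private leaf segment, so DAGs overlap within blocks only.
  trunks <- lapply(seq_len(n_blocks), function(b) {
    c(sprintf("B%02d", b), sprintf("%03d", sample(100:999, dag_depth - 1)))
  })
  tn <- vapply(seq_len(n_disease), function(i) {
    trunk <- trunks[[block_d[i]]]
    depth <- sample.int(dag_depth, 1)
    base <- paste(trunk[seq_len(depth)], collapse = ".")
    if (runif(1) < 0.5) paste0(base, ".", sprintf("%03d", sample(100:999, 1)))
    else base
  }, "")
  dags <- build_disease_dags(data.frame(disease = diseases, tree_number = tn))

  FS <- outer(block_m, block_m, `==`) * 1 +
    matrix(rnorm(n_mirna^2, sd = noise_sd), n_mirna, n_mirna)
  FS <- sanitize_similarity(FS, warn_clip = FALSE)
  dimnames(FS) <- list(mirnas, mirnas)

  structure(list(assoc = A, dags = dags, fs = FS,
                 blocks = list(mirna = block_m, disease = block_d),
                 config = list(n_mirna = n_mirna, n_disease = n_disease,
                               n_blocks = n_blocks, p_within = p_within,
                               p_between = p_between, dag_depth = dag_depth,
                               noise_sd = noise_sd, seed = seed)),
            class = "mda_sim")
}

#' @export
print.mda_sim <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic planted-block dataset: ", cfg$n_mirna, " miRNAs x ",
      cfg$n_disease, " diseases, ", cfg$n_blocks, " blocks, ",
      sum(x$assoc), " associations (seed ", cfg$seed, ")\n", sep = "")
  invisible(x)
}
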