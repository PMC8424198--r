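#' GIP kernel bandwidth
#'
#' The Gaussian interaction profile (GIP) kernel bandwidth is the reference
#' bandwidth `gamma_prime` divided by the mean squared Euclidean norm of
#' the interaction profiles along the chosen axis (columns of the
#' association matrix for diseases, rows for miRNAs) — the van Laarhoven
#' normalization, so the kernel scale adapts to the overall density of the
#' association matrix.
#'
#' @param A binary association matrix (miRNAs x diseases).
#' @param axis `"disease"` (profiles are columns) or `"mirna"` (rows).
#' @param gamma_prime reference bandwidth, default 1.
#' @return positive scalar bandwidth.
#' @export
gip_bandwidth <- function(A, axis = c("disease", "mirna"), gamma_prime = 1) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(A), gamma_prime > 0)
  norms2 <- if (axis == "disease") colSums(A^2) else rowSums(A^2)
  m <- mean(norms2)
  if (m == 0) stop("all interaction profiles are zero; GIP bandwidth undefined")
  gamma_prime / m
}

#' GIP kernel similarity
#'
#' Gaussian kernel on binary interaction profiles:
#' `K(x, y) = exp(-gamma * ||profile(x) - profile(y)||^2)` with the
#' bandwidth of [gip_bandwidth()]. Unlike DAG- or function-derived
#' similarities, every entry is strictly positive, which is why it is
#' averaged into the integrated similarities.
#'
#' @inheritParams gip_bandwidth
#' @return symmetric similarity matrix with unit diagonal and entries in
#'   `(0, 1]`, named along the chosen axis.
#' @export
gip_kernel <- function(A, axis = c("disease", "mirna"), gamma_prime = 1) {
  axis <- match.arg(axis)
  gamma <- gip_bandwidth(A, axis, gamma_prime)
  P <- if (axis == "disease") t(A) else A
  r <- rowSums(P^2)
  D2 <- outer(r, r, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0
  K <- exp(-gamma * D2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  nm <- if (axis == "disease") colnames(A) else rownames(A)
  dimnames(K) <- list(nm, nm)
  K
}

#' Average two similarity matrices
#'
#' Elementwise unconditional average, used to integrate a sparse
#' structure-derived similarity with the dense GIP kernel: the disease
#' similarity is the average of semantic and GIP-kernel similarity, the
#' miRNA similarity the average of functional and GIP-kernel similarity.
#'
#' @param S1,S2 square numeric matrices of identical shape and name order.
#' @return `(S1 + S2) / 2`.
#' @export
integrate_similarity <- function(S1, S2) {
  stopifnot(is.matrix(S1), is.matrix(S2))
  if (!identical(dim(S1), dim(S2)))
    stop("similarity matrices have different shapes: ",
         paste(dim(S1), collapse = "x"), " vs ", paste(dim(S2), collapse = "x"))
  if (!is.null(rownames(S1)) && !is.null(rownames(S2)) &&
      !identical(rownames(S1), rownames(S2)))
    stop("similarity matrices have different name orders")
  (S1 + S2) / 2
}
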