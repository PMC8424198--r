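# Pair scorer: combines GAT-refined node features with projected raw
# similarity features and maps each (disease, miRNA) pair to a probability,
# either through a fully connected network or a plain dot product.

#' Initialize fully connected predictor parameters
#'
#' A stack of dense layers with LeakyReLU between hidden layers and a
#' single sigmoid output unit. Weights are Glorot-uniform, biases zero.
#'
#' @param in_width input width (the concatenated pair representation).
#' @param hidden integer vector of hidden widths (default `c(128, 64)`,
#'   giving the three-layer predictor).
#' @param seed optional integer seed.
#' @return list of layers, each with `W` and `b`.
#' @export
fc_params <- function(in_width, hidden = c(128, 64), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  glorot <- function(nr, nc) {
    s <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -s, s), nr, nc)
  }
  dims <- c(in_width, hidden, 1)
  layers <- lapply(seq_len(length(dims) - 1), function(i) {
    list(W = glorot(dims[i + 1], dims[i]), b = numeric(dims[i + 1]))
  })
  names(layers) <- paste0("fc", seq_along(layers))
  layers
}

# forward: U (npairs x in_width) -> list(z = logits, cache)
fc_forward <- function(U, fc, act_slope) {
  L <- length(fc)
  acts <- vector("list", L + 1)
  pre <- vector("list", L)
  acts[[1]] <- U
  for (i in seq_len(L)) {
    z <- acts[[i]] %*% t(fc[[i]]$W)
    z <- sweep(z, 2, fc[[i]]$b, `+`)
    pre[[i]] <- z
    acts[[i + 1]] <- if (i < L) lrelu(z, act_slope) else z
  }
  list(z = drop(acts[[L + 1]]), acts = acts, pre = pre)
}

# backward: dz (npairs) -> grads per layer + dU
fc_backward <- function(dz, cache, fc, act_slope) {
  L <- length(fc)
  grads <- vector("list", L)
  d <- matrix(dz, ncol = 1)
  for (i in rev(seq_len(L))) {
    if (i < L) d <- d * dlrelu(cache$pre[[i]], act_slope)
    grads[[i]] <- list(W = crossprod(d, cache$acts[[i]]), b = colSums(d))
    d <- d %*% fc[[i]]$W
  }
  names(grads) <- names(fc)
  list(grads = grads, dU = d)
}

# Assemble the per-pair disease and miRNA representations.
# Hd: Nd x F refined disease features; Pd: Nd x F projected raw features
# (NULL when raw features are not used); di: pair disease indices.
pair_repr <- function(Hside, Pside, idx, accumulation) {
  X <- Hside[idx, , drop = FALSE]
  if (is.null(Pside)) return(X)
  R <- Pside[idx, , drop = FALSE]
  if (accumulation == "concat") cbind(X, R) else X + R
}

# Split dU back into the node-feature part and the raw-projection part.
split_pair_grad <- function(dUside, f_node, accumulation, use_raw) {
  if (!use_raw) return(list(dX = dUside, dR = NULL))
  if (accumulation == "concat") {
    list(dX = dUside[, seq_len(f_node), drop = FALSE],
         dR = dUside[, f_node + seq_len(ncol(dUside) - f_node), drop = FALSE])
  } else {
    list(dX = dUside, dR = dUside)
  }
}

#' Cross-entropy loss with L2 penalty
#'
#' Summed (not averaged) binary cross-entropy over the scored pairs plus an
#' L2 penalty `lambda * theta_norm_sq` on the model parameters. Scores
#' exactly 0 or 1 are clamped to `[1e-7, 1 - 1e-7]` before the logarithm,
#' with a warning.
#'
#' @param scores predicted probabilities in `(0, 1)`.
#' @param labels 0/1 labels, same length.
#' @param theta_norm_sq squared L2 norm of all trainable parameters.
#' @param lambda penalty factor (default 0).
#' @return scalar loss.
#' @export
#' @examples
#' bce_loss(0.5, 1)                      # log(2)
#' bce_loss(0.5, 1, theta_norm_sq = 1, lambda = 0.5)
bce_loss <- function(scores, labels, theta_norm_sq = 0, lambda = 0) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (any(scores <= 0 | scores >= 1)) {
    warning("scores clamped away from {0, 1} before taking logs")
    scores <- pmin(pmax(scores, 1e-7), 1 - 1e-7)
  }
  -sum(labels * log(scores) + (1 - labels) * log(1 - scores)) +
    lambda * theta_norm_sq
}

# internal, warning-free version used inside the training loop
bce_loss_quiet <- function(scores, labels) {
  scores <- pmin(pmax(scores, 1e-7), 1 - 1e-7)
  -sum(labels * log(scores) + (1 - labels) * log(1 - scores))
}
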