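# End-to-end trainer: joint full-batch gradient training of the GAT
# encoder, the raw-feature projections and the FC predictor with Adam.
# Parameters live in a nested list; for the optimizer and for finite
# difference checks they are flattened with unlist() and restored with
# relist(), so the analytic gradients and the parameter vector always share
# one canonical ordering.

#' Ablation variants
#'
#' Identifiers of the supported architecture variants: node features from
#' weighted-walk embeddings (`dw`) or raw integrated-similarity rows
#' (`raw`), with or without a (trained or untrained) GAT encoder, and a dot
#' product or fully connected (`fc`) predictor, optionally concatenating
#' projected raw features into the pair representation (`dw_raw_*`).
#' `dw_raw_gat_fc` is the full default pipeline.
#'
#' @return character vector of variant identifiers.
#' @export
hgmda_variants <- function() {
  c("dw_dot", "dw_gat_untrained_dot", "dw_gat_dot", "raw_gat_dot",
    "dw_raw_gat_dot", "dw_raw_gat_fc")
}

variant_flags <- function(variant) {
  switch(variant,
    dw_dot               = list(features = "embedding", gat = "none",
                                raw = FALSE, predictor = "dot"),
    dw_gat_untrained_dot = list(features = "embedding", gat = "untrained",
                                raw = FALSE, predictor = "dot"),
    dw_gat_dot           = list(features = "embedding", gat = "trained",
                                raw = FALSE, predictor = "dot"),
    raw_gat_dot          = list(features = "raw", gat = "trained",
                                raw = FALSE, predictor = "dot"),
    dw_raw_gat_dot       = list(features = "embedding", gat = "trained",
                                raw = TRUE, predictor = "dot"),
    dw_raw_gat_fc        = list(features = "embedding", gat = "trained",
                                raw = TRUE, predictor = "fc"),
    stop("unknown variant '", variant, "'; valid variants: ",
         paste(hgmda_variants(), collapse = ", "))
  )
}

theta_sqnorm <- function(theta) {
  v <- unlist(theta, use.names = FALSE)
  if (is.null(v)) 0 else sum(v^2)
}

# Fast structured <-> flat conversion (utils::relist rebuilds names and is
# far too slow to run once per epoch). The skeleton supplies list shape and
# leaf dims; values come from the flat vector in depth-first order, the
# same order unlist() uses.
unflatten <- function(vec, skel) {
  pos <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    n <- length(s)
    out <- vec[pos + seq_len(n)]
    pos <<- pos + n
    d <- dim(s)
    if (!is.null(d)) dim(out) <- d
    out
  }
  rec(skel)
}

glorot_mat <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

# Build the model state: fixed inputs plus a loss/gradient closure.
# X: (Nd+Nm) x F node features, diseases first; edges: 2-col (disease idx,
# Nd + mirna idx); pairs: data.frame(di, mi, y).
make_pair_model <- function(X, edges, SD, SM, pairs, control, seed) {
  flags <- variant_flags(control$variant)
  Nd <- nrow(SD); Nm <- nrow(SM)
  stopifnot(nrow(X) == Nd + Nm)
  f_dim <- ncol(X)
  graph <- gat_graph(edges, Nd + Nm)
  set.seed(seed)

  gat <- NULL
  if (flags$gat != "none") {
    gat <- gat_params(f_dim, n_layers = control$gat_layers,
                      n_heads = control$gat_heads, output_dim = f_dim,
                      attn_slope = control$attn_slope,
                      act_slope = control$act_slope)
  }
  theta <- list()
  if (flags$gat == "trained") theta$gat <- gat$theta
  if (flags$raw) {
    theta$Wd <- glorot_mat(Nd, f_dim)
    theta$Wm <- glorot_mat(Nm, f_dim)
  }
  side_width <- f_dim * (if (flags$raw && control$accumulation == "concat") 2 else 1)
  if (flags$predictor == "fc") {
    theta$fc <- fc_params(2 * side_width, hidden = control$fc_hidden)
  }

  di <- pairs$di; mi <- pairs$mi; y <- pairs$y
  # pair-gradient scatter back onto nodes (nodes without pairs get zero)
  scatter <- function(dU, idx, nrows) {
    out <- matrix(0, nrows, ncol(dU))
    agg <- rowsum(dU, idx)
    out[as.integer(rownames(agg)), ] <- agg
    out
  }

  loss_grads <- function(theta, want_grads = TRUE) {
    if (!is.null(gat) && flags$gat == "trained") gat$theta <- theta$gat
    if (is.null(gat)) {
      H <- X; fw <- NULL
    } else {
      fw <- gat_forward(X, graph, gat, return_cache = TRUE)
      H <- fw$H
    }
    Hd <- H[seq_len(Nd), , drop = FALSE]
    Hm <- H[Nd + seq_len(Nm), , drop = FALSE]
    Pd <- if (flags$raw) SD %*% theta$Wd else NULL
    Pm <- if (flags$raw) SM %*% theta$Wm else NULL
    Ud <- pair_repr(Hd, Pd, di, control$accumulation)
    Um <- pair_repr(Hm, Pm, mi, control$accumulation)
    if (flags$predictor == "fc") {
      fcres <- fc_forward(cbind(Ud, Um), theta$fc, control$act_slope)
      z <- fcres$z
    } else {
      z <- rowSums(Ud * Um)
    }
    scores <- plogis(z)
    loss <- bce_loss_quiet(scores, y) + control$lambda * theta_sqnorm(theta)
    out <- list(loss = loss, scores = scores, H = H, Pd = Pd, Pm = Pm)
    if (!want_grads) return(out)

    grads <- theta  # same skeleton, values overwritten below
    dz <- scores - y
    if (flags$predictor == "fc") {
      fb <- fc_backward(dz, fcres, theta$fc, control$act_slope)
      grads$fc <- fb$grads
      dUd <- fb$dU[, seq_len(side_width), drop = FALSE]
      dUm <- fb$dU[, side_width + seq_len(side_width), drop = FALSE]
    } else {
      dUd <- dz * Um
      dUm <- dz * Ud
    }
    sd_ <- split_pair_grad(dUd, f_dim, control$accumulation, flags$raw)
    sm_ <- split_pair_grad(dUm, f_dim, control$accumulation, flags$raw)
    if (flags$raw) {
      grads$Wd <- crossprod(SD, scatter(sd_$dR, di, Nd))
      grads$Wm <- crossprod(SM, scatter(sm_$dR, mi, Nm))
    }
    if (flags$gat == "trained") {
      dH <- rbind(scatter(sd_$dX, di, Nd), scatter(sm_$dX, mi, Nm))
      grads$gat <- gat_backward(dH, fw$caches, gat, graph)$grads
    }
    # L2 penalty gradient on every trainable parameter
    gv <- unlist(grads, use.names = FALSE)
    tv <- unlist(theta, use.names = FALSE)
    if (length(tv)) grads <- unflatten(gv + 2 * control$lambda * tv, grads)
    out$grads <- grads
    out
  }

  list(theta = theta, loss_grads = loss_grads, gat = gat, graph = graph,
       flags = flags, side_width = side_width, Nd = Nd, Nm = Nm)
}

# Full-batch Adam with decoupled-from-loss weight decay (added to the
# gradient, as in the usual Adam implementations) and early stopping on a
# training-loss plateau.
train_pair_model <- function(model, control) {
  theta <- model$theta
  tv <- unlist(theta, use.names = FALSE)
  if (!length(tv)) {             # e.g. embeddings + dot product: nothing to fit
    res <- model$loss_grads(theta, want_grads = FALSE)
    return(list(theta = theta, loss_log = res$loss, final = res, epochs = 0L))
  }
  m <- v <- numeric(length(tv))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- control$learning_rate; wd <- control$weight_decay
  best <- Inf; stall <- 0L
  loss_log <- numeric(control$epochs)
  epochs_run <- 0L
  for (t in seq_len(control$epochs)) {
    res <- model$loss_grads(theta)
    if (!is.finite(res$loss))
      stop("non-finite training loss at epoch ", t,
           "; try a lower learning rate")
    loss_log[t] <- res$loss
    epochs_run <- t
    g <- unlist(res$grads, use.names = FALSE) + wd * tv
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    tv <- tv - lr * mhat / (sqrt(vhat) + eps)
    theta <- unflatten(tv, theta)
    if (res$loss < best - 1e-8) {
      best <- res$loss; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= control$patience) break
    }
  }
  final <- model$loss_grads(theta, want_grads = FALSE)
  list(theta = theta, loss_log = loss_log[seq_len(epochs_run)],
       final = final, epochs = epochs_run)
}
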