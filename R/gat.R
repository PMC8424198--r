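# Multi-head graph attention encoder over the miRNA-disease bipartite
# graph, written as explicit matrix/edge-list operations with a matching
# analytic backward pass (verified against finite differences in the test
# suite). Graphs here have a few hundred nodes, so dense per-head matrices
# and rowsum() segment reductions are ample.

lrelu <- function(x, slope) x * (x > 0) + slope * x * (x <= 0)
dlrelu <- function(x, slope) (x > 0) + slope * (x <= 0)

#' Build the directed edge structure for attention
#'
#' Takes undirected edges (two-column index matrix), adds both
#' orientations and one self-loop per node (every node's neighbourhood
#' includes itself, which also gives isolated nodes a defined output), and
#' deduplicates.
#'
#' @param edges two-column integer matrix of undirected node-index pairs;
#'   may have zero rows.
#' @param n_nodes number of nodes.
#' @return object of class `gat_graph` with sorted `src`, `dst` index
#'   vectors.
#' @export
gat_graph <- function(edges, n_nodes) {
  if (is.null(edges) || !nrow(edges)) {
    src <- dst <- integer(0)
  } else {
    stopifnot(ncol(edges) == 2, max(edges) <= n_nodes, min(edges) >= 1)
    src <- c(edges[, 1], edges[, 2])
    dst <- c(edges[, 2], edges[, 1])
  }
  src <- c(src, seq_len(n_nodes))
  dst <- c(dst, seq_len(n_nodes))
  keep <- !duplicated(cbind(src, dst))
  src <- src[keep]; dst <- dst[keep]
  ord <- order(src, dst)
  src <- src[ord]; dst <- dst[ord]
  # self-loops guarantee every node occurs in both src and dst, so the
  # rowsum() segment reductions used in the layers return one row per node
  # in index order
  structure(list(src = src, dst = dst, n = n_nodes,
                 groups = split(seq_along(src), src)),
            class = "gat_graph")
}

#' Initialize multi-head GAT parameters
#'
#' Builds Glorot-uniform initialized parameters for a stack of attention
#' layers. All layers except the last concatenate their heads, each head
#' producing `output_dim / n_heads` features so the concatenated width
#' stays at `output_dim`; the last layer's heads each produce `output_dim`
#' features and are averaged before the activation. With the defaults the
#' node feature width is therefore preserved end to end.
#'
#' @param input_dim width of the input node features.
#' @param n_layers number of attention layers (default 2).
#' @param n_heads attention heads per layer (default 16).
#' @param output_dim width of every layer's combined output (default
#'   `input_dim`; must be divisible by `n_heads` when `n_layers > 1`).
#' @param attn_slope negative slope of the LeakyReLU inside the attention
#'   scorer (default 0.02).
#' @param act_slope negative slope of the LeakyReLU layer activation
#'   (default 0.2).
#' @param seed optional integer seed for the initialization.
#' @return object of class `gat_params`: list with `theta` (nested list of
#'   per-layer, per-head `W` and `a`) and `meta` (dimensions and slopes).
#' @export
gat_params <- function(input_dim, n_layers = 2, n_heads = 16,
                       output_dim = input_dim, attn_slope = 0.02,
                       act_slope = 0.2, seed = NULL) {
  stopifnot(n_layers >= 1, n_heads >= 1, input_dim >= 1, output_dim >= 1)
  if (n_layers > 1 && output_dim %% n_heads != 0)
    stop("output_dim must be divisible by n_heads for concatenating layers")
  if (!is.null(seed)) set.seed(seed)
  glorot <- function(nr, nc) {
    s <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -s, s), nr, nc)
  }
  layers <- vector("list", n_layers)
  meta <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fin <- if (l == 1) input_dim else output_dim
    combine <- if (l == n_layers) "average" else "concat"
    fo <- if (combine == "concat") output_dim %/% n_heads else output_dim
    heads <- lapply(seq_len(n_heads), function(k) {
      list(W = glorot(fo, fin),
           a = as.numeric(glorot(2 * fo, 1)))
    })
    names(heads) <- paste0("head", seq_len(n_heads))
    layers[[l]] <- heads
    meta[[l]] <- list(fin = fin, fo = fo, combine = combine)
  }
  names(layers) <- paste0("layer", seq_len(n_layers))
  structure(list(theta = layers,
                 meta = list(layers = meta, n_layers = n_layers,
                             n_heads = n_heads, input_dim = input_dim,
                             output_dim = output_dim,
                             attn_slope = attn_slope, act_slope = act_slope)),
            class = "gat_params")
}

# per-node column maxima of an E x K matrix grouped by graph$groups
group_max <- function(M, groups) {
  out <- vapply(groups, function(ii) {
    apply(M[ii, , drop = FALSE], 2, max)
  }, numeric(ncol(M)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)  # single-head case
  t(out)
}

# Stack all heads of one layer into single matrices so a layer is a handful
# of BLAS calls instead of a per-head loop: Wall is (K*Fo) x Fin with head
# blocks stacked by rows, a_src/a_dst are length-K*Fo vectors, and column
# block k of the n x (K*Fo) matrices belongs to head k.
stack_heads <- function(heads, fo) {
  K <- length(heads)
  list(Wall = do.call(rbind, lapply(heads, `[[`, "W")),
       a_src = unlist(lapply(heads, function(h) h$a[seq_len(fo)]),
                      use.names = FALSE),
       a_dst = unlist(lapply(heads, function(h) h$a[fo + seq_len(fo)]),
                      use.names = FALSE),
       rep_idx = rep(seq_len(K), each = fo),          # column -> head
       Bsum = (outer(rep(seq_len(K), each = fo), seq_len(K), `==`)) * 1,
       Bavg = (outer(rep(seq_len(fo), K), seq_len(fo), `==`)) / K)
}

gat_layer_forward <- function(H, heads, lmeta, meta, graph, engine = "cpp") {
  K <- length(heads)
  fo <- lmeta$fo
  if (ncol(H) != lmeta$fin)
    stop("feature width ", ncol(H), " does not match layer input ", lmeta$fin)
  st <- stack_heads(heads, fo)
  n <- nrow(H)
  if (engine == "cpp") {
    res <- .gat_fwd(H, st$Wall, st$a_src, st$a_dst, graph$src, graph$dst,
                    K, fo, lmeta$combine == "concat", meta$attn_slope,
                    meta$act_slope)
    return(list(H = res$H,
                cache = list(Hin = H, Zt = res$Zt, rawt = res$rawt,
                             alphat = res$alphat, Ut = res$Ut, st = st)))
  }
  Zall <- tcrossprod(H, st$Wall)                               # n x K*Fo
  s_src <- (Zall * rep(st$a_src, each = n)) %*% st$Bsum        # n x K
  s_dst <- (Zall * rep(st$a_dst, each = n)) %*% st$Bsum
  raw <- s_src[graph$src, , drop = FALSE] + s_dst[graph$dst, , drop = FALSE]
  logit <- lrelu(raw, meta$attn_slope)
  mx <- group_max(logit, graph$groups)                         # n x K
  ex <- exp(logit - mx[graph$src, , drop = FALSE])
  denom <- rowsum(ex, graph$src)                # n x K (self-loops: all nodes)
  alpha <- ex / denom[graph$src, , drop = FALSE]
  alpha_exp <- alpha[, st$rep_idx, drop = FALSE]               # E x K*Fo
  Zdst <- Zall[graph$dst, , drop = FALSE]
  Magg <- rowsum(alpha_exp * Zdst, graph$src)                  # n x K*Fo
  U <- if (lmeta$combine == "concat") Magg else Magg %*% st$Bavg
  dimnames(U) <- NULL
  list(H = lrelu(U, meta$act_slope),
       cache = list(Hin = H, Zall = Zall, raw = raw, alpha = alpha, U = U,
                    st = st))
}

#' Run the GAT encoder forward
#'
#' Applies the attention layers in sequence to the node feature matrix.
#' Output row `i` is the refined feature vector of node `i`.
#'
#' @param X node feature matrix, one row per node.
#' @param graph a [gat_graph()].
#' @param params a [gat_params()] object.
#' @param return_cache keep per-layer activations (used by the training
#'   backward pass)?
#' @param engine `"cpp"` (default, fused kernels) or `"r"` (reference
#'   implementation in plain matrix algebra); both compute the same
#'   quantities and the test suite checks their agreement.
#' @return refined feature matrix, or (with `return_cache = TRUE`) a list
#'   with elements `H` and `caches`.
#' @export
gat_forward <- function(X, graph, params, return_cache = FALSE,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "gat_params"), inherits(graph, "gat_graph"))
  if (nrow(X) != graph$n) stop("feature matrix rows must equal node count")
  H <- X
  caches <- vector("list", params$meta$n_layers)
  for (l in seq_len(params$meta$n_layers)) {
    res <- gat_layer_forward(H, params$theta[[l]], params$meta$layers[[l]],
                             params$meta, graph, engine)
    H <- res$H
    caches[[l]] <- res$cache
  }
  if (return_cache) list(H = H, caches = caches) else H
}

#' Attention coefficients of one GAT layer
#'
#' Exposes the softmax-normalized attention weights: for every directed
#' edge (including self-loops) and every head, the weight that the target
#' node assigns to the neighbour. For each node and head the weights over
#' its neighbourhood sum to 1.
#'
#' @param H input feature matrix of the layer.
#' @param graph a [gat_graph()].
#' @param params a [gat_params()] object.
#' @param layer layer index (default 1).
#' @return list with `src`, `dst` and `alpha` (edges x heads matrix).
#' @export
gat_attention <- function(H, graph, params, layer = 1) {
  stopifnot(layer >= 1, layer <= params$meta$n_layers)
  Hl <- H
  if (layer > 1) {
    for (l in seq_len(layer - 1)) {
      Hl <- gat_layer_forward(Hl, params$theta[[l]], params$meta$layers[[l]],
                              params$meta, graph)$H
    }
  }
  res <- gat_layer_forward(Hl, params$theta[[layer]],
                           params$meta$layers[[layer]], params$meta, graph)
  alpha <- if ("alphat" %in% names(res$cache)) t(res$cache[["alphat"]])
           else res$cache[["alpha"]]
  list(src = graph$src, dst = graph$dst, alpha = alpha)
}

gat_layer_backward <- function(dHout, cache, heads, lmeta, meta, graph,
                               engine = "cpp") {
  K <- length(heads)
  fo <- lmeta$fo
  st <- cache$st
  n <- nrow(cache$Hin)
  if (engine == "cpp") {
    res <- .gat_bwd(dHout, cache$Hin, cache$Zt, cache$rawt, cache$alphat,
                    cache$Ut, st$Wall, st$a_src, st$a_dst, graph$src,
                    graph$dst, K, fo, lmeta$combine == "concat",
                    meta$attn_slope, meta$act_slope)
    grads <- lapply(seq_len(K), function(k) {
      blk <- (k - 1) * fo + seq_len(fo)
      list(W = res$dWall[blk, , drop = FALSE],
           a = c(res$da_src[blk], res$da_dst[blk]))
    })
    names(grads) <- names(heads)
    return(list(grads = grads, dH = res$dH))
  }
  dU <- dHout * dlrelu(cache$U, meta$act_slope)
  dMagg <- if (lmeta$combine == "concat") dU
           else dU[, rep(seq_len(fo), K), drop = FALSE] / K    # n x K*Fo
  Zdst <- cache$Zall[graph$dst, , drop = FALSE]
  alpha_exp <- cache$alpha[, st$rep_idx, drop = FALSE]
  dG <- dMagg[graph$src, , drop = FALSE]                       # E x K*Fo
  dalpha <- (dG * Zdst) %*% st$Bsum                            # E x K
  dZall <- rowsum(dG * alpha_exp, graph$dst)                   # aggregation
  srow <- rowsum(cache$alpha * dalpha, graph$src)              # softmax jac.
  de <- cache$alpha * (dalpha - srow[graph$src, , drop = FALSE])
  dlogit <- de * dlrelu(cache$raw, meta$attn_slope)
  ds_src <- rowsum(dlogit, graph$src)                          # n x K
  ds_dst <- rowsum(dlogit, graph$dst)
  ds_src_exp <- ds_src[, st$rep_idx, drop = FALSE]
  ds_dst_exp <- ds_dst[, st$rep_idx, drop = FALSE]
  dZall <- dZall + ds_src_exp * rep(st$a_src, each = n) +
    ds_dst_exp * rep(st$a_dst, each = n)
  da_src <- colSums(cache$Zall * ds_src_exp)                   # length K*Fo
  da_dst <- colSums(cache$Zall * ds_dst_exp)
  dWall <- crossprod(dZall, cache$Hin)                         # K*Fo x Fin
  dH <- dZall %*% st$Wall
  dimnames(dWall) <- dimnames(dH) <- NULL
  grads <- lapply(seq_len(K), function(k) {
    blk <- (k - 1) * fo + seq_len(fo)
    list(W = dWall[blk, , drop = FALSE], a = c(da_src[blk], da_dst[blk]))
  })
  names(grads) <- names(heads)
  list(grads = grads, dH = dH)
}

# Backward pass through the full encoder: returns gradients matching
# params$theta plus the gradient w.r.t. the input features.
gat_backward <- function(dH, caches, params, graph, engine = "cpp") {
  L <- params$meta$n_layers
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    res <- gat_layer_backward(dH, caches[[l]], params$theta[[l]],
                              params$meta$layers[[l]], params$meta, graph,
                              engine)
    grads[[l]] <- res$grads
    dH <- res$dH
  }
  names(grads) <- names(params$theta)
  list(grads = grads, dX = dH)
}
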