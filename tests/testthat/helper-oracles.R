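# Independent oracles used across the suite. These are deliberately naive
# (path enumeration, exhaustive pairwise comparison) and share no code with
# the implementation paths they check.

# Brute-force semantic contributions: a node's contribution is the maximum
# over all directed paths from it down to one of the disease's own terms of
# delta^length, found by enumerating every path.
oracle_contributions <- function(dag, delta = 0.5) {
  children_of <- function(v) dag$edges[dag$edges[, 1] == v, 2]
  walk <- function(v, depth, visited) {
    # reaching an own term at this depth realises delta^depth; going deeper
    # only shrinks the value, so the path can stop here
    if (v %in% dag$terms) return(delta^depth)
    vals <- c()
    for (ch in children_of(v)) {
      if (ch %in% visited) stop("cycle")
      vals <- c(vals, walk(ch, depth + 1, c(visited, ch)))
    }
    if (!length(vals)) return(NA_real_)
    max(vals, na.rm = TRUE)
  }
  out <- vapply(dag$nodes, function(v) {
    if (v %in% dag$terms) 1 else walk(v, 0, v)
  }, 0)
  out[!is.na(out)]
}

oracle_semantic_similarity <- function(dag_i, dag_j, delta = 0.5) {
  ci <- oracle_contributions(dag_i, delta)
  cj <- oracle_contributions(dag_j, delta)
  shared <- intersect(names(ci), names(cj))
  sum(ci[shared] + cj[shared]) / (sum(ci) + sum(cj))
}

# Exhaustive pairwise AUC: P(positive outscores negative), ties half.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (n in sn) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(sp) * length(sn))
}

# Random DAG over a shared node pool: edges only go from lower-index pool
# nodes to higher (acyclic by construction), every non-root node gets at
# least one parent, own terms are the sinks.
random_pool_dag <- function(n_nodes, pool = paste0("T", sprintf("%02d", 1:15))) {
  nodes <- sort(sample(pool, n_nodes))
  edges <- NULL
  if (n_nodes > 1) {
    for (j in 2:n_nodes) {
      parents <- sample(seq_len(j - 1), size = sample(1:min(2, j - 1), 1))
      edges <- rbind(edges, cbind(nodes[parents], nodes[j]))
    }
  }
  has_child <- nodes %in% edges[, 1]
  terms <- if (is.null(edges)) nodes else nodes[!has_child]
  disease_dag(paste0("d-", paste(range(nodes), collapse = "")),
              terms = terms, nodes = nodes, edges = edges)
}

# Small random bipartite test graph + features for GAT checks.
random_gat_case <- function(n_left = 4, n_right = 5, f = 6, p_edge = 0.5) {
  n <- n_left + n_right
  em <- which(matrix(runif(n_left * n_right) < p_edge, n_left) == TRUE,
              arr.ind = TRUE)
  edges <- if (nrow(em)) cbind(em[, 1], n_left + em[, 2]) else NULL
  list(X = matrix(rnorm(n * f), n, f),
       graph = gat_graph(edges, n), n = n, f = f)
}

# Reduced-size control so unit tests stay fast; scientific structure (two
# GAT layers, concat+average combine, three FC layers) is preserved.
small_control <- function(...) {
  defaults <- list(feature_size = 16, gat_heads = 4, fc_hidden = c(16, 8),
                   walks_per_node = 4, walk_length = 8, epochs = 60,
                   patience = 60)
  do.call(hgmda_control, utils::modifyList(defaults, list(...)))
}

small_sim <- function(seed = 5, n = 20) {
  simulate_mda(n_mirna = n, n_disease = n, n_blocks = 2, seed = seed)
}
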