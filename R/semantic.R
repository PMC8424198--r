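#' Semantic contributions of DAG terms to a disease
#'
#' Computes, for every term in a disease's MeSH ancestor DAG, its semantic
#' contribution to the disease: the disease's own terms contribute exactly
#' 1, and any ancestor term contributes `delta` times the largest
#' contribution among its children within the DAG, i.e. contributions decay
#' geometrically with the distance to the closest own term. The semantic
#' value of the disease is the sum of all contributions. Computed in one
#' reverse-topological pass (children before parents), O(|E|).
#'
#' @param dag a [disease_dag()] object.
#' @param delta decay factor per generation, in `(0, 1]`; default 0.5.
#' @return list with `disease`, `contributions` (named numeric, all in
#'   `(0, 1]`) and `semantic_value` (their sum).
#' @export
#' @examples
#' d <- disease_dag("x", terms = "C04.557", nodes = c("C04", "C04.557"),
#'                  edges = cbind("C04", "C04.557"))
#' semantic_contributions(d)
semantic_contributions <- function(dag, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"), delta > 0, delta <= 1)
  ord <- dag_topological_order(dag)    # errors on cycles
  contrib <- stats::setNames(rep(NA_real_, length(dag$nodes)), dag$nodes)
  contrib[dag$terms] <- 1
  children <- split(dag$edges[, 2], factor(dag$edges[, 1], levels = dag$nodes))
  for (v in rev(ord)) {                # children before parents
    if (!is.na(contrib[v]) && contrib[v] == 1) next   # own term dominates
    ch <- children[[v]]
    if (length(ch)) {
      cc <- contrib[ch]
      cc <- cc[!is.na(cc)]
      if (length(cc)) contrib[v] <- delta * max(cc)
    }
  }
  # nodes with no descending path to an own term carry no contribution
  contrib <- contrib[!is.na(contrib)]
  list(disease = dag$disease,
       contributions = contrib,
       semantic_value = sum(contrib))
}

#' Disease semantic similarity from MeSH DAG overlap
#'
#' Two diseases are similar in proportion to the overlap of their ancestor
#' DAGs: the similarity is the sum, over shared terms, of both diseases'
#' semantic contributions to that term, divided by the sum of the two
#' semantic values. Self-similarity is 1 and the matrix is symmetric with
#' entries in `[0, 1]`.
#'
#' @param dags named list of [disease_dag()] objects (one per disease).
#' @param delta decay factor per generation, default 0.5.
#' @return symmetric similarity matrix with unit diagonal, ordered like
#'   `names(dags)`.
#' @export
semantic_similarity <- function(dags, delta = 0.5) {
  stopifnot(is.list(dags), length(dags) >= 1, !is.null(names(dags)))
  sc <- lapply(dags, semantic_contributions, delta = delta)
  terms <- lex_sort(unlist(lapply(sc, function(s) names(s$contributions)),
                           use.names = FALSE))
  nd <- length(dags)
  C <- matrix(0, length(terms), nd, dimnames = list(terms, names(dags)))
  for (j in seq_len(nd)) {
    C[names(sc[[j]]$contributions), j] <- sc[[j]]$contributions
  }
  dv <- vapply(sc, `[[`, 0, "semantic_value")
  B <- (C > 0) * 1
  # num[i, j] = sum over shared terms t of (C[t,i] + C[t,j])
  num <- crossprod(C, B) + crossprod(B, C)
  SS <- num / outer(dv, dv, "+")
  diag(SS) <- 1
  dimnames(SS) <- list(names(dags), names(dags))
  SS
}
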