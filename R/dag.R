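#' Construct a disease DAG object
#'
#' A disease DAG is the ancestor graph of a disease in the MeSH hierarchy:
#' nodes are tree-number strings (plus, for diseases without any tree
#' number, the disease's own name), edges point from parent to child
#' (one-segment extension of the parent's tree number). `terms` are the
#' disease's own tree numbers — the nodes whose semantic contribution is
#' exactly 1.
#'
#' @param disease canonical disease name.
#' @param terms character vector of the disease's own term identifiers.
#' @param nodes character vector of all node identifiers (must contain
#'   `terms`).
#' @param edges two-column character matrix of `(parent, child)` pairs;
#'   may have zero rows.
#' @return an object of class `disease_dag`.
#' @export
disease_dag <- function(disease, terms, nodes, edges) {
  nodes <- unique(as.character(nodes))
  terms <- unique(as.character(terms))
  if (!length(terms)) stop("disease_dag needs at least one own term")
  if (!all(terms %in% nodes)) stop("own terms must be nodes of the DAG")
  if (is.null(edges) || !length(edges)) {
    edges <- matrix(character(0), 0, 2)
  } else {
    edges <- matrix(as.character(edges), ncol = 2)
    edges <- unique(edges)
    if (!all(edges %in% nodes)) stop("every edge endpoint must be a DAG node")
  }
  colnames(edges) <- c("parent", "child")
  structure(list(disease = disease, terms = terms, nodes = nodes,
                 edges = edges),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("Disease DAG for '", x$disease, "': ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges, ", length(x$terms), " own term(s)\n", sep = "")
  invisible(x)
}

# All dot-prefixes of a tree number: "C04.557.337" ->
# c("C04", "C04.557", "C04.557.337")
tree_number_prefixes <- function(tn) {
  segs <- strsplit(tn, ".", fixed = TRUE)[[1]]
  vapply(seq_along(segs), function(k) paste(segs[seq_len(k)], collapse = "."), "")
}

#' Build disease DAGs from MeSH tree numbers
#'
#' For every disease, the DAG nodes are its tree numbers plus every
#' dot-prefix ancestor, and edges connect each prefix to its one-segment
#' extension; multiple tree numbers of one disease merge into a single DAG.
#' Node identity is the tree-number string, so two diseases share DAG
#' nodes exactly when their tree-number sets share prefixes. A disease with
#' no tree number (empty/`NA` field, or listed in `diseases` but absent
#' from the table) gets a single-node DAG containing only its own name,
#' with a warning.
#'
#' @param tree_table data.frame with columns `disease` and `tree_number`
#'   (one tree number per row), e.g. from [read_tree_numbers()].
#' @param diseases optional character vector of diseases that must all be
#'   present in the result (missing ones get single-node DAGs).
#' @return named list of [disease_dag()] objects, lexicographically sorted
#'   by canonical disease name.
#' @export
#' @examples
#' tt <- data.frame(disease = c("lung neoplasms", "lung neoplasms"),
#'                  tree_number = c("C04.588.894", "C08.785"))
#' dags <- build_disease_dags(tt)
#' dags[["lung neoplasms"]]
build_disease_dags <- function(tree_table, diseases = NULL) {
  stopifnot(is.data.frame(tree_table),
            all(c("disease", "tree_number") %in% names(tree_table)))
  dn <- canonicalize_names(tree_table$disease)
  tn <- toupper(trimws(as.character(tree_table$tree_number)))
  tn[!nzchar(tn) | is.na(tn)] <- NA_character_
  bad <- !is.na(tn) & !grepl("^[A-Z0-9]+(\\.[A-Z0-9]+)*$", tn)
  if (any(bad))
    stop("malformed tree number(s): ", paste(unique(tn[bad])[1:min(3, sum(bad))],
                                             collapse = ", "))
  all_dis <- lex_sort(c(dn, if (!is.null(diseases)) canonicalize_names(diseases)))
  no_tn <- character(0)
  dags <- lapply(all_dis, function(d) {
    tns <- unique(tn[dn == d & !is.na(tn)])
    if (!length(tns)) {
      no_tn <<- c(no_tn, d)
      return(disease_dag(d, terms = d, nodes = d, edges = NULL))
    }
    pref <- lapply(tns, tree_number_prefixes)
    nodes <- unique(unlist(pref))
    edges <- do.call(rbind, lapply(pref, function(p) {
      if (length(p) < 2) return(NULL)
      cbind(p[-length(p)], p[-1])
    }))
    disease_dag(d, terms = tns, nodes = nodes, edges = edges)
  })
  names(dags) <- all_dis
  if (length(no_tn))
    warning("disease(s) without tree numbers kept as single-node DAGs: ",
            paste(no_tn, collapse = ", "))
  dags
}

# Topological order of a disease_dag (parents before children).
# Errors on cycles; used both for validation and the semantic DP.
dag_topological_order <- function(dag) {
  nodes <- dag$nodes
  n <- length(nodes)
  if (!nrow(dag$edges)) return(nodes)
  pi <- match(dag$edges[, 1], nodes)
  ci <- match(dag$edges[, 2], nodes)
  indeg <- tabulate(ci, nbins = n)
  out <- split(ci, factor(pi, levels = seq_len(n)))
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (w in out[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) != n) stop("cycle detected in DAG for '", dag$disease, "'")
  nodes[ord]
}
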