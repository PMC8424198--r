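#' Random-walk transition model from a similarity matrix
#'
#' Converts a similarity matrix into a row-stochastic transition matrix for
#' similarity-weighted random walks: the diagonal is zeroed (a walk always
#' moves to another vertex — a self-loop contributes no skip-gram context)
#' and each row is normalized to sum to 1, so row `i` is a categorical
#' distribution proportional to the similarity weights of `i`'s neighbours.
#'
#' @param S square symmetric similarity matrix with nonnegative entries.
#' @return row-stochastic matrix with zero diagonal.
#' @export
transition_matrix <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (any(S < 0)) stop("similarity weights must be nonnegative")
  P <- S
  diag(P) <- 0
  rs <- rowSums(P)
  if (any(rs == 0)) {
    bad <- which(rs == 0)
    stop("isolated node(s) in similarity graph (all-zero off-diagonal row): ",
         paste(if (!is.null(rownames(S))) rownames(S)[bad] else bad,
               collapse = ", "))
  }
  P / rs
}

#' Sample similarity-weighted random walks
#'
#' Starts `walks_per_node` walks at every node and extends each to
#' `walk_length` nodes, drawing every step from the current node's
#' transition distribution. The walk corpus plays the role of sentences for
#' skip-gram embedding training.
#'
#' @param P row-stochastic transition matrix from [transition_matrix()].
#' @param walks_per_node number of walks started at each node (default 10).
#' @param walk_length nodes per walk (default 20, minimum 2).
#' @param seed optional integer seed; a given seed fully determines the
#'   corpus.
#' @return object of class `walk_corpus`: list with `walks` (list of
#'   integer node-index vectors), `names`, `walk_length`, `walks_per_node`,
#'   `seed`.
#' @export
sample_walks <- function(P, walks_per_node = 10, walk_length = 20, seed = NULL) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (walk_length < 2) stop("walk_length must be at least 2")
  if (walks_per_node < 1) stop("walks_per_node must be positive")
  if (max(abs(rowSums(P) - 1)) > 1e-9) stop("transition matrix rows must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(P)
  walks <- vector("list", n * walks_per_node)
  k <- 0L
  for (v in seq_len(n)) {
    for (w in seq_len(walks_per_node)) {
      walk <- integer(walk_length)
      walk[1] <- v
      for (t in 2:walk_length) {
        walk[t] <- sample.int(n, 1L, prob = P[walk[t - 1L], ])
      }
      k <- k + 1L
      walks[[k]] <- walk
    }
  }
  structure(list(walks = walks,
                 names = if (!is.null(rownames(P))) rownames(P) else as.character(seq_len(n)),
                 walk_length = walk_length,
                 walks_per_node = walks_per_node,
                 seed = seed),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat("Walk corpus: ", length(x$walks), " walks of length ", x$walk_length,
      " over ", length(x$names), " nodes (", x$walks_per_node,
      " per start node)\n", sep = "")
  invisible(x)
}

#' Write / read a walk corpus as plain text
#'
#' One walk per line, space-separated node names.
#'
#' @param corpus a `walk_corpus` object.
#' @param path file path.
#' @return `path` (write) or a `walk_corpus` (read; `seed` is `NA` because
#'   the file does not record it).
#' @export
write_walks <- function(corpus, path) {
  stopifnot(inherits(corpus, "walk_corpus"))
  lines <- vapply(corpus$walks,
                  function(w) paste(corpus$names[w], collapse = " "), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_walks
#' @export
read_walks <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty walk file: ", path)
  toks <- strsplit(trimws(lines), " ", fixed = TRUE)
  nms <- lex_sort(unlist(toks, use.names = FALSE))
  walks <- lapply(toks, match, nms)
  wl <- unique(lengths(walks))
  if (length(wl) != 1L) stop("walks of unequal length in ", path)
  structure(list(walks = walks, names = nms, walk_length = wl,
                 walks_per_node = length(walks) %/% length(nms), seed = NA),
            class = "walk_corpus")
}
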