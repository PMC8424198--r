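#' Learn node embeddings from a walk corpus
#'
#' Trains a skip-gram model with hierarchical softmax over the walk corpus,
#' treating walks as sentences and nodes as words, and returns one
#' `feature_size`-dimensional vector per node. Training is single-threaded
#' and fully deterministic given the corpus and `seed`. No node is dropped:
#' the minimum count is 1 and every node is required to appear in the
#' corpus.
#'
#' @param corpus a `walk_corpus` from [sample_walks()] (or [read_walks()]).
#' @param feature_size embedding dimension F (default 64).
#' @param window skip-gram context window (default 5).
#' @param epochs training passes over the corpus (default 5).
#' @param alpha initial learning rate with linear decay (default 0.025).
#' @param seed integer seed for initialization and window subsampling.
#' @return numeric matrix of shape `n_nodes x feature_size` with node names
#'   as row names.
#' @export
embed_nodes <- function(corpus, feature_size = 64, window = 5, epochs = 5,
                        alpha = 0.025, seed = 1) {
  stopifnot(inherits(corpus, "walk_corpus"))
  n <- length(corpus$names)
  seen <- unique(unlist(corpus$walks, use.names = FALSE))
  if (!all(seq_len(n) %in% seen))
    stop("node(s) absent from the walk corpus: ",
         paste(corpus$names[setdiff(seq_len(n), seen)], collapse = ", "))
  E <- .sg_hs_train(corpus$walks, n, as.integer(feature_size),
                    as.integer(window), as.integer(epochs),
                    as.numeric(alpha), as.integer(seed))
  if (any(!is.finite(E))) stop("non-finite embedding values; lower alpha")
  rownames(E) <- corpus$names
  E
}

#' Write / read node embeddings in word2vec text format
#'
#' First line `n_nodes feature_size`, then one line per node: name followed
#' by the embedding values, space-separated.
#'
#' @param E embedding matrix with row names.
#' @param path file path.
#' @return `path` (write) or the embedding matrix (read).
#' @export
write_embeddings <- function(E, path) {
  stopifnot(is.matrix(E), !is.null(rownames(E)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(E), ncol(E)), con)
  for (i in seq_len(nrow(E))) {
    writeLines(paste(c(rownames(E)[i],
                       format(E[i, ], digits = 17, scientific = TRUE, trim = TRUE)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), " ")[[1]])
  body <- strsplit(trimws(lines[-1]), " ", fixed = TRUE)
  body <- body[lengths(body) > 0]
  if (length(body) != hdr[1]) stop("embedding file row count mismatch")
  E <- do.call(rbind, lapply(body, function(f) as.numeric(f[-1])))
  if (ncol(E) != hdr[2]) stop("embedding file dimension mismatch")
  rownames(E) <- vapply(body, `[`, "", 1L)
  E
}
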