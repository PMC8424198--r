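#' Canonicalize entity names
#'
#' Lowercases, trims leading/trailing whitespace and collapses internal
#' whitespace runs to a single space. Database dialects (HMDD v2.0 vs v3.2,
#' MeSH exports) differ in case and spacing; all name matching in this
#' package happens on canonical forms.
#'
#' @param x character vector of raw names.
#' @return character vector of canonical names.
#' @export
#' @examples
#' canonicalize_names(c("  Breast   Neoplasms ", "hsa-miR-21"))
canonicalize_names <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Deterministic, locale-independent sort used for all index orders.
lex_sort <- function(x) sort(unique(x), method = "radix")

# Read a two-column tab-separated file, skipping blank lines, erroring on
# malformed rows with the offending line number. An optional header row is
# recognised when its canonical fields equal `header`.
read_two_col <- function(path, header = NULL, what = "pair") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty file: ", path)
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed %s row at line %d of '%s': expected 2 tab-separated columns, got %d",
                 what, idx[bad[1]], path, lengths(parts)[bad[1]]))
  }
  m <- do.call(rbind, parts)
  if (!is.null(header) && nrow(m) >= 1 &&
      identical(canonicalize_names(m[1, ]), header)) {
    m <- m[-1, , drop = FALSE]
    if (nrow(m) == 0) stop("file contains only a header: ", path)
  }
  m
}

#' Read a miRNA-disease association pair list
#'
#' Reads a tab-separated pair list (one `miRNA<TAB>disease` row per known
#' association, optional `mirna  disease` header) and builds the binary
#' association matrix with miRNAs as rows and diseases as columns. Names
#' are canonicalized (see [canonicalize_names()]) and both axes are sorted
#' lexicographically so the matrix is independent of file row order.
#' Duplicate pairs collapse to a single entry.
#'
#' @param path path to the TSV pair list (UTF-8).
#' @param name_map optional named character vector mapping source names to
#'   target names (applied to both miRNA and disease names after
#'   canonicalization; unmapped names pass through unchanged). Use this to
#'   reconcile database dialects, e.g. HMDD v3.2 terms onto v2.0 terms.
#' @return integer 0/1 matrix of dimension `n_mirna x n_disease` with
#'   dimnames.
#' @export
read_association_pairs <- function(path, name_map = NULL) {
  m <- read_two_col(path, header = c("mirna", "disease"), what = "association")
  mir <- apply_name_map(canonicalize_names(m[, 1]), name_map)
  dis <- apply_name_map(canonicalize_names(m[, 2]), name_map)
  make_assoc_matrix(mir, dis)
}

apply_name_map <- function(x, name_map) {
  if (is.null(name_map)) return(x)
  if (is.null(names(name_map))) stop("name_map must be a named character vector")
  keys <- canonicalize_names(names(name_map))
  vals <- canonicalize_names(unname(name_map))
  hit <- match(x, keys)
  x[!is.na(hit)] <- vals[hit[!is.na(hit)]]
  x
}

make_assoc_matrix <- function(mir, dis) {
  mirnas <- lex_sort(mir)
  diseases <- lex_sort(dis)
  A <- matrix(0L, length(mirnas), length(diseases),
              dimnames = list(mirnas, diseases))
  A[cbind(match(mir, mirnas), match(dis, diseases))] <- 1L
  validate_assoc(A)
  A
}

validate_assoc <- function(A) {
  if (!is.matrix(A)) stop("association matrix must be a matrix")
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("association matrix must carry miRNA row names and disease column names")
  if (anyDuplicated(rownames(A)) || anyDuplicated(colnames(A)))
    stop("association matrix names must be unique")
  if (!all(A %in% c(0L, 1L))) stop("association matrix entries must be 0 or 1")
  if (sum(A) < 1) stop("association matrix has no known associations")
  invisible(A)
}

#' Write an association matrix back to a pair list
#'
#' Inverse of [read_association_pairs()]: writes one `miRNA<TAB>disease`
#' row per nonzero entry, sorted, with a header.
#'
#' @param A binary association matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_association_pairs <- function(A, path) {
  validate_assoc(A)
  nz <- which(A == 1L, arr.ind = TRUE)
  df <- data.frame(mirna = rownames(A)[nz[, 1]],
                   disease = colnames(A)[nz[, 2]])
  df <- df[order(df$mirna, df$disease, method = "radix"), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("mirna", "disease"), fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a dense similarity matrix
#'
#' Reads a whitespace- or tab-delimited dense square matrix, with optional
#' first-row and/or first-column labels. The result is symmetrized by
#' averaging when asymmetry exceeds `1e-8`, the diagonal is forced to 1 and
#' values are clipped to `[0, 1]` (with a warning when clipping changes
#' anything beyond rounding noise).
#'
#' @param path path to the matrix file.
#' @param names optional ordered character vector of entity names. When the
#'   file carries labels the matrix is reordered to `names`; when it does
#'   not, `names` is assigned. A dimension or label mismatch is an error.
#' @return symmetric numeric matrix with unit diagonal, entries in `[0, 1]`.
#' @export
read_similarity_matrix <- function(path, names = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  is_num <- function(v) !anyNA(suppressWarnings(as.numeric(v)))
  has_col_labels <- !is_num(fields[[1]])
  body <- if (has_col_labels) fields[-1] else fields
  if (!length(body)) stop("similarity matrix file has a header but no rows: ", path)
  has_row_labels <- !is_num(vapply(body, `[`, "", 1L))
  row_labels <- if (has_row_labels) canonicalize_names(vapply(body, `[`, "", 1L)) else NULL
  vals <- lapply(body, function(f) {
    suppressWarnings(as.numeric(if (has_row_labels) f[-1] else f))
  })
  if (length(unique(lengths(vals))) != 1L)
    stop("ragged similarity matrix in ", path)
  S <- do.call(rbind, vals)
  if (anyNA(S)) stop("non-numeric entries in similarity matrix ", path)
  if (nrow(S) != ncol(S)) stop("similarity matrix is not square: ",
                               nrow(S), " x ", ncol(S))
  col_labels <- NULL
  if (has_col_labels) {
    cl <- canonicalize_names(fields[[1]])
    if (length(cl) == ncol(S) + 1L) cl <- cl[-1]  # corner label present
    if (length(cl) != ncol(S)) stop("column label count does not match matrix width")
    col_labels <- cl
  }
  lab <- if (!is.null(row_labels)) row_labels else col_labels
  if (!is.null(lab)) dimnames(S) <- list(lab, if (!is.null(col_labels)) col_labels else lab)
  if (!is.null(names)) {
    names <- canonicalize_names(names)
    if (length(names) != nrow(S))
      stop("similarity matrix dimension ", nrow(S),
           " does not match ", length(names), " names")
    if (!is.null(lab)) {
      ord <- match(names, rownames(S))
      if (anyNA(ord)) stop("similarity matrix labels do not cover requested names: ",
                           paste(names[is.na(ord)][seq_len(min(3, sum(is.na(ord))))],
                                 collapse = ", "))
      S <- S[ord, ord, drop = FALSE]
    }
    dimnames(S) <- list(names, names)
  }
  sanitize_similarity(S)
}

# Symmetrize (average), force unit diagonal, clip to [0,1].
sanitize_similarity <- function(S, warn_clip = TRUE) {
  S <- (S + t(S)) / 2  # exact no-op when already symmetric within 1e-8
  diag(S) <- 1
  lo <- S < 0; hi <- S > 1
  if (any(lo) || any(hi)) {
    if (warn_clip && (any(S[lo] < -1e-8) || any(S[hi] > 1 + 1e-8)))
      warning(sum(lo) + sum(hi), " similarity entries clipped to [0, 1]")
    S[lo] <- 0; S[hi] <- 1
  }
  S
}

#' Write a similarity matrix as labelled TSV
#'
#' @param S square numeric matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(S, path) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), !is.null(rownames(S)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(colnames(S), collapse = "\t"), con)
  for (i in seq_len(nrow(S))) {
    writeLines(paste(c(rownames(S)[i],
                       format(S[i, ], digits = 17, scientific = FALSE, trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a disease-to-MeSH-tree-number table
#'
#' Reads a TSV with columns `disease` and `tree_number` (one tree number
#' per row; a disease may span multiple rows; optional header). Disease
#' names are canonicalized. Rows whose tree-number field is empty are kept
#' with `NA` so [build_disease_dags()] can emit single-node DAGs for them.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `disease`, `tree_number`.
#' @export
read_tree_numbers <- function(path) {
  m <- read_two_col(path, header = c("disease", "tree_number"), what = "tree-number")
  tn <- trimws(m[, 2])
  tn[!nzchar(tn)] <- NA_character_
  data.frame(disease = canonicalize_names(m[, 1]),
             tree_number = toupper(tn),
             stringsAsFactors = FALSE)
}
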