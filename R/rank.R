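#' Rank candidate miRNAs for a disease
#'
#' Scores every miRNA without a known association to the disease in the
#' training matrix (known positives are excluded), sorts by decreasing
#' score with lexicographic miRNA-name tie-breaking, and returns the top
#' candidates.
#'
#' @param object a fitted [hgmda()] model.
#' @param disease disease name (canonicalized before matching).
#' @param top_k number of candidates to keep (default 50).
#' @return data.frame of class `hgmda_ranking` with columns `rank`,
#'   `mirna`, `score`; the disease is kept in attribute `"disease"`.
#' @export
rank_candidates <- function(object, disease, top_k = 50) {
  stopifnot(inherits(object, "hgmda"))
  d <- canonicalize_names(disease)
  j <- match(d, object$diseases)
  if (is.na(j)) {
    near <- agrep(d, object$diseases, max.distance = 0.3, value = TRUE)
    stop("unknown disease '", disease, "'",
         if (length(near)) paste0("; nearest matches: ",
                                  paste(head(near, 5), collapse = ", "))
         else "")
  }
  cand <- which(object$assoc[, j] == 0L)
  if (!length(cand)) stop("no candidate miRNAs: all are known positives")
  scores <- score_pairs_idx(object, rep(j, length(cand)), cand)
  ord <- order(-scores, object$mirnas[cand], method = "radix")
  keep <- head(ord, top_k)
  out <- data.frame(rank = seq_along(keep),
                    mirna = object$mirnas[cand][keep],
                    score = scores[keep])
  attr(out, "disease") <- object$diseases[j]
  class(out) <- c("hgmda_ranking", "data.frame")
  out
}

#' Check a ranked candidate list against validation pair lists
#'
#' Generic case-study verification: marks each ranked candidate as
#' confirmed when the (miRNA, disease) pair appears in any of the supplied
#' reference association lists (e.g. exports of later database releases).
#'
#' @param ranking an `hgmda_ranking` from [rank_candidates()].
#' @param references named list; each element is either a data.frame with
#'   columns `mirna` and `disease` or a path to a TSV pair list readable by
#'   [read_association_pairs()]'s format.
#' @return the ranking with an added `evidence` column (semicolon-separated
#'   reference names, `""` if unconfirmed) and logical `confirmed`.
#' @export
verify_candidates <- function(ranking, references) {
  stopifnot(inherits(ranking, "hgmda_ranking"), is.list(references),
            !is.null(names(references)))
  disease <- attr(ranking, "disease")
  hit_sets <- lapply(references, function(ref) {
    if (is.character(ref)) {
      m <- read_two_col(ref, header = c("mirna", "disease"), what = "association")
      ref <- data.frame(mirna = m[, 1], disease = m[, 2])
    }
    keep <- canonicalize_names(ref$disease) == disease
    unique(canonicalize_names(ref$mirna[keep]))
  })
  ev <- vapply(ranking$mirna, function(m) {
    paste(names(references)[vapply(hit_sets, function(s) m %in% s, TRUE)],
          collapse = ";")
  }, "")
  ranking$evidence <- unname(ev)
  ranking$confirmed <- nzchar(ranking$evidence)
  ranking
}

#' @export
print.hgmda_ranking <- function(x, ...) {
  cat("Top", nrow(x), "candidate miRNAs for '", attr(x, "disease"), "'\n")
  NextMethod()
}
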