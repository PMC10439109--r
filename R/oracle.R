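#' Precise alignment-based cosine of two spectra
#'
#' The loop-based reference scorer that blur-and-link scoring approximates:
#' all fragment pairs within the tolerance (inclusive) are enumerated, sorted
#' by intensity product descending (ties broken by smaller m/z difference,
#' then lower fragment index in `a`, then in `b`), and accepted greedily with
#' each fragment used at most once. The score is the sum of accepted
#' intensity products — the cosine similarity when both spectra are
#' unit-normalized — and the match count is the number of accepted pairs.
#'
#' Spectra must have been preprocessed identically to the blur-and-link path
#' (filter, square root, unit normalization); this function does not
#' renormalize. When validating blur-and-link results at tolerance `t` and
#' bin width `w`, run the precise scorer at `t - w`, the guaranteed linking
#' tolerance of the kernel.
#'
#' @param a,b [ms_spectrum()] objects, unit-normalized.
#' @param tolerance alignment tolerance in Da.
#' @return A list with `score` (in `[0, 1]` for unit-normalized inputs) and
#'   `matches` (integer). An empty spectrum scores 0 with 0 matches.
#' @examples
#' a <- ms_spectrum(c(100, 200), c(0.6, 0.8), 300)
#' b <- ms_spectrum(100.004, 1.0, 300)
#' aligned_cosine(a, b, tolerance = 0.009)  # score 0.6, 1 match
#' @export
aligned_cosine <- function(a, b, tolerance) {
  stopifnot(inherits(a, "ms_spectrum"), inherits(b, "ms_spectrum"),
            is.numeric(tolerance), tolerance >= 0)
  r <- greedy_cosine_all_cpp(list(a$mz), list(a$intensity),
                             list(b$mz), list(b$intensity), tolerance)
  list(score = r$scores[1, 1], matches = r$matches[1, 1])
}

#' Precise alignment-based cosine for all spectrum pairs
#'
#' Runs [aligned_cosine()] over every query x reference pair. This is the
#' ground-truth comparator for blur-and-link scoring in tests, and the
#' engine behind [rescore_hits()].
#'
#' @param query,ref preprocessed [spectrum_set()] objects.
#' @param tolerance alignment tolerance in Da.
#' @return A `score_result` with exact scores and match counts.
#' @export
oracle_score_all <- function(query, ref, tolerance) {
  stopifnot(inherits(query, "spectrum_set"), inherits(ref, "spectrum_set"))
  r <- greedy_cosine_all_cpp(
    lapply(query$spectra, `[[`, "mz"),
    lapply(query$spectra, `[[`, "intensity"),
    lapply(ref$spectra, `[[`, "mz"),
    lapply(ref$spectra, `[[`, "intensity"),
    tolerance)
  structure(
    list(scores = r$scores, matches = r$matches,
         params = list(bin_width = NA_real_, tolerance = tolerance,
                       shift = "none", delta = 0),
         query_ids = spectrum_ids(query), ref_ids = spectrum_ids(ref)),
    class = "score_result")
}

#' Re-score blur-and-link hits with the precise aligned cosine
#'
#' A fast way to get full agreement with conventional loop-based scoring is
#' to run blur-and-link over all pairs and then recalculate only the top hits
#' precisely. Each hit is re-scored with [aligned_cosine()], re-filtered at
#' the same thresholds, and the surviving hits are returned sorted by
#' descending precise score.
#'
#' @param hits a data.frame with columns `query_id` and `ref_id` (for example
#'   from [score_hits()]); any `score`/`matches` columns are kept as
#'   `blink_score`/`blink_matches`.
#' @param query,ref preprocessed [spectrum_set()] objects containing the ids
#'   referenced by `hits`.
#' @param tolerance precise alignment tolerance in Da (use the blur-and-link
#'   tolerance minus the bin width when re-scoring default runs).
#' @param min_score,min_matches thresholds re-applied to the precise values.
#' @return A data.frame with columns `query_id`, `ref_id`, `score`,
#'   `matches` (precise values), plus `blink_score`/`blink_matches` when
#'   present in the input, sorted by descending precise score.
#' @export
rescore_hits <- function(hits, query, ref, tolerance,
                         min_score = 0.7, min_matches = 6) {
  stopifnot(is.data.frame(hits),
            all(c("query_id", "ref_id") %in% names(hits)),
            inherits(query, "spectrum_set"), inherits(ref, "spectrum_set"))
  if (!nrow(hits)) {
    out <- data.frame(query_id = character(0), ref_id = character(0),
                      score = numeric(0), matches = integer(0))
    return(out)
  }
  qi <- match(hits$query_id, spectrum_ids(query))
  ri <- match(hits$ref_id, spectrum_ids(ref))
  if (anyNA(qi))
    stop("unknown query id(s): ",
         paste(unique(hits$query_id[is.na(qi)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(ri))
    stop("unknown reference id(s): ",
         paste(unique(hits$ref_id[is.na(ri)]), collapse = ", "),
         call. = FALSE)
  prec <- mapply(function(i, j) {
    r <- aligned_cosine(query$spectra[[i]], ref$spectra[[j]], tolerance)
    c(r$score, r$matches)
  }, qi, ri)
  out <- data.frame(query_id = hits$query_id, ref_id = hits$ref_id,
                    score = prec[1, ], matches = as.integer(prec[2, ]),
                    stringsAsFactors = FALSE)
  if ("score" %in% names(hits)) out$blink_score <- hits$score
  if ("matches" %in% names(hits)) out$blink_matches <- hits$matches
  out <- out[out$score >= min_score & out$matches >= min_matches, ,
             drop = FALSE]
  out <- out[order(-out$score, out$query_id, out$ref_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
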