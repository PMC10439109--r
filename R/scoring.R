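#' Score all spectrum pairs by sparse matrix multiplication
#'
#' The blurred side's intensity matrix is transposed and multiplied against
#' the unblurred side's: because intensities are unit-normalized, entry
#' `(i, j)` of the product is the blur-and-link cosine score of query `i`
#' against reference `j`. The same product on the fragment-count matrices
#' yields the (approximate) matching-ion counts; these are integral in exact
#' arithmetic and are rounded to the nearest integer to guard float drift.
#'
#' Exactly one of the two inputs must be blurred — blurring neither would
#' score with zero tolerance, blurring both would double it. Which side is
#' blurred does not change the result (the kernel matrix is symmetric), so
#' the cheaper convention is to blur the smaller set.
#'
#' @param query a `binned_spectra` for the query set (rows of the result).
#' @param ref a `binned_spectra` for the reference set (columns).
#' @return An object of class `score_result` with fields `scores` and
#'   `matches` (dense `n_query x n_ref` matrices), `params`, `query_ids`,
#'   `ref_ids`.
#' @export
score_all <- function(query, ref) {
  stopifnot(inherits(query, "binned_spectra"), inherits(ref, "binned_spectra"))
  if (abs(query$bin_width - ref$bin_width) > 1e-12 * ref$bin_width)
    stop("bin width mismatch between query (", query$bin_width,
         ") and reference (", ref$bin_width, ")", call. = FALSE)
  if (query$blurred == ref$blurred)
    stop("exactly one of query and reference must be blurred (got ",
         if (query$blurred) "both" else "neither", ")", call. = FALSE)
  if (!identical(query$shift, ref$shift))
    stop("shift mode mismatch between query and reference", call. = FALSE)

  universe <- sort(unique(c(query$bins, ref$bins)))
  Qi <- remap_bins(query$intensity, query$bins, universe)
  Ri <- remap_bins(ref$intensity, ref$bins, universe)
  Qc <- remap_bins(query$counts, query$bins, universe)
  Rc <- remap_bins(ref$counts, ref$bins, universe)

  scores <- as.matrix(Matrix::crossprod(Qi, Ri))
  matches <- round(as.matrix(Matrix::crossprod(Qc, Rc)))
  dimnames(scores) <- dimnames(matches) <- NULL
  tol <- if (query$blurred) query$tolerance else ref$tolerance
  structure(
    list(scores = scores, matches = matches,
         params = list(bin_width = query$bin_width, tolerance = tol,
                       shift = query$shift, delta = query$delta),
         query_ids = query$ids, ref_ids = ref$ids),
    class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf(
    "<score_result> %d query x %d reference (bin width %g Da, tolerance %g Da, shift %s)\n",
    nrow(x$scores), ncol(x$scores), x$params$bin_width, x$params$tolerance,
    x$params$shift))
  cat(sprintf("  max score %.4f, pairs with score >= 0.7 & matches >= 6: %d\n",
              max(x$scores), sum(x$scores >= 0.7 & x$matches >= 6)))
  invisible(x)
}

#' Classify spectrum pairs as similar
#'
#' A pair is similar when its cosine score and matching-ion count both reach
#' their thresholds; both comparisons are inclusive. The defaults, score >=
#' 0.7 with >= 6 matching ions, are the operating point commonly used for
#' spectral library matching.
#'
#' @param r a `score_result`.
#' @param min_score minimum cosine score (default 0.7).
#' @param min_matches minimum matching-ion count (default 6).
#' @return A logical `n_query x n_ref` matrix.
#' @export
classify_similar <- function(r, min_score = 0.7, min_matches = 6) {
  stopifnot(inherits(r, "score_result"))
  r$scores >= min_score & r$matches >= min_matches
}

#' Blur-and-link scoring of two preprocessed spectrum sets
#'
#' Convenience wrapper tying [discretize()], [make_kernel()], [blur()] and
#' [score_all()] together: both sets are discretized at the same bin width,
#' the side with fewer total fragments is blurred (the result is the same
#' either way; this is just cheaper), and all pairs are scored.
#'
#' @param query,ref preprocessed [spectrum_set()] objects.
#' @param bin_width bin width in Da (default 0.001).
#' @param tolerance linking tolerance in Da (default 0.01); must exceed
#'   `bin_width`.
#' @param shift,delta mass-shift mode passed to [discretize()].
#' @return A `score_result` (query rows, reference columns).
#' @examples
#' set.seed(1)
#' lib <- random_library(5, seed = 1)
#' pp <- preprocess_set(lib)
#' r <- blink_score(pp, pp)
#' diag(r$scores)  # self-scores are 1 for tolerance-separated spectra
#' @export
blink_score <- function(query, ref, bin_width = 0.001, tolerance = 0.01,
                        shift = c("none", "precursor", "fixed"), delta = 0) {
  shift <- match.arg(shift)
  k <- make_kernel(tolerance, bin_width)
  dq <- discretize(query, bin_width, shift, delta)
  dr <- discretize(ref, bin_width, shift, delta)
  if (sum(dq$counts) <= sum(dr$counts)) dq <- blur(dq, k) else dr <- blur(dr, k)
  score_all(dq, dr)
}

#' Analog search: regular, precursor-shifted, and combined scores
#'
#' Analog (neutral-loss) searching recovers structurally related compounds
#' whose fragments are offset by the difference in precursor mass. Spectra
#' are scored twice: once on the plain m/z coordinate and once on the neutral
#' loss coordinate `precursor_mz - mz`, where homologs with a constant mass
#' offset align exactly. The combined score of a pair is the element-wise
#' maximum of the two, and the combined match count is the count of whichever
#' term attained the maximum (ties go to the regular term). Both raw results
#' are returned as well, so any other combination rule can be applied
#' downstream.
#'
#' @inheritParams blink_score
#' @return A list with `score_result` elements `regular`, `shifted`,
#'   `combined`.
#' @export
analog_score_all <- function(query, ref, bin_width = 0.001, tolerance = 0.01) {
  stopifnot(inherits(query, "spectrum_set"), inherits(ref, "spectrum_set"))
  pre_ok <- function(set) all(vapply(set$spectra, function(s)
    is.finite(s$precursor_mz) && s$precursor_mz > 0, logical(1)))
  if (!pre_ok(query) || !pre_ok(ref))
    stop("every spectrum needs a precursor m/z for analog search",
         call. = FALSE)
  regular <- blink_score(query, ref, bin_width, tolerance, shift = "none")
  shifted <- blink_score(query, ref, bin_width, tolerance, shift = "precursor")
  take_shift <- shifted$scores > regular$scores
  combined <- regular
  combined$scores <- pmax(regular$scores, shifted$scores)
  combined$matches[take_shift] <- shifted$matches[take_shift]
  combined$params$shift <- "combined"
  list(regular = regular, shifted = shifted, combined = combined)
}
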