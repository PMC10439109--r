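#' Remove noise fragments from a spectrum
#'
#' Standard noise filtering before cosine scoring: drops fragments with zero
#' intensity, fragments above the precursor m/z, and fragments below a
#' fraction of the base peak. The base-peak threshold is computed on the
#' fragments that survive the zero/precursor filters, which makes the filter
#' idempotent. Comparisons follow the usual convention literally: a fragment
#' at exactly `base_peak_fraction` of the base peak is kept ("< 1 %" removes
#' strictly-below ions) and a fragment at exactly the precursor m/z is kept
#' ("greater than the precursor" removes strictly-above ions).
#'
#' @param s an [ms_spectrum()].
#' @param base_peak_fraction fragments with intensity below this fraction of
#'   the base peak are removed (default 0.01, i.e. 1 %).
#' @param remove_above_precursor drop fragments with m/z above the precursor.
#' @return A filtered `ms_spectrum`; possibly empty, in which case it is
#'   flagged with attribute `empty_after_filter` and a warning is raised
#'   (empty spectra must be excluded from scoring).
#' @export
filter_noise <- function(s, base_peak_fraction = 0.01,
                         remove_above_precursor = TRUE) {
  stopifnot(inherits(s, "ms_spectrum"))
  keep <- s$intensity > 0
  if (remove_above_precursor) keep <- keep & s$mz <= s$precursor_mz
  if (any(keep)) {
    base <- max(s$intensity[keep])
    keep <- keep & s$intensity >= base_peak_fraction * base
  }
  out <- ms_spectrum(s$mz[keep], s$intensity[keep], s$precursor_mz,
                     id = s$id, charge = s$charge)
  if (!length(out$mz)) {
    warning("spectrum '", s$id, "' is empty after noise filtering")
    attr(out, "empty_after_filter") <- TRUE
  }
  out
}

#' Square-root scale fragment intensities
#'
#' Square-root scaling compresses the dynamic range of fragment intensities
#' so the cosine score is not dominated by one or two intense ions.
#'
#' @param s an [ms_spectrum()].
#' @return The spectrum with each intensity replaced by its square root.
#' @export
sqrt_scale <- function(s) {
  stopifnot(inherits(s, "ms_spectrum"))
  ms_spectrum(s$mz, sqrt(s$intensity), s$precursor_mz,
              id = s$id, charge = s$charge)
}

#' Unit-vector normalize fragment intensities
#'
#' After normalization the Euclidean norm of the intensity vector is 1, so
#' the dot product of two aligned spectra is their cosine similarity. This
#' must be the last preprocessing step.
#'
#' @param s an [ms_spectrum()].
#' @return The spectrum with intensities scaled to unit Euclidean norm.
#' @export
unit_normalize <- function(s) {
  stopifnot(inherits(s, "ms_spectrum"))
  nrm <- sqrt(sum(s$intensity^2))
  if (!length(s$mz) || nrm == 0)
    stop("cannot unit-normalize spectrum '", s$id,
         "': all intensities are zero (run filter_noise first)", call. = FALSE)
  ms_spectrum(s$mz, s$intensity / nrm, s$precursor_mz,
              id = s$id, charge = s$charge)
}

#' Preprocess a spectrum set for scoring
#'
#' Applies the fixed pipeline filter -> square root -> unit normalization to
#' every spectrum. Normalization must come last or cosine scores are wrong.
#' Spectra left empty by filtering are dropped from the set (their ids are
#' reported in a warning) rather than scored as zero vectors.
#'
#' @param set a [spectrum_set()].
#' @param base_peak_fraction see [filter_noise()].
#' @param apply_sqrt apply square-root intensity scaling (default `TRUE`).
#' @param remove_above_precursor see [filter_noise()].
#' @return A preprocessed `spectrum_set`, possibly shorter than the input.
#' @export
preprocess_set <- function(set, base_peak_fraction = 0.01, apply_sqrt = TRUE,
                           remove_above_precursor = TRUE) {
  stopifnot(inherits(set, "spectrum_set"))
  out <- vector("list", length(set$spectra))
  dropped <- character(0)
  for (i in seq_along(set$spectra)) {
    s <- withCallingHandlers(
      filter_noise(set$spectra[[i]], base_peak_fraction,
                   remove_above_precursor),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!length(s$mz)) {
      dropped <- c(dropped, s$id)
      next
    }
    if (apply_sqrt) s <- sqrt_scale(s)
    out[[i]] <- unit_normalize(s)
  }
  if (length(dropped))
    warning("dropped ", length(dropped), " spectra empty after filtering: ",
            paste(dropped, collapse = ", "))
  spectrum_set(Filter(Negate(is.null), out), source = set$source,
               role = set$role)
}
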