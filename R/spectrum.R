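#' Construct a centroided MS/MS spectrum
#'
#' A spectrum is a list of fragment m/z values (Da) with matching intensities,
#' a precursor m/z, and a text identifier. Fragments are stored sorted by
#' ascending m/z; fragments at exactly identical m/z are merged by summing
#' their intensities, since downstream binning sums them anyway.
#'
#' @param mz numeric vector of fragment m/z values in Da, all > 0.
#' @param intensity numeric vector of non-negative intensities, same length
#'   as `mz`.
#' @param precursor_mz m/z of the precursor ion (Da), > 0.
#' @param id text identifier, unique within a [spectrum_set()].
#' @param charge integer precursor charge, or `NA` when unknown. Charge is
#'   carried as metadata only; no scoring step uses it.
#' @return An object of class `ms_spectrum`.
#' @examples
#' s <- ms_spectrum(c(150.1, 100.05), c(80, 20), precursor_mz = 301.14)
#' s$mz  # sorted ascending
#' @export
ms_spectrum <- function(mz, intensity, precursor_mz, id = "spectrum",
                        charge = NA_integer_) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length", call. = FALSE)
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("all fragment m/z values must be finite and > 0", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("all intensities must be finite and >= 0", call. = FALSE)
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L ||
      !is.finite(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be a single positive number", call. = FALSE)

  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
      mz <- unique(mz)
    }
  }
  structure(
    list(id = as.character(id), precursor_mz = as.numeric(precursor_mz),
         charge = as.integer(charge), mz = mz, intensity = intensity),
    class = "ms_spectrum"
  )
}

#' Number of fragments in a spectrum
#' @param s an `ms_spectrum`.
#' @return integer fragment count.
#' @export
n_fragments <- function(s) {
  stopifnot(inherits(s, "ms_spectrum"))
  length(s$mz)
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum> %s: %d fragments, precursor m/z %.4f%s\n",
              x$id, length(x$mz), x$precursor_mz,
              if (is.na(x$charge)) "" else sprintf(", charge %+d", x$charge)))
  invisible(x)
}

#' Construct an ordered collection of spectra
#'
#' The order of spectra is significant: position in the list equals the column
#' index in every downstream binned matrix and score matrix. Spectrum ids must
#' be unique within a set.
#'
#' @param spectra list of [ms_spectrum()] objects.
#' @param source provenance text, e.g. a file path or `"synthetic"`.
#' @param role `"query"` or `"reference"`.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, source = "synthetic",
                         role = c("query", "reference")) {
  role <- match.arg(role)
  if (!is.list(spectra) || !all(vapply(spectra, inherits, logical(1), "ms_spectrum")))
    stop("spectra must be a list of ms_spectrum objects", call. = FALSE)
  ids <- vapply(spectra, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate spectrum ids in set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(list(spectra = spectra, source = source, role = role),
            class = "spectrum_set")
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

#' @export
`[.spectrum_set` <- function(x, i) {
  spectrum_set(x$spectra[i], source = x$source, role = x$role)
}

#' @export
print.spectrum_set <- function(x, ...) {
  nf <- vapply(x$spectra, function(s) length(s$mz), integer(1))
  cat(sprintf("<spectrum_set> %d %s spectra from %s (%d fragments total)\n",
              length(x$spectra), x$role, x$source, sum(nf)))
  invisible(x)
}

#' Spectrum ids of a set
#' @param x a `spectrum_set`.
#' @return character vector of ids, in set order.
#' @export
spectrum_ids <- function(x) {
  stopifnot(inherits(x, "spectrum_set"))
  vapply(x$spectra, `[[`, character(1), "id")
}
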