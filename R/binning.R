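#' Convert m/z values to integer bins
#'
#' Discretization is by flooring: `bin = floor(mz / bin_width)`. Floor (rather
#' than round) binning is what makes the kernel's guaranteed linking tolerance
#' exactly `tolerance - bin_width` (see [make_kernel()]). The division is
#' guarded with a relative epsilon of 1e-9 so m/z values intended to be exact
#' multiples of the bin width land in the upper bin consistently instead of
#' falling a float ulp short.
#'
#' @param mz numeric vector of m/z (or shifted mass coordinate) values, > 0.
#' @param bin_width bin width in Da, > 0.
#' @return Numeric vector of integer-valued bin indices (returned as doubles:
#'   at small bin widths the indices exceed the 32-bit integer range).
#' @examples
#' bin_index(100.0005, 0.001)  # 100000
#' @export
bin_index <- function(mz, bin_width) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive number", call. = FALSE)
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("m/z values must be finite and > 0", call. = FALSE)
  x <- mz / bin_width
  floor(x * (1 + 1e-9))
}

#' Build the uniform blur kernel linking bins within tolerance
#'
#' The kernel is a ones-vector of half-width `round(tolerance / bin_width) - 1`
#' bins. Convolving one side of a comparison with it links every pair of
#' fragments whose floored bins differ by at most the half-width. With floor
#' binning this realizes a guaranteed ("true") linking tolerance of
#' `tolerance - bin_width`: fragment pairs closer than that always share a
#' blurred bin, pairs farther apart than `tolerance` never do, and pairs in
#' between link or not depending on where they fall within their bins.
#'
#' @param tolerance linking tolerance parameter in Da (default 0.01). Must be
#'   strictly greater than `bin_width`.
#' @param bin_width bin width in Da (default 0.001).
#' @return An object of class `blur_kernel` with fields `tolerance`,
#'   `bin_width`, `half_width` (integer bins).
#' @examples
#' make_kernel(0.01, 0.001)$half_width  # 9 -> effective tolerance 0.009 Da
#' @export
make_kernel <- function(tolerance = 0.01, bin_width = 0.001) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0 ||
      !is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("tolerance and bin_width must be single positive numbers",
         call. = FALSE)
  if (tolerance <= bin_width)
    stop("BLINK bin width cannot exceed tolerance (tolerance = ", tolerance,
         ", bin_width = ", bin_width, ")", call. = FALSE)
  hw <- as.integer(round(tolerance / bin_width) - 1)
  stopifnot(hw >= 0L)
  structure(list(tolerance = tolerance, bin_width = bin_width,
                 half_width = hw),
            class = "blur_kernel")
}

#' Guaranteed linking tolerance of a kernel
#'
#' @param k a `blur_kernel`.
#' @return The maximum m/z difference (Da) at which two fragments are always
#'   linked: `half_width * bin_width`.
#' @export
effective_tolerance <- function(k) {
  stopifnot(inherits(k, "blur_kernel"))
  k$half_width * k$bin_width
}

#' @export
print.blur_kernel <- function(x, ...) {
  cat(sprintf(
    "<blur_kernel> tolerance %g Da, bin width %g Da, half-width %d bins (guaranteed tolerance %g Da)\n",
    x$tolerance, x$bin_width, x$half_width, effective_tolerance(x)))
  invisible(x)
}

# Internal: build a compact sparse matrix pair over occupied bins only.
# `bins` holds the absolute integer bin value of each matrix row, sorted
# ascending; this keeps tiny bin widths (bin indices up to ~2e9) cheap because
# only occupied bins are materialized.
new_binned <- function(intensity, counts, bins, bin_width, ids, shift, delta,
                       blurred = FALSE, tolerance = NA_real_) {
  structure(list(intensity = intensity, counts = counts, bins = bins,
                 bin_width = bin_width, ids = ids, shift = shift,
                 delta = delta, blurred = blurred, tolerance = tolerance),
            class = "binned_spectra")
}

#' Discretize a spectrum set into paired sparse intensity/count matrices
#'
#' Each fragment of spectrum `j` contributes its intensity to
#' `intensity[bin, j]` and 1 to `counts[bin, j]`, where `bin` is the floored
#' integer bin of its mass coordinate. The coordinate is the fragment m/z for
#' `shift = "none"`; the neutral loss `precursor_mz - mz` for
#' `shift = "precursor"` (so equal neutral losses align across different
#' precursors in analog searches); and `mz + delta` for `shift = "fixed"`.
#' Fragments whose shifted coordinate is not positive are dropped (their count
#' is reported in a message).
#'
#' Rows cover occupied bins only; the absolute bin value of each row is kept
#' in the `bins` field and used to align matrices at scoring time.
#'
#' @param set a preprocessed [spectrum_set()] (see [preprocess_set()]).
#' @param bin_width bin width in Da (default 0.001).
#' @param shift `"none"`, `"precursor"`, or `"fixed"`.
#' @param delta mass shift in Da for `shift = "fixed"`.
#' @return An object of class `binned_spectra` holding the two sparse
#'   matrices (rows = occupied bins, columns = spectra).
#' @export
discretize <- function(set, bin_width = 0.001,
                       shift = c("none", "precursor", "fixed"), delta = 0) {
  stopifnot(inherits(set, "spectrum_set"))
  shift <- match.arg(shift)
  if (!length(set$spectra)) stop("cannot discretize an empty set", call. = FALSE)

  n <- length(set$spectra)
  coord <- vector("list", n)
  inten <- vector("list", n)
  dropped <- 0L
  for (j in seq_len(n)) {
    s <- set$spectra[[j]]
    x <- switch(shift,
                none = s$mz,
                precursor = s$precursor_mz - s$mz,
                fixed = s$mz + delta)
    ok <- x > 0
    dropped <- dropped + sum(!ok)
    coord[[j]] <- x[ok]
    inten[[j]] <- s$intensity[ok]
  }
  if (dropped > 0L)
    message(dropped, " fragments dropped: non-positive shifted coordinate")
  lens <- lengths(coord)
  if (sum(lens) == 0L) stop("no fragments left to discretize", call. = FALSE)

  bins_all <- bin_index(unlist(coord), bin_width)
  cols <- rep.int(seq_len(n), lens)
  ubins <- sort(unique(bins_all))
  rows <- match(bins_all, ubins)

  intensity <- Matrix::sparseMatrix(i = rows, j = cols, x = unlist(inten),
                                    dims = c(length(ubins), n))
  counts <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                                 dims = c(length(ubins), n))
  new_binned(intensity, counts, ubins, bin_width, spectrum_ids(set),
             shift, delta)
}

#' @export
print.binned_spectra <- function(x, ...) {
  cat(sprintf(
    "<binned_spectra> %d spectra, %d occupied bins (bin width %g Da, shift %s%s)%s\n",
    ncol(x$intensity), length(x$bins), x$bin_width, x$shift,
    if (x$shift == "fixed") sprintf(" %+g Da", x$delta) else "",
    if (x$blurred) ", blurred" else ""))
  invisible(x)
}

#' Blur binned matrices with a uniform kernel
#'
#' Expands each occupied bin into the `2 * half_width + 1` bins centred on it,
#' distributing its intensity (and fragment count) to all of them. This is
#' exactly a convolution with a ones-vector of length `2 * half_width + 1`,
#' i.e. left-multiplication by a symmetric banded matrix of ones, and is what
#' links bins across spectra within the tolerance at scoring time. The bin
#' range grows by `half_width` on each side, so no mass is truncated at the
#' edges; the total of the blurred matrix is `(2 * half_width + 1)` times the
#' total of the input.
#'
#' Only one side of a comparison may be blurred (blurring both would double
#' the tolerance), so blurring an already-blurred object is an error.
#'
#' @param m a `binned_spectra` from [discretize()].
#' @param k a `blur_kernel` from [make_kernel()] with the same bin width.
#' @return A blurred `binned_spectra`.
#' @export
blur <- function(m, k) {
  stopifnot(inherits(m, "binned_spectra"), inherits(k, "blur_kernel"))
  if (m$blurred) stop("matrices are already blurred", call. = FALSE)
  if (abs(m$bin_width - k$bin_width) > 1e-12 * k$bin_width)
    stop("kernel bin width (", k$bin_width, ") does not match matrices (",
         m$bin_width, ")", call. = FALSE)
  hw <- k$half_width
  if (hw == 0L)
    return(new_binned(m$intensity, m$counts, m$bins, m$bin_width, m$ids,
                      m$shift, m$delta, blurred = TRUE,
                      tolerance = k$tolerance))
  Ti <- methods::as(m$intensity, "TsparseMatrix")
  offs <- seq.int(-hw, hw)
  nk <- length(offs)
  src_bins <- m$bins[Ti@i + 1L]
  bins_all <- rep(src_bins, times = nk) + rep(offs, each = length(src_bins))
  cols <- rep.int(Ti@j + 1L, nk)
  ubins <- sort(unique(bins_all))
  rows <- match(bins_all, ubins)
  intensity <- Matrix::sparseMatrix(i = rows, j = cols,
                                    x = rep.int(Ti@x, nk),
                                    dims = c(length(ubins), ncol(m$intensity)))
  Tc <- methods::as(m$counts, "TsparseMatrix")
  # identical sparsity pattern pre-blur, so the same row/col expansion applies
  counts <- Matrix::sparseMatrix(i = rows, j = cols,
                                 x = rep.int(Tc@x, nk),
                                 dims = c(length(ubins), ncol(m$counts)))
  new_binned(intensity, counts, ubins, m$bin_width, m$ids, m$shift, m$delta,
             blurred = TRUE, tolerance = k$tolerance)
}

# Internal: re-index a compact sparse matrix onto a common bin universe.
remap_bins <- function(M, bins, universe) {
  T <- methods::as(M, "TsparseMatrix")
  Matrix::sparseMatrix(i = match(bins[T@i + 1L], universe), j = T@j + 1L,
                       x = T@x, dims = c(length(universe), ncol(M)))
}
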