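# Shared fixtures and independent oracles, all built in code at test time.

# Pure-R greedy alignment cosine: an implementation of the reference scorer
# independent of the compiled one, used to cross-check it on small inputs.
r_greedy_cosine <- function(a, b, tolerance) {
  if (!length(a$mz) || !length(b$mz)) return(list(score = 0, matches = 0L))
  d <- abs(outer(a$mz, b$mz, "-"))
  idx <- which(d <= tolerance, arr.ind = TRUE)
  if (!nrow(idx)) return(list(score = 0, matches = 0L))
  prod <- a$intensity[idx[, 1]] * b$intensity[idx[, 2]]
  dmz <- d[idx]
  o <- order(-prod, dmz, idx[, 1], idx[, 2])
  idx <- idx[o, , drop = FALSE]
  prod <- prod[o]
  used_a <- logical(length(a$mz)); used_b <- logical(length(b$mz))
  score <- 0; matches <- 0L
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- used_b[j] <- TRUE
      score <- score + prod[k]
      matches <- matches + 1L
    }
  }
  list(score = score, matches = matches)
}

# Dense convolution oracle for blur(): reconstructs the dense bin x spectrum
# matrix and convolves each column with a ones-vector of length 2*hw + 1.
dense_blur <- function(binned, half_width) {
  bins <- binned$bins
  lo <- min(bins) - half_width
  hi <- max(bins) + half_width
  dense <- function(M) {
    D <- matrix(0, hi - lo + 1, ncol(M))
    T <- methods::as(M, "TsparseMatrix")
    for (k in seq_along(T@x))
      D[bins[T@i[k] + 1] - lo + 1, T@j[k] + 1] <-
        D[bins[T@i[k] + 1] - lo + 1, T@j[k] + 1] + T@x[k]
    out <- matrix(0, nrow(D), ncol(D))
    for (j in seq_len(ncol(D)))
      for (r in seq_len(nrow(D))) {
        win <- max(1, r - half_width):min(nrow(D), r + half_width)
        out[r, j] <- sum(D[win, j])
      }
    out
  }
  list(intensity = dense(binned$intensity), counts = dense(binned$counts),
       first_bin = lo)
}

# Reconstruct a dense matrix from a compact binned_spectra over a bin range.
dense_from_binned <- function(binned, M, lo, hi) {
  D <- matrix(0, hi - lo + 1, ncol(M))
  T <- methods::as(M, "TsparseMatrix")
  for (k in seq_along(T@x))
    D[binned$bins[T@i[k] + 1] - lo + 1, T@j[k] + 1] <- T@x[k]
  D
}

# Write an MGF file from raw text lines, returning its path.
mgf_fixture <- function(lines) {
  path <- tempfile(fileext = ".mgf")
  writeLines(lines, path)
  path
}

# A tiny deterministic two-spectrum set with well-separated fragments.
toy_set <- function(role = "query") {
  spectrum_set(list(
    ms_spectrum(c(100.0, 200.0, 300.0), c(3, 4, 12), 350, id = "a"),
    ms_spectrum(c(120.0, 220.0), c(1, 1), 340, id = "b")
  ), role = role)
}

expect_spectra_equal <- function(x, y, mz_tol = 1e-6, int_rtol = 1e-9) {
  expect_equal(x$id, y$id)
  expect_equal(x$precursor_mz, y$precursor_mz, tolerance = mz_tol)
  expect_equal(x$mz, y$mz, tolerance = mz_tol)
  expect_equal(x$intensity, y$intensity, tolerance = int_rtol)
}
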