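test_that("bin_index floors m/z onto integer bins, robust at exact multiples", {
  expect_equal(bin_index(100.0005, 0.001), 100000)
  expect_equal(bin_index(0.0005, 0.001), 0)
  expect_equal(bin_index(100.0005, 0.01), 10000)
  expect_error(bin_index(-1, 0.001), "> 0")
  expect_error(bin_index(100, 0), "positive")

  # exact rational-arithmetic oracle: mz = a/b, bin_width = c/d, so the true
  # bin is the integer quotient (a*d) %/% (b*c). Exercises exact-multiple
  # boundaries (where the float quotient can fall an ulp short) and interior
  # points alike.
  grid <- expand.grid(a = c(1, 3, 7, 100, 1001, 99999, 1234567),
                      b = c(1, 2, 4, 8, 10, 1000),
                      c = c(1, 3, 10, 1000),
                      d = c(1000, 10000, 100000))
  for (k in seq_len(nrow(grid))) {
    a <- grid$a[k]; b <- grid$b[k]; cc <- grid$c[k]; d <- grid$d[k]
    expected <- (a * d) %/% (b * cc)
    expect_equal(bin_index(a / b, cc / d), expected,
                 info = sprintf("mz=%g/%g bw=%g/%g", a, b, cc, d))
  }
})

test_that("discretize builds paired sparse matrices over occupied bins", {
  # two spectra sharing one bin -> one row, two column entries
  set <- spectrum_set(list(
    ms_spectrum(100.0005, 1, 300, id = "a"),
    ms_spectrum(100.0005, 1, 300, id = "b")))
  d <- discretize(preprocess_set(set), 0.001)
  expect_equal(length(d$bins), 1)
  expect_equal(d$bins, 100000)
  expect_equal(as.numeric(d$counts), c(1, 1))

  # two fragments in one bin accumulate: intensity a+b, count 2
  s <- unit_normalize(ms_spectrum(c(100.0001, 100.00052, 200), c(3, 4, 12), 300))
  d <- discretize(spectrum_set(list(s)), 0.001)
  expect_equal(length(d$bins), 2)
  i <- which(d$bins == 100000)
  expect_equal(d$intensity[i, 1], sum(s$intensity[1:2]))
  expect_equal(d$counts[i, 1], 2)

  # precursor mode bins the neutral loss precursor_mz - mz
  s <- ms_spectrum(100.0, 1, 300.0, id = "nl")
  d <- discretize(spectrum_set(list(s)), 0.001, shift = "precursor")
  expect_equal(d$bins, bin_index(200.0, 0.001))

  # fixed mode shifts by delta
  d <- discretize(spectrum_set(list(s)), 0.001, shift = "fixed", delta = 14.016)
  expect_equal(d$bins, bin_index(114.016, 0.001))

  expect_error(discretize(spectrum_set(list()), 0.001), "empty")
})

test_that("discretize invariants hold on random libraries", {
  lib <- preprocess_set(random_library(20, seed = 71))
  d <- discretize(lib, 0.001)
  # identical sparsity pattern before blurring
  expect_identical(which(as.matrix(d$intensity) != 0),
                   which(as.matrix(d$counts) != 0))
  # column sums of counts = retained fragment counts
  expect_equal(as.numeric(Matrix::colSums(d$counts)),
               vapply(lib$spectra, n_fragments, integer(1)) + 0)
  # all stored values positive
  expect_true(all(d$intensity@x > 0) && all(d$counts@x > 0))
})

test_that("the kernel half-width realizes tolerance minus bin width", {
  expect_equal(make_kernel(0.01, 0.001)$half_width, 9L)
  expect_equal(effective_tolerance(make_kernel(0.01, 0.001)), 0.009)
  expect_equal(make_kernel(0.002, 0.001)$half_width, 1L)
  expect_equal(make_kernel(0.01, 0.0001)$half_width, 99L)
  expect_error(make_kernel(0.01, 0.02), "bin width cannot exceed tolerance")
  expect_error(make_kernel(0.001, 0.001), "bin width cannot exceed tolerance")
})

test_that("linkage bounds: always linked within hw*bw, never beyond tolerance", {
  # brute force over random fragment pairs at a fine bin width (hw = 99)
  set.seed(72)
  k <- make_kernel(0.01, 0.0001)
  n <- 1e4
  mz1 <- runif(n, 50, 2000)
  d <- c(runif(n / 2, 0, effective_tolerance(k)),
         runif(n / 2, 0.01 * (1 + 1e-9), 0.05))
  mz2 <- mz1 + d
  linked <- abs(bin_index(mz2, k$bin_width) - bin_index(mz1, k$bin_width)) <=
    k$half_width
  expect_true(all(linked[seq_len(n / 2)]))
  expect_false(any(linked[seq(n / 2 + 1, n)]))
})

test_that("blur equals dense convolution with a ones kernel", {
  lib <- preprocess_set(random_library(5, n_frag_range = c(3, 10),
                                       mz_range = c(50, 90), seed = 73))
  d <- discretize(lib, 1)  # coarse bins -> toy-sized dense matrices
  for (hw in c(1L, 3L, 9L)) {
    k <- make_kernel((hw + 1) * 1.0, 1.0)
    expect_equal(k$half_width, hw)
    b <- blur(d, k)
    oracle <- dense_blur(d, hw)
    lo <- min(b$bins); hi <- max(b$bins)
    expect_identical(lo, oracle$first_bin)
    expect_equal(dense_from_binned(b, b$intensity, lo, hi), oracle$intensity)
    expect_equal(dense_from_binned(b, b$counts, lo, hi), oracle$counts)
    # conservation: total grows by the kernel length
    expect_equal(sum(b$intensity), (2 * hw + 1) * sum(d$intensity))
  }
})

test_that("blur edge cases: identity at half-width 0, no double blurring", {
  s <- preprocess_set(spectrum_set(list(ms_spectrum(100.0005, 1, 300))))
  d <- discretize(s, 0.001)
  k0 <- make_kernel(0.0014, 0.001)  # rounds to half-width 0
  expect_equal(k0$half_width, 0L)
  b0 <- blur(d, k0)
  expect_identical(b0$bins, d$bins)
  expect_equal(as.matrix(b0$intensity), as.matrix(d$intensity))

  k9 <- make_kernel(0.01, 0.001)
  b <- blur(d, k9)
  # a single fragment of value v becomes 19 consecutive bins holding v
  expect_equal(length(b$bins), 19)
  expect_equal(b$bins, seq(100000 - 9, 100000 + 9))
  expect_true(all(b$intensity@x == 1))
  expect_error(blur(b, k9), "already blurred")

  # two fragments 5 bins apart: overlap region holds the sum of both
  s2 <- spectrum_set(list(unit_normalize(
    ms_spectrum(c(100.0005, 100.0055), c(1, 1), 300))))
  b2 <- blur(discretize(s2, 0.001), k9)
  v <- 1 / sqrt(2)
  overlap <- b2$bins >= 100005 - 9 & b2$bins <= 100000 + 9
  expect_true(all(abs(b2$intensity[which(overlap), 1] - 2 * v) < 1e-12))
  expect_true(all(abs(b2$intensity[which(!overlap), 1] - v) < 1e-12))
})

test_that("blur commutes with column permutation of spectra", {
  lib <- preprocess_set(random_library(6, seed = 74))
  k <- make_kernel(0.01, 0.001)
  d <- discretize(lib, 0.001)
  perm <- c(3, 1, 6, 2, 5, 4)
  d_perm <- discretize(lib[perm], 0.001)
  b <- blur(d, k)
  b_perm <- blur(d_perm, k)
  expect_identical(b$bins, b_perm$bins)
  expect_equal(as.matrix(b_perm$intensity), as.matrix(b$intensity[, perm]))
  expect_equal(as.matrix(b_perm$counts), as.matrix(b$counts[, perm]))
})
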