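test_that("aligned cosine handles the canonical hand-worked cases", {
  # identical unit spectra: score 1, every fragment matched
  s <- unit_normalize(ms_spectrum(c(100, 150, 200), c(1, 2, 3), 300))
  r <- aligned_cosine(s, s, 0.009)
  expect_equal(r$score, 1, tolerance = 1e-12)
  expect_equal(r$matches, 3L)

  # disjoint spectra
  a <- unit_normalize(ms_spectrum(c(100, 200), c(1, 1), 300))
  b <- unit_normalize(ms_spectrum(c(101, 201), c(1, 1), 300))
  expect_equal(aligned_cosine(a, b, 0.009), list(score = 0, matches = 0L))

  # one candidate within tolerance out of two fragments
  a <- ms_spectrum(c(100.000, 200.000), c(0.6, 0.8), 300)
  b <- ms_spectrum(100.004, 1.0, 300)
  r <- aligned_cosine(a, b, 0.009)
  expect_equal(r$score, 0.6)
  expect_equal(r$matches, 1L)

  # empty spectrum scores zero
  e <- suppressWarnings(filter_noise(ms_spectrum(100, 0, 300)))
  expect_equal(aligned_cosine(e, s, 0.009), list(score = 0, matches = 0L))
})

test_that("aligned cosine is symmetric and bounded on random pairs", {
  set.seed(91)
  pl <- paired_libraries(40, shared_fraction = 0.6, jitter = 0.006, seed = 91)
  q <- preprocess_set(pl$query); r <- preprocess_set(pl$ref)
  for (i in seq_len(40)) {
    ab <- aligned_cosine(q$spectra[[i]], r$spectra[[i]], 0.009)
    ba <- aligned_cosine(r$spectra[[i]], q$spectra[[i]], 0.009)
    expect_equal(ab$score, ba$score, tolerance = 1e-12)
    expect_identical(ab$matches, ba$matches)
    expect_gte(ab$score, 0)
    expect_lte(ab$score, 1 + 1e-12)
  }
})

test_that("compiled greedy pairing agrees with an independent R implementation", {
  set.seed(92)
  pl <- paired_libraries(30, n_frag_range = c(3, 15), shared_fraction = 0.7,
                         jitter = 0.008, intensity_noise = 0.3, seed = 92)
  q <- preprocess_set(pl$query); r <- preprocess_set(pl$ref)
  res <- oracle_score_all(q, r, 0.009)
  for (i in seq_len(30)) for (j in seq(i, min(i + 2, 30))) {
    ref <- r_greedy_cosine(q$spectra[[i]], r$spectra[[j]], 0.009)
    expect_equal(res$scores[i, j], ref$score, tolerance = 1e-12)
    expect_equal(res$matches[i, j], ref$matches)
  }
})

test_that("greedy pairing agrees with the matchms reference implementation", {
  # independent cross-check against the loop-based comparator the method is
  # benchmarked against; tolerance-separated spectra avoid tie-break
  # ambiguity between implementations.
  set.seed(93)
  lib <- random_library(8, n_frag_range = c(5, 15), min_spacing = 0.02,
                        seed = 93)
  pp <- preprocess_set(lib)
  qs <- lapply(pp$spectra, perturb_pair, shared_fraction = 0.7,
               jitter = 0.005, intensity_noise = 0.2, min_spacing = 0.02)
  qpp <- preprocess_set(spectrum_set(qs))

  lines <- character(0)
  ours <- matrix(0, 8, 2)
  for (i in 1:8) {
    a <- qpp$spectra[[i]]; b <- pp$spectra[[i]]
    r <- aligned_cosine(a, b, 0.009)
    ours[i, ] <- c(r$score, r$matches)
    lines <- c(lines,
               paste(sprintf("%.10f", a$mz), collapse = " "),
               paste(sprintf("%.10f", a$intensity), collapse = " "),
               paste(sprintf("%.10f", b$mz), collapse = " "),
               paste(sprintf("%.10f", b$intensity), collapse = " "))
  }
  pairs_file <- tempfile(fileext = ".txt")
  writeLines(lines, pairs_file)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from matchms import Spectrum",
    "from matchms.similarity import CosineGreedy",
    "lines = open(sys.argv[1]).read().strip().split('\\n')",
    "sim = CosineGreedy(tolerance=float(sys.argv[2]))",
    "for k in range(0, len(lines), 4):",
    "    v = [np.array([float(x) for x in lines[k+m].split()]) for m in range(4)]",
    "    sa = Spectrum(mz=v[0], intensities=v[1], metadata={'precursor_mz': 1000.0}, metadata_harmonization=False)",
    "    sb = Spectrum(mz=v[2], intensities=v[3], metadata={'precursor_mz': 1000.0}, metadata_harmonization=False)",
    "    r = sim.pair(sa, sb)",
    "    print(float(r['score']), int(r['matches']))"
  ), py)
  out <- system2("python", c(py, pairs_file, "0.009"), stdout = TRUE)
  mm <- do.call(rbind, lapply(strsplit(out, " "), as.numeric))
  expect_equal(ours[, 1], mm[, 1], tolerance = 1e-6)
  expect_equal(ours[, 2], mm[, 2])
})

test_that("rescoring hits re-filters by precise score and sorts descending", {
  set.seed(94)
  bs <- oracle_benchmark_sets(40, seed = 94)
  q <- preprocess_set(bs$query); r <- preprocess_set(bs$ref)
  res <- blink_score(q, r)
  hits <- score_hits(res, 0.7, 6)
  expect_gt(nrow(hits), 0)
  re <- rescore_hits(hits, q, r, 0.009)
  # exact-equivalence conditions: nothing changes
  expect_equal(nrow(re), nrow(hits))
  expect_equal(re$score, re$blink_score, tolerance = 1e-9)
  expect_identical(re$matches, as.integer(re$blink_matches))

  # empty hit list passes through
  empty <- rescore_hits(hits[0, ], q, r, 0.009)
  expect_equal(nrow(empty), 0)

  # thresholds above every precise score empty the list
  none <- rescore_hits(hits, q, r, 0.009, min_score = 1.01)
  expect_equal(nrow(none), 0)

  # unknown ids are an error
  bad <- hits; bad$query_id[1] <- "nope"
  expect_error(rescore_hits(bad, q, r, 0.009), "unknown query id")
})

test_that("blur-and-link never scores below the greedy alignment", {
  set.seed(95)
  pl <- paired_libraries(60, shared_fraction = 0.7, jitter = 0.012,
                         intensity_noise = 0.2, seed = 95)
  q <- preprocess_set(pl$query); r <- preprocess_set(pl$ref)
  b <- blink_score(q, r, 0.001, 0.01)
  o <- oracle_score_all(q, r, 0.009)
  expect_true(all(b$scores >= o$scores - 1e-9))
})
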