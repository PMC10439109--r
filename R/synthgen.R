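#' Generate a random synthetic spectrum library
#'
#' Emulates a library of centroided high-resolution MS/MS spectra: fragment
#' m/z drawn uniformly over a wide range with sub-0.01 Da placement, and
#' heavy-tailed (exponential) intensities. Fragment positions are thinned by
#' rejection until all pairwise spacings within a spectrum exceed
#' `min_spacing`; the precursor m/z is placed above the largest fragment.
#' Everything is driven by R's integer-state RNG, so a given seed reproduces
#' the library exactly on any platform.
#'
#' @param n_spectra number of spectra to generate.
#' @param n_frag_range integer `(min, max)` fragments per spectrum, drawn
#'   uniformly.
#' @param mz_range fragment m/z range in Da (default 50–2000).
#' @param intensity_mean mean of the exponential intensity law (default 100).
#' @param min_spacing minimum pairwise m/z spacing within a spectrum in Da
#'   (default 0, i.e. unconstrained).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param id_prefix prefix for generated spectrum ids.
#' @param role role recorded on the returned set.
#' @return A [spectrum_set()] with `source = "synthetic"`.
#' @export
random_library <- function(n_spectra, n_frag_range = c(5, 30),
                           mz_range = c(50, 2000), intensity_mean = 100,
                           min_spacing = 0, seed = NULL,
                           id_prefix = "syn", role = "reference") {
  stopifnot(n_spectra >= 1, length(n_frag_range) == 2,
            n_frag_range[1] >= 1, n_frag_range[2] >= n_frag_range[1],
            length(mz_range) == 2, mz_range[1] > 0, mz_range[2] > mz_range[1],
            min_spacing >= 0)
  if (!is.null(seed)) set.seed(seed)
  spectra <- vector("list", n_spectra)
  for (i in seq_len(n_spectra)) {
    nf <- if (n_frag_range[1] == n_frag_range[2]) n_frag_range[1]
          else sample(seq(n_frag_range[1], n_frag_range[2]), 1L)
    mz <- spaced_mz(nf, mz_range, min_spacing)
    inten <- rexp(nf, rate = 1 / intensity_mean)
    inten[inten <= 0] <- intensity_mean * 1e-6
    precursor <- max(mz) + runif(1, 1, 50)
    spectra[[i]] <- ms_spectrum(mz, inten, precursor,
                                id = sprintf("%s_%04d", id_prefix, i))
  }
  spectrum_set(spectra, source = "synthetic", role = role)
}

# Internal: draw n m/z values with pairwise spacing > min_spacing by
# rejection, with bounded retries.
spaced_mz <- function(n, mz_range, min_spacing, avoid = numeric(0),
                      clearance = 0, max_tries = 10000L) {
  mz <- numeric(0)
  tries <- 0L
  while (length(mz) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("cannot place ", n, " fragments with spacing ", min_spacing,
           " in [", mz_range[1], ", ", mz_range[2],
           "]: infeasible density", call. = FALSE)
    x <- runif(1, mz_range[1], mz_range[2])
    if (length(mz) && min(abs(mz - x)) <= min_spacing) next
    if (length(avoid) && min(abs(avoid - x)) <= clearance) next
    mz <- c(mz, x)
  }
  sort(mz)
}

#' Generate a perturbed partner spectrum
#'
#' Builds a spectrum sharing a controllable fraction of fragments with `s`:
#' a random subset of `ceiling(shared_fraction * n)` fragments is kept, each
#' m/z perturbed uniformly within `±jitter` and each intensity multiplied by
#' lognormal noise; the remaining fragments are replaced with fresh random
#' ones kept at least `clearance` Da away from every original fragment (so an
#' unshared fragment never accidentally matches) and `min_spacing` away from
#' each other and the kept fragments. An optional uniform `mass_shift` is
#' applied to all fragments and the precursor, which makes the pair a
#' synthetic homolog for analog-search tests: the neutral losses are then
#' identical by construction.
#'
#' @param s the [ms_spectrum()] to perturb.
#' @param shared_fraction fraction of fragments to keep, in `[0, 1]`.
#' @param jitter maximum absolute m/z perturbation of kept fragments (Da).
#' @param intensity_noise lognormal sdlog of the multiplicative intensity
#'   noise on kept fragments (0 = none).
#' @param mass_shift uniform shift in Da applied to all fragments and the
#'   precursor (default 0).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param clearance minimum distance of fresh fragments from every original
#'   fragment (default 0.021 Da, safely beyond the default 0.01 Da linking
#'   tolerance plus jitter).
#' @param min_spacing minimum spacing of fresh fragments from each other and
#'   from kept fragments (default 0).
#' @param mz_range range for fresh fragment m/z; capped at the precursor so
#'   fresh fragments survive noise filtering.
#' @param intensity_mean exponential mean for fresh fragment intensities.
#' @param id id of the returned spectrum (default `"<id>_p"`).
#' @return A perturbed `ms_spectrum`.
#' @export
perturb_pair <- function(s, shared_fraction, jitter = 0,
                         intensity_noise = 0, mass_shift = 0, seed = NULL,
                         clearance = 0.021, min_spacing = 0,
                         mz_range = c(50, 2000), intensity_mean = 100,
                         id = NULL) {
  stopifnot(inherits(s, "ms_spectrum"),
            shared_fraction >= 0, shared_fraction <= 1, jitter >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(s$mz)
  n_keep <- as.integer(ceiling(shared_fraction * n))
  keep <- if (n_keep) sort(sample.int(n, n_keep)) else integer(0)

  mz <- s$mz[keep] + runif(n_keep, -jitter, jitter)
  inten <- s$intensity[keep] *
    (if (intensity_noise > 0) rlnorm(n_keep, 0, intensity_noise) else 1)

  n_fresh <- n - n_keep
  if (n_fresh > 0) {
    hi <- min(mz_range[2], s$precursor_mz)
    fresh <- spaced_mz(n_fresh, c(mz_range[1], hi), min_spacing,
                       avoid = c(s$mz, mz), clearance = max(clearance, min_spacing))
    mz <- c(mz, fresh)
    inten <- c(inten, rexp(n_fresh, rate = 1 / intensity_mean))
  }
  inten[inten <= 0] <- intensity_mean * 1e-6
  ms_spectrum(mz + mass_shift, inten, s$precursor_mz + mass_shift,
              id = if (is.null(id)) paste0(s$id, "_p") else id,
              charge = s$charge)
}

#' Query/reference pair of libraries with controlled overlap
#'
#' Generates a reference library and a query set in which query spectrum `i`
#' is a [perturb_pair()] partner of reference spectrum `i`. With default
#' (unconstrained) spacing this emulates the realistic case used for
#' agreement-rate benchmarking.
#'
#' @inheritParams random_library
#' @param shared_fraction,jitter,intensity_noise,mass_shift passed to
#'   [perturb_pair()].
#' @return A list with elements `query` and `ref` ([spectrum_set()]s).
#' @export
paired_libraries <- function(n_spectra, n_frag_range = c(5, 30),
                             mz_range = c(50, 2000), intensity_mean = 100,
                             min_spacing = 0, shared_fraction = 0.75,
                             jitter = 0.01, intensity_noise = 0.1,
                             mass_shift = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- random_library(n_spectra, n_frag_range, mz_range, intensity_mean,
                        min_spacing, seed = NULL, role = "reference")
  qs <- lapply(ref$spectra, perturb_pair, shared_fraction = shared_fraction,
               jitter = jitter, intensity_noise = intensity_noise,
               mass_shift = mass_shift, min_spacing = min_spacing,
               mz_range = mz_range, intensity_mean = intensity_mean)
  list(query = spectrum_set(qs, source = "synthetic", role = "query"),
       ref = ref)
}

#' Benchmark libraries on which blur-and-link scoring is provably exact
#'
#' Constructs a query/reference pair designed so that blur-and-link scoring
#' at (`tolerance`, `bin_width`) agrees *exactly* with the precise aligned
#' cosine at `tolerance - bin_width`:
#'
#' * within-spectrum fragment spacings all exceed `2 * tolerance`, so no
#'   fragment can link to two partners (the mechanism behind the method's
#'   one-sided score deviation is absent by construction);
#' * kept query fragments sit within `jitter <= tolerance - bin_width` of
#'   their reference partner, so both scorers always link them;
#' * every other query–reference fragment distance is pushed outside
#'   `(tolerance - bin_width, tolerance]`, the "grey zone" where linking
#'   depends on bin phase, by redrawing offending fragments.
#'
#' @inheritParams paired_libraries
#' @param tolerance,bin_width the blur-and-link parameters the sets are
#'   conditioned on.
#' @return A list with elements `query` and `ref`.
#' @export
oracle_benchmark_sets <- function(n_spectra = 200, n_frag_range = c(8, 20),
                                  mz_range = c(50, 2000),
                                  intensity_mean = 100,
                                  shared_fraction = 0.8, jitter = 0.008,
                                  intensity_noise = 0.1,
                                  tolerance = 0.01, bin_width = 0.001,
                                  seed = NULL) {
  stopifnot(jitter <= tolerance - bin_width)
  if (!is.null(seed)) set.seed(seed)
  spacing <- 2 * tolerance
  ref <- random_library(n_spectra, n_frag_range, mz_range, intensity_mean,
                        min_spacing = spacing, seed = NULL, role = "reference")
  qs <- lapply(ref$spectra, perturb_pair, shared_fraction = shared_fraction,
               jitter = jitter, intensity_noise = intensity_noise,
               clearance = spacing + bin_width, min_spacing = spacing,
               mz_range = mz_range, intensity_mean = intensity_mean)
  query <- spectrum_set(qs, source = "synthetic", role = "query")
  query <- enforce_pair_conditions(query, ref, tolerance, bin_width,
                                   jitter = jitter, mz_range = mz_range)
  list(query = query, ref = ref)
}

# Internal: redraw query fragments that violate the exactness conditions —
# within-spectrum spacing <= 2*tolerance, or a distance to any reference
# fragment inside the phase-dependent zone (tolerance - bin_width, tolerance]
# that is not an intended (<= jitter) partner match. Redrawn fragments are
# placed beyond `tolerance + bin_width` of every reference fragment.
enforce_pair_conditions <- function(query, ref, tolerance, bin_width,
                                    jitter, mz_range, max_rounds = 50L) {
  ref_mz <- sort(unlist(lapply(ref$spectra, `[[`, "mz")))
  lo <- tolerance - bin_width
  hi <- tolerance * (1 + 1e-9)
  clear <- tolerance + bin_width
  in_zone <- function(x) {
    # any reference fragment at distance in (lo, hi] of x?
    n_hi <- findInterval(x + hi, ref_mz) - findInterval(x - hi, ref_mz)
    n_lo <- findInterval(x + lo, ref_mz) - findInterval(x - lo, ref_mz)
    n_hi > n_lo
  }
  spectra <- query$spectra
  for (si in seq_along(spectra)) {
    s <- spectra[[si]]
    for (round in seq_len(max_rounds)) {
      mz <- s$mz
      bad <- vapply(seq_along(mz), function(i) {
        others <- mz[-i]
        if (length(others) && min(abs(others - mz[i])) <= 2 * tolerance)
          return(TRUE)
        in_zone(mz[i])
      }, logical(1))
      if (!any(bad)) break
      for (i in which(bad)) {
        mz[i] <- redraw_clear(mz, i, ref_mz, clear, 2 * tolerance,
                              c(mz_range[1], min(mz_range[2], s$precursor_mz)))
      }
      s <- ms_spectrum(mz, s$intensity, s$precursor_mz, id = s$id,
                       charge = s$charge)
      spectra[[si]] <- s
    }
  }
  spectrum_set(spectra, source = query$source, role = query$role)
}

# Internal: draw a replacement m/z farther than `clear` from every reference
# fragment and than `spacing` from the spectrum's other fragments.
redraw_clear <- function(mz, i, ref_mz, clear, spacing, range,
                         max_tries = 10000L) {
  others <- mz[-i]
  for (t in seq_len(max_tries)) {
    x <- runif(1, range[1], range[2])
    k <- findInterval(x, ref_mz)
    near_ref <- (k >= 1 && x - ref_mz[k] <= clear) ||
      (k < length(ref_mz) && ref_mz[k + 1] - x <= clear)
    if (near_ref) next
    if (length(others) && min(abs(others - x)) <= spacing) next
    return(x)
  }
  stop("cannot redraw a clear fragment position: infeasible density",
       call. = FALSE)
}
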