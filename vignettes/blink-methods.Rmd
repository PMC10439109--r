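---
title: "Blur-and-link cosine scoring: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blur-and-link cosine scoring: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinkr)
```

## The scoring model

Spectral library search scores a query MS/MS spectrum against reference
spectra by the cosine of their fragment intensity vectors after aligning
fragments within a mass tolerance. The loop-based formulation enumerates
candidate fragment pairs per spectrum pair; blur-and-link vectorizes the
whole search.

Let $w$ be the bin width (Da) and $t$ the tolerance parameter (Da). Each
preprocessed spectrum $j$ becomes column $j$ of two sparse matrices over
integer bins $b = \lfloor mz / w \rfloor$: $Q[b, j]$ accumulates
unit-normalized intensities, $C[b, j]$ fragment counts. One side of the
comparison is convolved along the bin axis with a uniform ones kernel of
half-width

$$h = \mathrm{round}(t / w) - 1,$$

which spreads each occupied bin over $2h + 1$ consecutive bins. The single
sparse product $S = (K Q_{\text{query}})^{\mathsf T} Q_{\text{ref}}$ then
contains the cosine score of every query × reference pair; the same product
on the count matrices approximates the matching-ion counts. Because the
kernel matrix $K$ is symmetric, it does not matter which side is blurred;
`blink_score()` blurs the side with fewer fragments because that is cheaper.

### The effective-tolerance identity

With floor binning, two fragments at distance $d$ satisfy
$|\lfloor a/w \rfloor - \lfloor b/w \rfloor| \le h$ — i.e. share a blurred
bin — for every bin phase exactly when $d \le h w$, and never when
$d > (h+1)w$. With $h = \mathrm{round}(t/w) - 1$ and $t$ a multiple of $w$
this gives a guaranteed ("true") linking tolerance of

$$t_{\text{eff}} = t - w,$$

0.009 Da at the defaults $t = 0.01$, $w = 0.001$. Distances in
$(t - w,\, t]$ link or not depending on where they fall within their bins
(the "grey zone"). This identity is why the precise comparator should be
run at $t - w$ when validating default runs, and it is what
`scripts/acceptance.R` verifies by brute force. Floor (rather than round)
binning was chosen precisely because it makes this identity exact.

### Why scores can exceed the aligned cosine, never undershoot it

The precise scorer (`aligned_cosine()`) pairs each fragment with at most one
partner, greedily by descending intensity product. Blur-and-link instead
sums the intensity product of *every* linked fragment pair. All products are
non-negative, and every pair the greedy scorer accepts at tolerance
$t - w$ is guaranteed linked, so the blur-and-link score is bounded below by
the greedy score; when several fragments fall inside one tolerance window it
can exceed it. On spectra whose within-spectrum fragment spacings exceed
$2t$ and whose cross-spectrum distances avoid the grey zone, the two scorers
coincide exactly — the property the separation-controlled benchmark
libraries (`oracle_benchmark_sets()`) are built to realize, and that the
test suite asserts at $10^{-9}$.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `bin_width` | 0.001 | Da | discretization step; smaller is more faithful and slower |
| `tolerance` | 0.01 | Da | kernel window; guaranteed linking is `tolerance - bin_width` |
| `base_peak_fraction` | 0.01 | — | noise filter: fragments below this fraction of the base peak are removed |
| `apply_sqrt` | TRUE | — | square-root intensity scaling before normalization |
| `min_score` | 0.7 | — | similarity operating point, inclusive |
| `min_matches` | 6 | ions | similarity operating point, inclusive |

`tolerance` must strictly exceed `bin_width` (at equality the kernel
half-width would be zero *and* the guaranteed tolerance zero); both
`make_kernel()` and the command line reject such settings. The defaults suit
high-resolution instruments; for wide-tolerance (low-resolution) data the
grey zone grows with `bin_width` and a loop-based scorer is the better tool.

Preprocessing order is fixed — noise filter, then square root, then unit
normalization — because the cosine interpretation of the matrix product
requires normalization to be last. The base-peak threshold is evaluated on
the fragments that survive the zero-intensity and above-precursor filters,
which makes `filter_noise()` idempotent (a base peak above the precursor
cannot silently lower the threshold on a second pass). The fragment at
exactly the precursor m/z is kept, and a fragment at exactly the base-peak
fraction is kept; both comparisons are strict on the removal side. Spectra
emptied by filtering are dropped from the set with their ids reported, not
scored as zero vectors.

## Analog (neutral-loss) search

For analog search the binning coordinate is the neutral loss
$\mathit{precursor} - mz$, so spectra of homologs whose fragments and
precursor share a constant mass offset align exactly. The sign convention
(neutral loss rather than $mz + \mathit{precursor}$) is this package's
choice: it makes equal losses align across different precursors, and a
`fixed` shift mode (`mz + \delta`) is available for any other convention.
`analog_score_all()` returns the regular result, the shifted result, and a
combined result whose score is the element-wise maximum of the two — a
conservative combination that reduces to each mode at its extremes — with
the match count taken from whichever term attained the maximum (ties go to
the regular term). Both raw matrices are always returned so modified-cosine
style combinations can be applied downstream.

## Numerical choices

* **Binning epsilon.** `bin_index()` computes
  `floor((mz / w) * (1 + 1e-9))`: values intended to be exact multiples of
  the bin width can fall one float ulp below the integer, and the relative
  epsilon lands them in the upper bin consistently. The test suite checks
  floor semantics against an exact rational-arithmetic oracle.
* **Count rounding.** Blurred count products are integral in exact
  arithmetic; they are rounded to the nearest integer to guard float drift.
  Counts are reported as computed, not capped at
  `min(n_frag_query, n_frag_ref)` — they are an approximation by design,
  and capping would hide the very deviation the precise re-score resolves.
* **Greedy tie-breaks.** Candidate pairs with equal intensity products are
  ordered by smaller m/z difference, then lower fragment index in the first
  spectrum, then in the second. Reference implementations differ in
  version-dependent ways here, so equivalence tests use spectra without
  constructed ties; on such data the scorer agrees with matchms'
  `CosineGreedy` to machine precision.
* **Degenerate inputs.** Empty spectra score 0 with 0 matches in the
  precise scorer and are excluded before matrix construction in the
  blur-and-link path; all-zero intensity vectors are an error at
  normalization (they must have been filtered); shifted coordinates that
  are not positive are dropped with a reported count.
* **Compact bin storage.** Matrices are stored over occupied bins only,
  with the absolute bin value kept per row and matrices re-indexed onto the
  union universe at scoring time. Bin indices up to ~2×10⁹ (bin width 10⁻⁶
  over m/z 2000) therefore cost nothing beyond the non-zeros.

## The synthetic generator

`random_library()` emulates centroided high-resolution spectra: fragment
m/z uniform over 50–2000 Da with sub-0.01 Da placement, intensities
exponential with mean 100 (a heavy-tailed stand-in for real fragment
intensity distributions — the exact law is not critical because the
properties being tested are distribution-free), 5–30 fragments per
spectrum, and a precursor placed above the largest fragment. The integer
seed drives R's RNG only, so output is reproducible across platforms.
`perturb_pair()` derives partners sharing a controlled fraction of
fragments with bounded m/z jitter and lognormal intensity noise; fresh
(unshared) fragments are kept at least 0.021 Da — beyond tolerance plus
jitter — from every original fragment so they never accidentally match.

Two regimes are used deliberately:

* `min_spacing = 2 × tolerance` with jitter ≤ `tolerance − bin_width` and
  grey-zone-free cross distances (`oracle_benchmark_sets()`): the
  multi-linking mechanism is absent by construction and blur-and-link must
  equal the precise scorer exactly. Offending fragments are redrawn until
  the conditions hold, so exactness is enforced, not hoped for.
* `min_spacing = 0` with jitter up to the full tolerance
  (`paired_libraries()`): realistic, unconstrained spectra on which the two
  scorers may disagree in the grey zone; agreement is then a rate.

What the generator does **not** emulate: chemically realistic fragmentation,
isotope envelopes, adducts, correlated noise between related compounds, or
the m/z clustering of real compound classes. Passing tests therefore show
the algorithm's analytic properties hold, not that any particular agreement
rate transfers quantitatively to a specific instrument or library.

## Problem sizes in the shipped suites

The packaged checks use sizes chosen to exercise every property at desk
scale: exact equivalence on 200 × 200 spectra (40,000 pairs), the ≥ 99%
agreement rate on 1,000 × 1,000 unconstrained spectra (~10⁶ pairs),
linkage brute force over 10⁵ random fragment pairs, and a bin-width sweep
over 10⁻⁵–9×10⁻³ Da on 150 × 150 pairs (a finer 10⁻⁶ start adds minutes of
blur time for no additional discrimination on these libraries — agreement
is already exact from 10⁻⁵ down).

## Known limitations

* Tolerance is absolute (Da); ppm-relative tolerance is not supported.
* Matching-ion counts are approximate whenever several ions share a
  tolerance window; use `rescore_hits()` where exact counts matter.
* Wide tolerances relative to fragment spacing inflate scores one-sidedly;
  the grey zone `(t − w, t]` is inherent to binned linking.
* Dense score matrices are returned; at 10⁴ × 10⁴ and beyond, write hits
  with thresholds (`write_scores()`) rather than holding full matrices.
* Only centroided data is supported, and only the MGF dialect described in
  `?read_mgf` is parsed.
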