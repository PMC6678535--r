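---
title: "Paired copy-number profiling of drug-resistant cell lines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired copy-number profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When a tumor cell line is driven to drug resistance by prolonged exposure
to a chemotherapeutic, the resistant derivative differs from its parental
line by a handful of *acquired* copy-number abnormalities (CNAs) — for
example, focal amplification of an efflux-pump locus such as
ABCB1/MDR1 — superimposed on the large load of aberrations the two lines
share. `cnadiff` implements a complete two-channel array-CGH workflow for
finding those acquired lesions in a paired design, together with the
pharmacological readout (IC50 and resistance index) that motivates the
comparison.

A hybridization measures, per probe, a test-channel (Cy5, tumor DNA) and
a reference-channel (Cy3, normal DNA) intensity; the quantity of interest
is the probe-level log2(Test/Ref) ratio, which is piecewise constant in
genomic position with level 0 at balanced copy number.

## Normalization

**Dye correction** ("Cy3 fitted over Cy5"): a robust local-linear loess of
log2(Cy3) on log2(Cy5) (span 0.3, degree 1, 3 robustness iterations)
estimates the intensity-dependent dye trend `f(a)`; the reference channel
is rescaled by `2^(a − f(a))`. Two numerical choices matter:

* The curve is fitted on a uniform-by-quantile subsample of at most
  20,000 probes and interpolated, which makes the fit O(1) in array size
  with negligible loss of precision.
* The curve is estimated on the central 99.5% of test intensities and
  extended **linearly** beyond them. Probes of a high-level amplification
  sit far outside the bulk intensity range and can locally dominate the
  extreme tail; without the extension the tail fit follows them and
  absorbs a visible fraction of their signal.

An inherent limitation remains: any correction conditioned on a
noise-carrying covariate shrinks true signal by the regression-to-the-mean
factor `sigma_eps^2 / sigma_brightness^2` (channel noise variance over
probe-brightness variance), about 1% of the aberration amplitude under
the synthetic generator's defaults. This is a property of
intensity-trend normalization itself, not of the implementation; it is
why recovered amplitudes of extreme amplifications (|log2| near 5) sit a
few hundredths below their true value.

**GC correction**: a loess of the log-ratio on probe GC fraction (same
settings), subtracted after centering the fitted curve, so the mean GC
effect is removed while the profile's level is preserved. The operation
is idempotent to within fit tolerance.

## Segmentation

Circular binary segmentation, implemented from first principles. Within
a segment of n probes, the candidate change is an arc (i, j]; with
centered cumulative sums `C` the two-sample statistic is
`|C[j] − C[i]| * sqrt(n / (k (n − k)))`, k = j − i. The arc maximizing
the statistic is accepted as a split iff its permutation p-value
(values permuted within the tested segment) is at most `alpha`, and the
procedure recurses on the resulting pieces, left to right.

* Defaults mirror the classical reference-tool defaults: `alpha` 0.01,
  minimum arc width 2, trimmed (2.5%) variance. `nperm` defaults to
  1,000 (the reference tool documents 10,000); at `alpha` 0.01 this
  still resolves the accept/reject boundary with a count of 10.
* The permutation test is *sequential*: permutations stop as soon as the
  exceedance count proves p > alpha. Accepted splits always use the full
  permutation budget.
* The per-permutation scan uses an exact branch-and-bound: for arc width
  k, no statistic can exceed `(max C − min C) * w_k`, and `w_k`
  decreases towards k = n/2, so widths are visited in decreasing-weight
  order and the scan stops at the first width whose bound falls below
  the observed statistic. This prunes ~99% of the work under the
  permutation null and is mathematically identical to the full scan —
  the test suite verifies exact agreement with an exhaustive O(n^2)
  oracle, including the permutation decisions, on 100 random arrays.
* Segments longer than 5,000 probes are scanned in overlapping 2,500
  probe windows (50% overlap). Focal CNAs (tens to hundreds of probes)
  are contained in a window; the permutation test uses the identical
  windowed statistic, so calibration is unaffected. Events wider than a
  window are still found through recursive splitting, but their
  statistic is evaluated window-locally; this is the one approximation
  in the segmentation and the reason correctness properties are tested
  on exhaustively scanned sizes.
* The statistic's scale factors out of both the argmax and the
  permutation comparison, so decisions are invariant to the variance
  estimate; the trimmed SD matters only for reporting.
* Ties in the scan resolve to the smallest i, then smallest j; all
  randomness flows from one integer seed through R's RNG, so runs are
  bit-reproducible.

## Centering and calling

A profile is centered on the *most centered of its three most populated
density peaks*: Gaussian KDE with Silverman bandwidth on a 2,048-point
grid, local maxima ranked by height, and among the top three the one
closest to zero is subtracted (closest to the profile mean under the
alternative `center_of_mass` rule; peak-level rather than segment-level
density is used, weighting by probe mass). The calling threshold is
one-fourth of the median absolute difference between consecutive probes
along the genome — a derivative-based noise estimate that ignores the
(rare) segment boundaries. For Gaussian noise of SD sigma it converges
to `sqrt(2) * qnorm(0.75) / 4 * sigma ≈ 0.2385 sigma`. The 23
inter-chromosome junction pairs are excluded by default (toggleable);
on a 180K array they shift the median by well under 0.1%. Calls are
strict: a segment mean exactly at ±threshold is neutral (with a 1e-9
guard so noiseless zero-mean segments are not called on float dust).

## The paired differential

Two profiles are first put on a common dynamics scale. Dynamics is the
IQR of probe values; the lower-dynamics profile is mapped onto the other
by OLS (`high ~ slope * low + intercept`) and replaced by the fitted
transform. Two refinements make this stable in the sparse-aberration
regime:

* The regression is fitted on **segment-mean expansions** (each probe
  represented by its CBS segment mean), not raw probe values: with focal
  aberrations covering <1% of the genome, raw-probe OLS is attenuated by
  `var_noise / (var_signal + var_noise)` to nearly zero, which would
  transfer every shared aberration into the difference profile.
* Probes whose segmental state (gain/neutral/loss relative to each
  profile's own calling threshold, after median-centering the
  expansions) *disagrees* between the profiles are excluded from the
  fit. The transform's purpose is to align the dynamic range of shared
  biology; discordant probes are precisely the candidate private lesions
  the comparison is meant to find, and they enter as high-leverage
  points if the dynamics ordering ever picks the resistant member as the
  one to rescale. With no concordant aberrant structure at all (two flat
  profiles) the transform degrades to a pure level shift.
* IQRs closer than 2% (relative) are treated as ties — the IQR's
  sampling resolution on a dense array is an order of magnitude below
  that — and resolve by sample-id order.

The difference profile (test − ref, positive = acquired gain, regardless
of which side was rescaled) is then segmented and called exactly like a
single-sample profile, with its calling threshold recomputed **from the
difference itself** (the rule is a function of a profile; the difference
is a profile; a flag allows inheriting the test or ref threshold
instead). Every non-neutral segment is reported with its mean
("Diff.l2r"), annotated with overlapping genes and cytobands (half-open
overlap, ≥1 bp), and sorted by |Diff.l2r|.

## Cross-sample structure

Profiles are clustered with Pearson distance (1 − r over shared probes)
and Ward aggregation (`hclust` method `ward.D2`), exportable as Newick.
Clustering is invariant to common affine rescaling. Cytoband enrichment
of a gene list is an upper-tail hypergeometric test per band with
Benjamini–Hochberg correction — a deliberately transparent stand-in for
web-service positional enrichment, not a reproduction of it; genes map
to every band they overlap.

## Dose-response and resistance index

Viability curves are fitted with the 4-parameter logistic
`response(d) = bottom + (top − bottom) / (1 + (d/ic50)^hill)` by
nonlinear least squares in log10-dose, multi-start over hill (0.5, 1, 2)
and a 7-point geometric IC50 grid, best residual sum of squares winning;
vehicle (dose 0) wells are excluded from the fit and `top`/`bottom` are
unconstrained. A fit is censored when the optimizer fails, the response
never falls, or the IC50 lands outside [min dose/10, max dose×10]; a
censored IC50 is a directional bound and propagates through the
resistance index `RI = IC50(resistant) / IC50(parental)` as a bound
(e.g. ">100"/0.04 → ">2500"); bounds on both sides are indeterminate.
The printed drug-sensitivity table shipped in `extdata` drives a worked
example in which fitting is bypassed entirely.

## The synthetic generator

`generate_design` spreads probes over 24 chromosomes in hg19 length
proportions (largest-remainder rounding, jittered spacing) with a smooth
sinusoidal GC field in [0.3, 0.7]. `simulate_pair` back-computes channel
intensities from a ground-truth CNA specification: reference = lognormal
base (log2 SD 1.6, emulating the orders-of-magnitude probe-affinity
spread of real arrays), test = reference × 2^(true log2), then a
quadratic GC bias, an intensity-dependent dye bias on the reference
channel (a smooth function of the test-channel intensity — the covariate
the dye correction conditions on; bias driven by other covariates leaves
residual errors at high-amplitude CNAs and is out of the emulated model
class), Gaussian log-space noise split evenly between channels
(log-ratio SD 0.25 by default), and a 0.1% rate of heavy-tailed (t, 3
df) outlier probes. Everything is deterministic given one seed, and the
truth table closes the loop for end-to-end validation.

What the generator does **not** emulate — and what passing tests
therefore do not certify on real data: spatial (sub-grid) artifacts,
probe-sequence-specific affinity beyond GC, wavy genomic baselines,
tumor heterogeneity/purity, and replicate probes. Adjacent heavy-tailed
outliers are genuinely significant under within-segment permutation and
occasionally yield a spurious 2-probe region; the classical remedy
(outlier smoothing before segmentation) is intentionally not applied, to
keep the segmentation auditable.

## Problem sizes and budgets

The shipped tests exercise the full 180K-probe scale where the claim
depends on it (paired differential recovery over 10 simulated pairs;
null differential over 20 pairs) and reduced sizes elsewhere (60-probe
arrays for exhaustive-oracle agreement; 60K probes for breakpoint
recovery over 3 replicates; 20K probes for clustering), sizes chosen so
the whole suite completes in minutes on a single core while keeping
every property at the scale where it is informative.

## Known limitations

* Amplitude shrinkage of ~1% of the aberration amplitude from
  intensity-conditioned normalization (see above).
* The windowed scan evaluates statistics window-locally for chromosomes
  beyond 5,000 probes.
* No ploidy/purity model: calls are relative to the density-peak center,
  not absolute copy numbers.
* The enrichment module is positional and hypergeometric only.
* Printed resistance indices in the source drug-sensitivity table are
  not all exact ratios of the printed IC50s (they were presumably
  computed from unrounded fits); only the self-consistent
  methotrexate/HOS row is used as a worked example.
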