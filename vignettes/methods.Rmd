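---
title: "Methods: calcium transient, wave, and expression analysis in icswave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium transient, wave, and expression analysis in icswave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

icswave analyses live GCaMP recordings of the cochlear sensory epithelium —
spontaneous Ca^2+^ transients in hair cells and supporting cells, and
intercellular Ca^2+^ signaling (ICS) waves that propagate across the
supporting-cell network — together with the qPCR readouts of the unfolded
protein response (UPR) that accompany noise exposure. This vignette explains
the models and procedures the package implements, the tunable parameters and
their defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the underlying conventions were open.

```{r setup, message = FALSE}
library(icswave)
library(dplyr)
```

## From movie to trace table

A recording is a single-channel time-lapse stack with a physical pixel size
(μm/px) and a fixed frame interval (s). Fluorescence is measured on a grid of
square regions of interest slightly larger than one cell: 56 × 56 px = 11 ×
11 μm at the default calibration of 0.1964 μm/px. `roi_grid()` tiles the
frame from the top-left corner and drops partial tiles at the right and
bottom edges; a 1400 × 728 px frame therefore yields 25 × 13 = 325 ROIs.
Tiling origin and edge handling are conventions, not physical facts; they
are fixed this way so that ROI counts and center coordinates are
deterministic. Pixel indices are 0-based and boxes are half-open, so ROI
centers — the coordinates used for all wave geometry — are unambiguous.
`extract_traces()` reduces the movie to the ROI × frame table of mean
intensities on which everything downstream operates, with frame 0 at t = 0.

## Baseline and the 10×SD detection threshold

A Ca^2+^ peak is an excursion of a trace above `F0 + k·σ`, with `k = 10` by
default. `F0` (baseline fluorescence) and `σ` (baseline SD) must be
estimated without contamination by the very transients being detected, and
without hand-labelling baseline windows. `estimate_baseline()` therefore
uses a robust location/scale estimate per ROI: `F0` is the median, `σ` is
1.4826 × the median absolute deviation (the consistent Gaussian scale
estimate), computed over frames surviving an iterative exclusion — frames
more than 5 robust SDs above the running median are dropped and the
estimate recomputed, twice. This is stable as long as roughly half the
frames are event-free. If fewer than `baseline_min_fraction` (default 20%)
of frames survive, the ROI falls back to the global median/MAD and is
flagged. A degenerate `σ = 0` is accepted only for exactly constant traces;
a zero robust scale on a non-constant trace is rejected as a degenerate
baseline rather than silently producing an infinite threshold.

One property of this estimator matters for interpretation: frames carrying
small residual signal (the low tail of an exponential decay, the foot of a
rise) sit below the exclusion cutoff and inflate the MAD slightly. On
densely active traces the detection threshold is therefore a few percent
higher than the nominal `10σ`, which makes detected rates conservative.
The validation suite measures this directly on synthetic traces.

## Events and their kinetics

`detect_peaks()` turns each maximal contiguous supra-threshold excursion
into one event. Excursions whose onsets fall closer together than
`min_separation` (default two frame intervals) are merged, limiting double
counting when noise dips a trace just below threshold between samples.
Onset and offset times are linearly interpolated between the bracketing
frames (`interpolate_crossings`, on by default), so event times are not
quantized to the frame grid. Events still above threshold at the end of the
recording are retained with `complete = FALSE`.

Kinetics follow the conventions of the recordings the package targets:

* **Rise time** — time from baseline to half-maximum: the interval between
  the last interpolated upward crossing of `F0` before the peak and the
  interpolated crossing of `F0 + amplitude/2` on the rising limb. For a
  noiseless linear ramp of duration R this equals R/2.
* **Decay time** — time from the peak to the interpolated downward crossing
  of the *detection threshold* `F0 + k·σ` that ends the event. "Return to
  baseline" is not otherwise operationalized; reusing the detection
  threshold keeps onset and offset symmetric and makes the quantity
  closed-form testable: an exponential decay from amplitude `A·σ` crosses
  the threshold `τ·ln(A/k)` after the peak — 27.2 s for A = 100, k = 10,
  τ = 11.81 s, and 2.52 s for τ = 1.094 s. Decays censored by the end of
  the recording are reported as lower bounds (`decay_censored`) and should
  be excluded from mean-decay summaries to avoid truncation bias.

Two systematic effects of this operationalization are worth knowing.
First, the detector has a dead time: two transients on one ROI whose
excursions overlap, or whose onsets fall within `min_separation`, count
once. For per-cell Poisson activity at rate r the detected rate is thinned
by roughly `1 − exp(−r·w)` with w the dead-time window; at the default
2-s frames this is several percent at r = 0.02 events/s. Any threshold
detector shares this property. Second, with noise the *first* downward
threshold crossing is an early-biased estimate of the noiseless crossing:
during a slow decay the trace spends many samples at small positive margin
above threshold, and the first negative noise fluctuation ends the event.
The bias scales inversely with how fast the decaying signal traverses the
noise band around the threshold, so it is negligible for fast decays
(τ ≈ 1 s at 0.1-s sampling) and of order a second for slow ones
(τ ≈ 12 s). The validation suite quantifies both effects against ground
truth.

Steady-state cytosolic Ca^2+^ is summarised by `steady_state()` as the
plain arithmetic mean of the raw trace over a fixed window, 300 s by
default. Rates are counts over the recording duration: `peak_rate()`
reports events/s over the whole field by default — the per-field
denominator is an assumption, exposed through the optional region map,
since regional rates (inner sulcus, hair-cell region, outer sulcus) are
also reported this way and sum to the field rate over disjoint regions.

## Intercellular waves

No published rule defines when two cell-level events belong to the same
ICS wave, so the package commits to the simplest order-invariant
operationalization: single-linkage connected components over the relation
*link two events iff their ROI centers are within `d_max` μm and their
onsets within `dt_max` s*. Defaults: `d_max` = 1.5 × the 11-μm ROI pitch =
16.5 μm (adjacent and diagonal neighbours link, skips do not), `dt_max` =
`d_max` / v_min with v_min = 5 μm/s → 3.3 s (slower propagation than
5 μm/s is treated as coincidence), and at least `min_members = 3` ROIs per
wave. Components below `min_members` stay isolated peaks and still count
toward peak rates. All three constants are exposed in `wave_params()`.

Per wave, the origin is the center of the earliest-onset member (ties
broken by lowest ROI index — a pure determinism device), the propagation
distance is the maximum member distance from the origin, and the speed
comes from the physically motivated regression: for radial propagation at
constant speed v, member lags satisfy `Δt = d / v`, so the speed is the
inverse of the origin-constrained least-squares slope
`b = Σ d·Δt / Σ d²`. This uses every member (robust to a single straggler)
and is exact on noiseless radial waves, where it agrees with the
(max distance)/(max lag) estimator. A non-positive slope (e.g. all members
simultaneous) leaves the speed undefined and flagged; undefined speeds are
excluded from mean-speed summaries rather than coerced. Per-wave speeds
are averaged across waves (rather than pooling all lag–distance points),
matching the per-wave reporting convention of the recordings.

## Fast versus slow hair-cell transients

Noise-evoked outer-hair-cell transients separate into a fast population
with no morphological change and a slow population accompanied by cell
swelling and fragmentation that precedes death. The package measures the
morphology directly from the movie: `track_cell_area()` segments the
cell's ROI cutout against a local background (median and SD of the ROI
border ring — local, hence robust to illumination gradients), keeps the
connected component overlapping the baseline centroid, and reports the
per-frame area, the maximum area relative to the baseline (median over
event-free baseline frames) area, and whether segmentation ever yields two
or more components after a single baseline component. For a disk that
swells linearly by factor s, the area ratio is s².

Because the numeric boundary between the two populations is only shown
graphically in the source recordings, classification uses an explicit
deterministic rule rather than a 2-means split: an event is **slow** iff
its cell's maximum area ratio reaches `area_cut` (default 1.2) or the cell
fragments; otherwise **fast**. The rule is total, order-invariant, and the
cut is configurable. `transient_prevalence()` reports, per label, the
fraction of *all* cells in the field (silent cells included in the
denominator) with at least one event of that label, as a percentage
rounded half-up to one decimal — base R's round-half-to-even would turn
13/80 = 16.25% into 16.2% instead of the conventional 16.3%.

## qPCR expression statistics

Relative expression uses the 2^−ΔCt^ method against a reference gene
(Gapdh by default): `2^−(Ct_gene − Ct_ref)`. Samples with inadequate
reference signal (reference Ct > 24) are excluded with a logged reason.
Fold changes divide each sample by the *arithmetic* mean of the control
group's relative expression, per gene, so control folds average exactly 1
(the geometric mean would not reproduce control bars at 1). The
Chop/S-Xbp1 ratio — an index of the UPR's shift toward its proapoptotic
arm — is computed per sample and is algebraically independent of the
reference gene. Whether panel bars averaged 2^−ΔCt^ values before or after
log transformation is not documented anywhere authoritative; the
arithmetic domain is assumed throughout.

Outlier removal adapts the ROUT idea (robust fit + FDR-controlled calls at
q = 1%) to a univariate group column, since the original method is defined
for robust regression: the robust center is the median, the robust scale
(RSDR) is the 68.27th percentile of absolute residuals with the small-n
correction n/(n−1), each point's studentized residual gets a two-tailed
t p-value on n − 1 degrees of freedom, and Benjamini–Hochberg at level q
flags outliers, removed in one pass. Groups smaller than 5 are never
touched. This preserves the method's intent without reverse-engineering a
proprietary implementation; under a clean normal null at n = 20 it removes
nothing in well over 95% of samples.

Group comparisons follow the standard dispatch: Shapiro–Wilk normality per
group at α = 0.05; two groups → Student's t (all normal) or Mann–Whitney
rank-sum (otherwise, and for zero-variance groups, where the normal-theory
path is undefined; ties are handled by the normal approximation); more
than two groups → one-way ANOVA with Dunnett's multiple comparisons
against the designated control (via multcomp). The per-gene panel
workflow is the composition `relative_expression() |> fold_vs_control()`
plus per-gene two-tailed t tests of the 2^−ΔCt^ values; no multiple-testing
correction is applied across panel genes by default, mirroring per-gene
reporting, with a BH option available.

## What the synthetic generator emulates — and what it does not

`generate_traces()` / `generate_movie()` simulate a field of labelled
cells with exact ground truth, so every pipeline stage can be validated
without raw recordings:

* static cell layout; baseline fluorescence plus i.i.d. Gaussian noise
  (per ROI sample at trace level, per pixel at movie level);
* spontaneous transients per cell as independent Poisson processes, with a
  linear rise and single-exponential decay — the simplest waveform
  consistent with observed transient shapes, with every kinetic parameter
  exposed;
* ICS waves as radial propagation at constant speed from point initiation
  sites with a hard radius cutoff, each member activated at exactly
  `start + distance/speed` (the geometry behind the lag–distance
  regression; wavefront curvature is not modelled);
* rare slow transients with linear radius growth to `swell_factor` over
  the rise and fragmentation into two disjoint half-area blobs after the
  peak — just enough morphology to exercise the area/fragmentation
  classifier, with no claim to cytological realism.

Defaults mirror the recording conditions: 2-s frame interval, 11-μm ROI
pitch, wave speeds of order 15–30 μm/s, amplitudes expressed in multiples
of the noise SD (default 20, twice the detection threshold). Because no
amplitude distribution is published for real events, amplitudes are a
convention, not an estimate. The default rise duration is 2 s: at the
default 2-s frame interval a transient must dwell above threshold for at
least about one frame to be observable at all, which requires
`rise/2 + τ·ln(amplitude/k) ≥ Δt`; a 2-s rise satisfies this for the
default amplitude and decay while remaining in the physiological range for
these indicators. Reproducibility is per-entity: every cell, wave site,
and frame draws from its own deterministic substream of the master seed,
so adding a cell never perturbs the draws of existing ones.

Not emulated: photophysics (bleaching, indicator binding kinetics),
optical point-spread, motion artifacts, ATP/connexin signalling mechanism,
or any relationship between Ca^2+^ activity and the UPR readouts. Passing
recovery tests on this generator therefore demonstrates that the
*measurement pipeline* is correct and calibrated — not that real cochlear
data meet the generator's assumptions.

## Problem sizes and numerical choices in the validation suite

The recovery studies shipped with the package use sizes chosen to make
Monte-Carlo error small relative to the quantities checked while staying
desk-scale: 20 noiseless 8-ROI chains for speed recovery; 10-seed Poisson
simulations for rates (6 sites × 0.005 events/s over 3000 s and 40 sites
over 600 s for waves; 95 × 0.02/s and 75 × 0.01/s over 600 s for peaks);
50 and 100 planted transients on long records (1800 s and 300 s at 0.1-s
sampling) for decay recovery — records are kept long so the decay tail
contaminates the robust baseline negligibly; and the 80-cell field (7
fast, 13 slow, 60 silent) for the classification worked example.
`scripts/acceptance.R` re-runs all of these from scratch.

Degenerate inputs are handled explicitly rather than propagated: empty
event lists cluster to empty wave tables; all-simultaneous waves get
flagged undefined speeds; constant traces yield `σ = 0` and no events;
zero-variance comparison groups route to the rank test; sub-minimum
outlier groups are returned untouched.

## Known limitations

* Detected event rates are conservative for overlapping activity (detector
  dead time) and decay times of slow transients are slightly early-biased
  under noise (first-crossing estimation); both effects are quantified
  against ground truth in the validation suite and should be kept in mind
  when comparing absolute rates across conditions with very different
  activity levels.
* Input movies are assumed oriented and registered; drift correction,
  bleach correction and background subtraction are out of scope.
* The wave-identification rule and the fast/slow area cut are declared
  conventions; conclusions that depend sensitively on them should be
  checked across a range of `wave_params()` / `classify_params()`.
* Longer-duration, slower organ-level wave phenomena than the radial
  waves modelled here are outside the detector's design envelope.
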