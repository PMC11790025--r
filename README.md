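# icswave

Analysis of live calcium imaging and stress-gene expression in the cochlear
sensory epithelium.

Loud noise perturbs Ca²⁺ homeostasis in the hearing organ: hair cells show
cytosolic Ca²⁺ transients — some of them "slow" transients that accompany
cell swelling, fragmentation and death — and supporting cells launch
intercellular Ca²⁺ signaling (ICS) waves that propagate across the
epithelium at tens of μm/s. The same exposures activate the unfolded
protein response (UPR), whose proapoptotic shift is indexed by the
*Chop*/*S-Xbp1* expression ratio. icswave implements the quantitative
pipeline for both readouts, for labs doing GCaMP imaging of cochlear (or
similar epithelial) preparations and qPCR panels of stress markers.

## What it computes

**Imaging.** A movie (frames × H × W, pixel size in μm/px, frame interval
Δt) is reduced to a grid of square ROIs (56 × 56 px = 11 × 11 μm; a
1400 × 728 px frame gives the canonical 325 ROIs) and per-ROI mean
fluorescence traces F(t). Per ROI, a robust baseline F₀ (median) and
baseline SD σ (1.4826 × MAD, after iterative exclusion of supra-baseline
frames) define the detection threshold

    F(t) > F₀ + k·σ,  k = 10,

and each maximal supra-threshold excursion is one Ca²⁺ event with
interpolated onset, peak amplitude ΔF = F_max − F₀, rise time (baseline to
half-maximum) and decay time (peak to the interpolated return below the
threshold; for an exponential decay with constant τ from amplitude A·σ this
equals τ·ln(A/k)). Events are clustered into ICS waves by single-linkage on
(distance ≤ d_max) ∧ (onset gap ≤ dt_max); each wave's speed is the inverse
of the origin-constrained least-squares slope of member lag on distance
(Δt = d/v), its distance the maximal member distance from the origin. Rates
are events/s and waves/s over the recording. Hair-cell transients are
classified **fast** vs **slow** from segmented cell-area dynamics
(max area ratio ≥ 1.2 or fragmentation → slow), with per-label prevalence
over all cells.

**Expression.** Relative expression by the 2^−ΔCt method versus *Gapdh*
(samples with *Gapdh* Ct > 24 excluded), fold change versus the unexposed
control-group mean, per-sample *Chop*/*S-Xbp1* ratio, ROUT-style robust
outlier removal at q = 1%, and normality-dispatched group comparisons
(Shapiro–Wilk, then Student's t / Mann–Whitney / one-way ANOVA + Dunnett).

A synthetic-data generator (`generate_traces()`, `generate_movie()`)
produces recordings with exact ground truth — Poisson transients, radial
waves activated at exactly d/v, slow transients with swelling and
fragmentation — so every stage is testable without raw data.

## Worked example

Simulate a supporting-cell field with one wave-initiation site, detect
events, and cluster waves:

```r
library(icswave)
library(dplyr)

cfg <- synth_config(
  560, 280, duration = 600,                 # 10 x 5 ROI field, 10 min
  cells = cell_grid(560, 280),              # confluent cell sheet
  wave_sites = tibble(x_um = 55, y_um = 27.5),
  wave_site_rate = 0.01, wave_speed = 15.5, wave_radius = 44,
  seed = 8
)
rec      <- generate_traces(cfg)
baseline <- estimate_baseline(rec$traces)
events   <- detect_events(rec$traces, baseline)
waves    <- cluster_waves(events, rec$grid)

events |> select(roi, onset_s, peak_s, amp_ratio, rise_s, decay_s) |> head(3)
#>     roi onset_s peak_s amp_ratio rise_s decay_s
#> 1    26    35.0     36      22.2  0.952    2.11
#> 2    25    35.1     36      18.6  0.990    1.44
#> 3    36    35.3     36      15.1  6.60     2.47

waves |> select(wave_id, start_s, n_members, speed_um_s, distance_um)
#>   wave_id start_s n_members speed_um_s distance_um
#> 1       1    35.0        35       16.4        45.4
#> 2       2   204.         36       18.7        45.4
#> 3       3   265.         36       17.8        45.4
#> 4       4   320.         36       17.2        45.4
#> 5       5   551.         36       14.7        45.4

peak_rate(events, 600)   # 179 events -> 0.298 peaks/s over the field
wave_rate(waves, 600)    # 5 waves    -> 0.00833 waves/s
```

Five waves fired from the site (rate 0.01/s × 600 s, minus coincidence
losses), each recruiting the ~36 cells within its 44-μm radius; per-wave
speed estimates scatter around the generating 15.5 μm/s (onset
interpolation at a 2-s frame interval adds a few μm/s of per-wave error;
on noiseless lag–distance chains the estimator is exact):

```r
sim <- sim_wave_chains(20, 8, lag_s = 0.3943)   # 11-um steps at 27.9 um/s
wv  <- cluster_waves(sim$events, sim$grid)
signif(mean(wv$speed_um_s), 3)
#> [1] 27.9
```

Expression analysis of a simulated Ct table (12 animals, 4 genes, the
106-dB group's *Chop* shifted −1 cycle ⇒ 2-fold):

```r
set.seed(3)
ct <- tibble(
  animal_id = rep(1:12, each = 4),
  group     = rep(c("CTL", "106dB"), each = 24),
  gene      = rep(c("Gapdh", "BiP", "Chop", "S-Xbp1"), 12),
  ct        = c(rbind(rnorm(12, 20, 0.3), rnorm(12, 24, 0.4),
                      rnorm(12, 26, 0.4) - rep(c(0, 1), each = 6),
                      rnorm(12, 25, 0.4)))
)
expr <- relative_expression(ct)               # 2^-(Ct_gene - Ct_Gapdh)
upr_panel(ct, control = "CTL")
#>     gene group fold p_value n_control n_group
#> 1    BiP 106dB 1.06 0.70703         6       6
#> 2   Chop 106dB 1.72 0.00351         6       6
#> 3 S-Xbp1 106dB 1.25 0.49637         6       6

compare_groups(expression_ratio(expr), ratio, group, control = "CTL")
#> <group_comparison> Student's t test: statistic = 2.2, p = 0.05243
```

`plot_traces()`, `plot_wave_fit()` and `plot_expression()` draw the
corresponding diagnostics; `tidy()`/`glance()` tidy the comparison objects.
A thin CLI (`exec/icswave`) exposes `simulate`, `extract`, `detect`,
`waves` and `qpcr` subcommands over the same functions.

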