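# laminarec

Layer-resolved stability analysis of chronic intracortical recordings and
depth-tracked histology of the surrounding tissue response.

## The problem

Chronic microelectrode implants degrade: impedance rises in the first
week, signal-to-noise falls over months, and neurons are lost around the
device track. When a single-shank probe spans all cortical layers
(L1–L6), every one of these effects can depend on *depth* — which layer a
site sits in determines its spike amplitude, how long it stays active, and
how much neuronal loss surrounds it. `laminarec` provides the full
analysis chain for such studies, for electrophysiologists and
neural-interface engineers:

* **Spike pipeline** — 250 Hz–3 kHz first-order Butterworth (zero-phase),
  robust noise level `σ_N = median(|x|)/0.675`, invalidation of
  simultaneous high-amplitude artifacts, detection at `−4σ_N`, PCA +
  k-means unit sorting with silhouette model selection, unit acceptance at
  ≥200 spikes, amplitude and `SNR = μ_pp/(2σ_N)` per unit, and per-channel
  active-site summaries.
* **Impedance** — complex-plane averaging of repeated EIS sweeps
  (10 Hz–100 kHz), 1 kHz magnitude/phase extraction, percent change over
  days.
* **Depth-tracked histology** — serial 20 µm sections distributed
  cyclically over slides so that slide identity + slice position recover
  cortical depth (slide 1/slice 1 ↦ 0–20 µm, slide 2/slice 1 ↦ 20–40 µm);
  a trainable pixel classifier (single-hidden-layer perceptron) segments
  NeuN-stained nuclei; 25 µm concentric rings around the explanted device
  hole yield density and circularity (`4πA/P²`) profiles; nuclei-free
  cell-loss area is estimated per depth, manually (traced ROIs, averaged
  over evaluators) or automatically (nearest-nuclei order statistics
  against the far-field density).
* **Laminar statistics** — layer binning over half-open depth intervals,
  one-way ANOVA with Dunn–Bonferroni pairwise t-tests (Tukey HSD
  optional), ANCOVA with time (interaction F), Kruskal–Wallis/Wilcoxon
  with Shapiro–Wilk and Levene checks, linear and loess depth trends.
* **Synthetic generators** — seeded simulators of multichannel sessions,
  longitudinal studies (linear SNR decay, layer-specific site survival),
  EIS sweeps (Randles-style circuit with a first-week magnitude schedule),
  and histology phantom stacks (tapering elliptical hole, mid-cortex kill
  zone, bimodal L4/L6 nuclei density, elongation increasing toward the
  hole) — every generator returns exact ground truth for parameter
  recovery.

Everything is tibble-first and pipe-friendly; fitted statistics expose
`tidy()`/`glance()` methods and results have `plot_*()`/`autoplot()`
helpers.

## Worked example

Simulate a two-week, 16-channel study, run the spike pipeline, and fit the
laminar amplitude gradient:

```r
library(laminarec)
library(dplyr)

design  <- study_design(session_weeks = c(1, 2))
study   <- simulate_study(design, rates_hz = 30, duration_s = 4, seed = 1)
metrics <- process_study(study$sessions, min_spikes = 50)
head(metrics, 8)
#> # A tibble: 8 × 9
#>   channel depth_um layer  week active n_units mean_amp_uv wf_amp_raw_uv   snr
#>     <int>    <dbl> <chr> <dbl> <lgl>    <int>       <dbl>         <dbl> <dbl>
#> 1       1       50 L1        1 TRUE         1        61.1          61.1  5.59
#> 2       2      150 L2/3      1 TRUE         1        61.7          63.3  5.79
#> 3       3      250 L2/3      1 TRUE         1        64.3          66.0  5.94
#> 4       4      350 L2/3      1 TRUE         1        66.0          69.9  6.11
#> 5       5      450 L2/3      1 TRUE         1        65.8          66.0  6.02
#> 6       6      550 L2/3      1 TRUE         1        66.0          67.7  6.08
#> 7       7      650 L4        1 TRUE         1        68.4          69.1  6.30
#> 8       8      750 L4        1 TRUE         1        69.8          71.3  6.43
```

One row per channel per session: its layer, whether it carried an accepted
unit (`active`), the classic per-spike amplitude and SNR on the filtered
trace (`mean_amp_uv`, `snr`), and the average-waveform amplitude on the
wideband trace (`wf_amp_raw_uv`) used for depth fits.

```r
metrics |>
  filter(active) |>
  group_by(depth_um) |>
  summarise(amp = mean(wf_amp_raw_uv)) |>
  piecewise_depth_fit("amp", breakpoint_um = 1050)
#> # A tibble: 2 × 3
#>   segment slope_per_mm     n
#>   <chr>          <dbl> <int>
#> 1 rising          13.3    11
#> 2 falling        -25.1    6
```

The generator's amplitude profile rises at 13.9 µV/mm to a 1,050 µm peak
and falls at −31.6 µV/mm below it; a single simulated subject recovers the
rising slope closely and the falling slope within the noise of six depth
points (the test suite pools six subjects for the calibrated recovery).

Impedance and shape metrics follow the same pattern:

```r
eis_summary(simulate_eis(day = 1, n_repeats = 3, noise_frac = 0.02))
#> # A tibble: 1 × 4
#>   channel   day mag_1khz_ohm phase_1khz_deg
#>     <dbl> <dbl>        <dbl>          <dbl>
#> 1       1     1      198532.          -67.0

percent_change(195.6, 1135.8)   # first-week 1 kHz magnitude rise, percent
#> [1] 480.6748

circularity(pi * 7^2, 2 * pi * 7)  # a perfect circle
#> [1] 1
```

For histology, `simulate_stack()` renders a depth-tagged phantom stack,
`process_stack()` trains the pixel classifier on ~5 % of slices and
segments the rest, and `stack_profile()` returns the depth-indexed
cell-loss, density and circularity profiles with the depth of peak loss.

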