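---
title: "Layer-resolved recording stability and depth-tracked histology: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-resolved recording stability and depth-tracked histology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`laminarec` implements an analysis pipeline for chronic laminar
microelectrode studies: a single-shank probe whose recording sites span the
cortical depth, recorded longitudinally after implantation, followed by
serial-section histology of the tissue around the explanted device. The
package has five parts:

1. **Spike-band electrophysiology** — filtering, robust noise estimation,
   artifact invalidation, threshold detection, PCA/k-means unit sorting,
   amplitude/SNR metrics, and per-channel activity summaries.
2. **Impedance spectroscopy** — averaging of repeated sweeps, 1 kHz
   magnitude/phase extraction, and longitudinal change.
3. **Depth-tracked histology** — slide/position depth tracking of serial
   sections, trainable pixel classification of neuronal nuclei,
   concentric-ring density and circularity profiles, and neuronal
   cell-loss area estimation.
4. **Laminar statistics** — layer binning, one-way ANOVA with pairwise
   Bonferroni-adjusted t-tests (or Tukey HSD), ANCOVA with time,
   Kruskal–Wallis/Wilcoxon with Shapiro–Wilk and Levene assumption checks,
   and linear or loess depth trends.
5. **Synthetic data generators** — seeded simulators of recordings,
   impedance sweeps, and histology stacks with known ground truth, so the
   whole pipeline can be validated by parameter recovery.

No animal data ship with the package; every analysis stage is exercised
against the generators.

# Electrophysiology model

## Signal chain

Raw voltages are band-pass filtered at 250 Hz – 3 kHz with a first-order
Butterworth filter. The filter is applied forward and backward
(`signal::filtfilt`), so it is zero-phase: detected trough times are not
shifted by filter delay. A first-order band-pass is deliberately gentle;
its passband is soft enough that even fully in-band spikes lose a few
percent of their amplitude (see *Amplitude estimators* below).

The noise level of a trace is the robust estimator

$$\sigma_N = \frac{\mathrm{median}(|x|)}{0.675},$$

which equals the standard deviation for Gaussian noise (0.675 is the
Gaussian quartile) and is nearly insensitive to the spikes riding on it, as
long as spikes occupy a small fraction of samples. This breaks down when
spikes occupy more than roughly 15 % of samples — worth keeping in mind
when simulating very short, very dense sessions.

Samples exceeding 90 % of a channel's session peak simultaneously on at
least two channels (within a 1 ms window) are treated as motion or
stimulation artifacts, and the window is masked on all channels. Both the
window and the channel count are configurable.

Spikes are negative-going crossings of $-4\sigma_N$ (extracellular somatic
spikes are downward deflections); events closer than 1 ms are merged,
keeping the deeper trough. Note that a $4\sigma$ threshold on a long
Gaussian trace *will* produce a handful of isolated false crossings — at
24.4 kHz, a few per minute. These are not suppressed at the detection
stage; they are eliminated downstream by the spike-count acceptance rule.

Snippets (0.6 ms before to 1.0 ms after the trough) are projected onto
their first three principal components and scanned with k-means for
$k = 1,\dots,5$ (fixed seed, ten restarts). The cluster count is chosen by
mean silhouette width, with $k = 1$ whenever the best silhouette falls
below 0.5; ties break toward smaller $k$. Units with fewer than 200 spikes
are excluded from analysis (the acceptance rule for a five-minute session;
tests on shorter synthetic sessions scale this down explicitly). A channel
is *active* in a session when it carries at least one accepted unit.

## Amplitude estimators

The unit SNR follows the classic definition
$\mathrm{SNR} = \mu_{pp} / (2\sigma_N)$ with $\mu_{pp}$ the mean over
spikes of each snippet's peak-to-peak excursion, both measured on the
filtered trace. Two properties of $\mu_{pp}$ matter when it is used for
*laminar amplitude gradients*:

* per-spike extremes are biased upward by noise, and the bias is larger
  (relative and absolute) for weak units, which flattens amplitude-depth
  gradients by an amount that is material at SNR ≈ 2–3;
* the first-order band-pass removes ~5 % of even a well-matched spike's
  amplitude.

The pipeline therefore also reports `wf_amp_raw_uv`: the peak-to-peak
amplitude of the unit's *average* waveform, measured on the wideband trace
at the sorted spike times, with snippets realigned to the unit average by
cross-correlation (integer shifts, one pass) before averaging. Noise
cancels in the average, realignment removes the align-on-noisy-minimum
bias, and the wideband trace avoids filter droop. Depth-profile fits in
the package's own validation use this estimator; `mean_amp_uv`/`snr` keep
the classic definitions.

# Synthetic recordings

`simulate_session()` builds each channel as white Gaussian noise plus an
analytic biphasic template at Poisson spike times with a 1 ms refractory
period. The template is a Gaussian-windowed ~950 Hz wavelet (1.5 ms
support, trough before after-potential, unit trough-to-peak), with 70 % of
the excursion carried by the trough. Two considerations fix this shape:
its spectrum sits inside the 250 Hz–3 kHz band (a template with
substantial out-of-band energy loses up to 10 % of its amplitude in the
filter, which would contaminate every amplitude recovery test), and the
trough-dominant asymmetry keeps units detectable at a $4\sigma$ threshold
down to SNR ≈ 1.3–1.5, the regime actually observed at chronic time
points.

Amplitude versus depth is piecewise linear: rising at 13.9 µV/mm from the
pial surface to a 1,050 µm peak, falling at −31.6 µV/mm below it, with a
60 µV surface amplitude — values chosen to emulate the laminar amplitude
profile of a 16-site, 100 µm-pitch probe inserted 1,600 µm (sites at
50–1,550 µm, 24,414 Hz sampling). The generator returns exact ground
truth (spike trough indices, per-channel template amplitudes), so the
profile is recoverable to machine precision from noiseless sessions.

`simulate_session()`'s default noise is 5 µV — a clean early-implant noise
floor. `simulate_study()` instead drives noise from an SNR schedule: the
population-mean SNR declines linearly at `decay_per_month` (−0.338 by
default, from 2.74 at week 0; months = weeks × 7 / 30.44), implemented as
noise growth with stable amplitudes, matching the empirical pattern of
stable spike amplitude but falling SNR. Channels drop out permanently with
layer-specific exponential survival (half-lives in weeks; defaults give
L4/L5 the longest survival). Both the weekly noise and each channel's
survival are part of the returned ground truth.

# Synthetic impedance

`simulate_eis()` evaluates a Randles-style equivalent circuit — series
solution resistance plus a charge-transfer resistance in parallel with a
constant-phase element — over a 10 Hz–100 kHz logarithmic grid. No
mechanistic circuit is being reproduced here; the circuit is plumbing
whose purpose is Nyquist-shaped curves with a controllable 1 kHz
magnitude. A day schedule rescales the
interfacial branch so the 1 kHz magnitude interpolates log-linearly from
195.6 kΩ (day 1) to 1,135.8 kΩ (day 7), reproducing the ~5.8-fold (+481 %)
first-week rise. Repeats are averaged **in the complex plane** (not in
magnitude/phase separately): complex averaging preserves Nyquist geometry
and is the natural reading of "averaged" for vector-valued sweeps. The
1 kHz value is read at the grid point nearest in log-frequency, with
log-log interpolation available; on the smooth synthetic curve the two
differ by well under 1 %.

# Depth-tracked histology

## Depth tracker

Serial sections of thickness $t$ are distributed cyclically across $S$
slides. Slice $i$ (1-based) lands on slide $((i-1) \bmod S) + 1$ at
position $\lfloor (i-1)/S \rfloor + 1$, and conversely a tag (slide $s$,
position $p$) maps to the serial index $i = (p-1)S + s$ and the half-open
depth interval $[(i-1)t,\, it)$ µm. With 20 µm sections the first slice of
slide 1 is 0–20 µm and the first slice of slide 2 is 20–40 µm. The number
of slides per cycle is configurable (default 10); only the
slices-per-slide count (8) is fixed by the acquisition protocol being
emulated. The mapping is a bijection — property-tested over layouts up to
20 × 20.

## Phantom

`histo_phantom()` renders grayscale NeuN-like slices: an elliptical
zero-intensity device hole at the centre whose half-axes taper
monotonically with depth (the probe narrows toward its tip), a
nuclei-free *kill zone* of configurable radius around the hole centre
(default peaking at 200 µm at 600 µm depth over a 60 µm baseline), and
nuclei placed by a hard-core Poisson process at a depth-dependent density
(default bimodal with peaks centred in the L4 and L6 intervals). The
hard-core constraint — minimum centroid separation of one nucleus diameter
plus two pixels — replaces a pure Poisson process because nuclei are solid
bodies; at cortical densities a pure Poisson process would overlap most
nuclei, and per-nucleus segmentation scores would measure overlap rather
than segmentation.

Each nucleus is an area-preserving ellipse (7 µm equivalent radius) whose
true circularity increases with distance from the hole at
`elongation_gradient` (default 0.079 units/mm, reaching 1 at 600 µm) —
surviving neurons near the device are more elongated. The axis ratio that
realises a target circularity is solved from Ramanujan's ellipse-perimeter
approximation. Rendering is at 1 µm/px over an 800 × 800 px field,
matching 10× fluorescence imaging; at coarser grids (≥ 2 µm/px) the minor
axis of an elongated nucleus spans under 3 px and *any* contour-based
circularity saturates — a resolution artifact, not a pipeline property.

## Segmentation

Slices are preprocessed (intensities normalised to [0, 1], Gaussian blur
of 1 px, 0.2 % contrast stretch split between the tails; 8-bit
quantisation is left to image I/O). A single-hidden-layer perceptron
(`nnet`, 4 hidden units, seeded) maps a small documented feature stack —
raw intensity, Gaussian smoothings at 1 and 2 px, gradient magnitude — to
per-pixel nucleus probability. Training pixels are drawn balanced from
roughly 5 % of slices at random depths, mirroring the
annotate-a-few-sections workflow. The probability map is thresholded at
0.5, components below 20 µm² are removed, and touching nuclei can
optionally be split by a watershed on the distance map (off by default).

Each region is measured on a smoothed marching-squares contour
(`grDevices::contourLines` at level 0.5): pixel-edge perimeters would
inflate the perimeter and bias circularity low. The smoothing scale adapts
to region size — 0.7 px for nucleus-sized regions (heavier smoothing
erodes high-curvature tips and compresses the circularity scale), up to
2.5 px for large regions where the staircase must be fully suppressed.
Circularity is $4\pi A / P^2$, clipped at 1.

## Rings and cell loss

Nuclei are binned by the distance from their centroid to the *hole
boundary* (not its centre — the hole is elongated) into half-open 25 µm
concentric rings; counts and per-ring circularity summaries form the ring
profile. Ring counts conserve the total nuclei within the outermost ring.

Cell-loss area supports the manual convention — per-evaluator traced
polygons, shoelace areas, averaged across evaluators, hole included — and
an automatic estimator. The obvious automatic design, a binned radial
density profile thresholded at 50 % of far-field, turned out to be
Poisson-limited: at cortical densities a 20 µm annulus at the zone
boundary holds ~20 expected nuclei, and the crossing point carries >10 %
area error on a single slice even with perfect segmentation. The shipped
estimator therefore uses the nearest-nuclei order statistics: outside a
nuclei-free disc of radius $r_0$ in a field of density $\lambda$, the
$j$-th smallest centroid distance satisfies
$E[d_{(j)}^2] = r_0^2 + j/(\pi\lambda)$, so the median of
$d_{(j)}^2 - j/(\pi\lambda)$ over the first five $j$ (with $\lambda$
measured on the outermost annuli) estimates $r_0^2$ essentially without
bias, robust to a stray nucleus or two, at 2–5 % area accuracy for zones
above ~120 µm radius. The reported area is $\pi \hat r^2$, hole included.
Below ~120 µm radius only a handful of nuclei border the zone and *no*
counting estimator reaches 10 % from one slice; recovery tests assert the
10 % bound where the zone is resolvable and the peak location (±100 µm)
on the smoothed profile everywhere.

`stack_profile()` joins per-slice results on depth-interval midpoints,
attaches layer labels, and smooths the profiles with loess (quadratic
local fits), reporting the depth of the smoothed loss maximum and the
local maxima of the density profile. The loss and circularity profiles
use a span of 0.5 (a single broad peak); the density profile uses 0.25,
because laminar density structure lives on ~200–300 µm scales and a
0.5-span smooth erases the L6 peak.

# Laminar statistics

The default layer map for rat S1 is L1 [0, 150), L2/3 [150, 600),
L4 [600, 950), L5 [950, 1350), L6 [1350, 1600) µm — boundaries anchored to
descriptive laminar cues (the cell-loss peak near 600 µm at the L2/3–L4
transition; the amplitude peak near 1,050 µm in L5); they are defaults,
not measurements, and every function takes an arbitrary `layer_map()`.
Depths on an internal boundary belong to the deeper layer (half-open
intervals, used consistently everywhere).

`layer_anova()` runs one-way ANOVA with pairwise pooled-variance t-tests
under Bonferroni adjustment ($p_{adj} = \min(1, m\,p)$) by default — Tukey
HSD is the alternative — because the pairwise comparisons being emulated
are Dunn–Bonferroni-corrected t-tests, while Tukey appears as the named
post hoc; both are provided. `ancova_time()` fits
`metric ~ layer * time` and reports the interaction F-test (identical to
the full-vs-reduced comparison). `nonparam_tests()` bundles
Kruskal–Wallis, pairwise Wilcoxon rank-sum, and the Shapiro–Wilk/Levene
checks that gate the parametric path. `depth_trend()` returns
least-squares slopes per mm over a stated depth range, or a loess smooth
with its argmax. All F statistics are tested against explicit
sum-of-squares oracles to 10⁻⁸ relative error, and type-I error rates are
verified at 0.05 ± 0.02 under seeded null simulations (1,000 replicates).

Slopes "per month" use months = weeks × 7 / 30.44.

# Problem sizes in the test suite

Validation runs are sized for a single CPU:

* amplitude-slope recovery: six subjects, week 1–2 sessions of 4 s at
  30 spikes/s, acceptance rule scaled to 50 spikes;
* survival-ranking recovery: 100 single-subject studies (10 sessions of
  1 s at 40 spikes/s, 25-spike rule, single-unit sorting), each compared
  with that run's realised ground-truth ranking;
* histology recovery: one 80-slice stack (20 µm sections, 10 slides per
  cycle, 8 per slide) at 800 × 800 px, 1 µm/px;
* statistics: 1,000-replicate null simulations.

# Limitations

* The generators emulate the *statistical structure* of a laminar implant
  study, not its biophysics: no LFP or correlated noise, one template per
  channel, white noise, elliptical nuclei, no staining gradients or
  vignetting. Passing recovery tests demonstrates the pipeline's
  correctness on data with known truth, not performance on real tissue.
* The unit sorter is a transparent re-specification (PCA + k-means with
  silhouette selection), not a reproduction of any commercial sorter.
* SNR conventions: the generator's ground-truth SNR is defined on the
  wideband signal; the pipeline's reported SNR follows the filtered-signal
  convention. The two differ by a fixed factor for a fixed template and
  band, which cancels in trends but matters for absolute comparisons.
* Equivalent-circuit parameters of the impedance phantom are illustrative;
  no circuit fitting of real sweeps is provided.
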