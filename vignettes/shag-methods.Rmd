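---
title: "Delay-sorted carpet plots: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay-sorted carpet plots: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shagcarpet)
```

## The model

A carpet plot is the voxels × time matrix of z-scored BOLD intensity.
`shagcarpet` sorts its rows by an estimate of each voxel's signal-arrival
delay, so that any intensity event shared across voxels — a gadolinium
bolus, a systemic low-frequency oscillation (sLFO), a CO₂-driven
vasodilation — appears as a tilted edge. If the event reaches the
earliest-arriving row at time $t_0$ and the latest at $t_0 + \Delta$, the
edge's breakpoints $(r, t_r)$ over delay-ascending rank $r$ follow
$t_r \approx \beta_0 + \beta_1 r$, and the **transit time**
$\hat\Delta = \beta_1 (R-1)$ estimates how long the event took to traverse
all $R$ sorted rows.

The chain of estimators is:

1. **Scaling.** Each voxel row is demeaned and divided by its standard
   deviation (`scale_demean()`). The original method's "scaled, demeaned"
   preprocessing does not pin down the scale factor; per-row z-scoring
   makes the 0.2 contrast gate and the robustness-grid contrast/noise axes
   dimensionally coherent. The choice affects absolute contrast values, not
   transit times. Zero-variance rows cannot be z-scored; they are left at
   zero and flagged.
2. **Delay maps** (`rs_delays()`, `dsc_ttp()`, `co2_delays()`), below.
3. **Sorting and cropping** (`build_shag()`, `crop_shag()`). Rows sort by
   delay descending, ties broken by voxel id so the permutation is total
   and reproducible. Voxels whose match quality falls below a floor tend to
   draw extreme random delays and pile up at both ends of the ordering;
   cropping removes only maximal *contiguous* low-quality blocks at the
   extremes, never interior rows, mirroring how noisy rows actually present.
   The floor replaces the original visual inspection with a reproducible
   rule; it is a parameter (`quality_floor`, default 0.3) rather than a
   claim about any particular dataset.
4. **Slope detection** (`detect_edges()`), below.

## Delay estimators

**Resting state** (`rs_delays()`): each row is band-passed to 0.01–0.1 Hz
with a zero-lag (forward–backward) 4th-order Butterworth filter, upsampled
by cubic spline to 0.072 s, and cross-correlated against the band-passed
global mean over lags up to `max_lag`. The delay is the lag of the maximum
cross-correlation coefficient (MCCC); the MCCC itself is the quality.
Defaults: `max_lag = 10` s — large enough for transit spans of a few
seconds, but bounded because at the 0.1 Hz band edge a lag beyond half a
period (5 s) can alias onto the neighbouring cycle; the MCCC quality floor
catches most such wraps. Cross-correlation is Pearson-normalized on the
truncated overlap, so MCCC ∈ [−1, 1] regardless of lag.

**DSC** (`dsc_ttp()`): the bolus dip is modeled as
$s(t) = b - A\,u^{\alpha} e^{\alpha(1-u)}$, $u = (t-t_0)/t_p$, the standard
gamma-variate first-pass shape whose extremum sits at $t_0 + t_p$. All five
parameters are free; `minpack.lm::nlsLM` does the least squares. Starting
values matter more than the optimizer here: the onset is initialized at the
last pre-dip sample below 5 % of the dip depth and $t_p$ as the gap from
that onset to the raw minimum — initializing $t_p$ from the absolute peak
time instead sends late-arriving boluses into a local minimum. Time-to-peak
is read off the fitted curve on a 0.0001 s grid. Voxels with no dip deeper
than `dip_k` row-sd, failed fits, or fit $R^2$ below 0.5 are flagged with
`NA` delays.

**CO₂ challenge** (`co2_delays()`): rows are band-passed to 0.001–0.02 Hz,
upsampled to 0.1 s together with the end-tidal CO₂ regressor, and
cross-correlated (`max_lag` 15 s). The very low band leaves few independent
samples per 10-minute scan, so even pure-noise voxels reach MCCC ≈ 0.5
against the smooth regressor; a null simulation (white-noise voxels through
the same pipeline) puts the null 99th percentile near 0.54 while true block
responses exceed 0.9, so the default quality floor is 0.7 rather than the
resting-state 0.3.

Delays are relative quantities. The rs map is referenced to the global mean
(so a constant shift of all voxels cancels); DSC TTP is referenced to scan
start; CO₂ lags are referenced to the administered gas trace. Transit times
depend only on delay *differences*, so reference choices do not move them.

## The slope detector

`detect_edge()` implements: 2-D Gaussian blur → horizontal (time)
central-difference derivative → per row, the time of the extreme derivative
within a window around the candidate center → OLS of breakpoint time on
delay-ascending rank.

Parameter defaults, and why:

* **Blur σ = 2 samples (time) × 5 rows (voxel axis).** The time blur must
  be narrow against one oscillation period but wide enough to suppress
  per-sample noise; the row blur pools the ~10 neighbouring rows that share
  nearly the same delay. Both are exposed (`sigma_time`, `sigma_row`).
  Boundary handling is reflective; a consequence worth knowing is that
  reflection flattens the breakpoint line within ~σ rows of the top and
  bottom edges, attenuating the fitted slope by roughly a factor
  (1 − c·σ_row/R). On whole-brain carpets (thousands of rows) this is
  negligible; on toy images it is not, which is why the simulation
  frameworks below default to realistic row counts.
* **Derivative**: central difference `[-1, 0, +1]/(2 dt)` — the simplest
  operator consistent with a "horizontal derivative filter"; anything
  sharper amplifies noise before the per-row argmax.
* **Window**: ± half the mean peak-to-peak interval of the smoothed global
  signal, capped at ±5 s — wide enough to contain one edge, narrow enough
  to exclude the neighbouring oscillation. Degenerate windows (< 3 usable
  columns) are an error, not a silent fit.
* **Edge centers** (`estimate_edge_centers()`): local extrema of the
  smoothed global signal's derivative, strongest first, greedily separated
  by `min_separation` (default 5 s = half the shortest sLFO period, so one
  oscillation cannot be counted twice), capped at the edge budget
  `⌊duration × f_max⌋`.
* **Inclusion gates** (`select_edges()`): global-signal contrast (following
  extremum minus preceding extremum) must exceed 0.2 in scaled intensity
  units, and the derivative at the center must reach `rate_floor` (default:
  the 25th percentile of qualifying derivative peaks — a percentile adapts
  across SNR regimes where a fixed number would not). Excluded edges are
  kept with their reason rather than dropped.
* **Sign convention**: rank 0 is the earliest-arriving (bottom) row, so an
  edge propagating in delay order has positive slope and a DSC bolus has
  positive transit by construction; edges tilted against the propagation
  direction come out negative. Transit uses $R-1$ row gaps because it is
  the fitted time difference between the first and last row.
* **Ties** in the per-row argmax resolve to the earlier column
  (deterministic, reproducible); with any noise present ties are measure
  zero.

## Synthetic phantoms

`make_phantom()` generates the three modalities with known ground truth:
a shared base signal per modality (rs: 3–8 random sinusoids in
0.01–0.1 Hz; DSC: baseline minus a gamma-variate dip, α = 3; CO₂: a
two-block boxcar — 2 min baseline before, between and after — convolved
with an 8 s single-exponential response), time-shifted per voxel by cubic
interpolation of a 0.01 s fine grid so sub-TR delays are exact, plus
i.i.d. Gaussian noise. A configurable fraction of voxels carries pure noise
and no pattern; whole-brain motion spikes offset single time columns.
Everything is reproducible bit-for-bit from the seed, with the caller's RNG
state restored.

What the phantoms deliberately do **not** emulate: hemodynamic response
shape differences across voxels, cardiac/respiratory aliasing, spatially
structured (non-white) noise, motion other than instantaneous global
spikes, and any mixture of neuronal and vascular sources. Passing tests on
phantoms therefore demonstrate estimator correctness under the stated
model, not robustness to every failure mode of real scans. The "noise
voxel" model (pure Gaussian) is itself an open question — real pattern-free
voxels may carry structured signal that correlates spuriously with the
reference.

## Simulation frameworks

**TR sampling-error sweep** (`tr_error_sweep()`): an ideal noise-free
linear edge (step profile per row, event times spanning the true transit)
is sampled at interval TR for 50 sampling-start offsets uniform over
[0, TR), and the full detector runs on each sampled image. The signed error
(estimated − true) traces how temporal quantization biases the transit: the
error magnitude never exceeds the TR, shrinks as the true transit grows,
and is asymmetric (staircase quantization loses slope more easily than it
gains). Default construction: 400 rows — comparable to a cropped
single-slice carpet, and large enough that the row-blur boundary
attenuation described above does not masquerade as sampling error (with
~100 rows it adds several tenths of a second of spurious negative bias).

**Contrast × noise robustness grid** (`noise_robustness_grid()`): the clean
component of a single-edge base carpet is rescaled to each target contrast,
white noise of each target sd is added, and the edge is re-fitted in 30
independent trials per cell — always at the center located once on the
clean base, so per-cell statistics isolate the detector's response to image
quality rather than re-detection jitter. The bundled base
(`dsc_base_carpet()`) is a synthetic stand-in for a real DSC carpet, which
cannot be distributed: 16 000 z-scored gamma-variate rows (a scaled-down
whole-brain carpet; trial-to-trial transit variance scales with the ratio
of the row-blur correlation length (~18 rows) to the row count, so a
toy-sized base overstates detector variability by construction), TR 1.5 s,
transit 4.2 s, bolus time-to-peak 4 s. Its native decile-based contrast is
≈ 2.2 rather than ≈ 3: pushing the z-scored bolus shape to contrast 3
requires an unphysiologically wide (10–12 s) dip that blunts the very edge
the grid measures, and the grid rescales contrast per cell anyway.

One construction choice deserves emphasis. The bolus onset (`t0 = 60.4` s)
is deliberately off the sampling grid, at a phase where the noiseless
detected transit slightly exceeds the true value. Sampling phase is
arbitrary in reality, but it selects the regime of the noise response: at a
phase where quantization bias happens to vanish, added noise *dithers* the
breakpoint staircase and pushes the mean estimate toward the true transit —
i.e. upward — whereas the operating regime of interest (and the one a real
measured baseline sits in) is the one where image degradation can only
attenuate the detected slope. The default phase puts the grid in that
monotone-degradation regime.

**Contrast and noise estimators** (`estimate_contrast()`,
`estimate_noise_sd()`) place real carpets on the grid axes: contrast is the
mean of smoothed pixels above the 90th percentile minus the mean below the
10th; noise sd is the MAD of the raw-minus-smoothed residual divided by the
smoother's residual-variance factor, so pure white noise is recovered
unbiased and the localized residual leakage of a sharp clean edge (a few
percent) is largely ignored.

## Rank-sum confidence interval

`ranksum_median_ci()` is the Hodges–Lehmann construction: the CI for a
location difference is cut from the ordered pairwise differences
$a_i - b_j$ at ranks
$k = \lfloor mn/2 - z_{\alpha/2}\sqrt{mn(m+n+1)/12} + \tfrac12 \rfloor$
(normal approximation of the rank-sum statistic, continuity-corrected,
clamped so an interval always exists). For samples of five or fewer per
group the cut ranks coincide with those from exhaustive enumeration of the
exact rank-sum distribution, which the test suite checks against
`wilcox.test(conf.int = TRUE, exact = TRUE)` as an independent oracle.
Degenerate all-equal inputs yield a zero-width interval with a warning.
Midranks handle ties in the accompanying test machinery; the CI itself
depends only on the ordering of the pairwise differences.

## Problem sizes

The package's own test and reproduction runs use desk-scale problems chosen
to keep every property measurable: phantoms of 20–200 voxels for estimator
tests, a 2 000-row base for grid monotonicity checks, the full 16 000-row
base for the lowest-quality-cell statistics, 50 offsets for the TR sweep,
and 1 000 simulated pairs for CI coverage. These sizes are the package's
choices; all are parameters.

## Known limitations

* A straight line is a first-order model of an edge; real propagation
  fronts curve, and the OLS fit averages that curvature into one slope.
* The detector's row blur biases slopes slightly toward zero near the
  image boundary (quantified above); transit times from carpets with few
  rows should be treated with caution.
* Gaussian white noise is an oversimplification of BOLD noise; the
  robustness grid bounds the detector's sensitivity under that model only.
* Cropping by quality floor reproduces the *mechanism* of removing
  pattern-free voxels but cannot reproduce any particular study's visually
  chosen crop fraction.
* The rs delay reference is the global mean, so voxels dominated by
  regional (non-systemic) fluctuations acquire delays that are poorly
  defined; they are expected to be flagged by the MCCC floor.
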