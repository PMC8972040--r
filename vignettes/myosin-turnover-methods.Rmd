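---
title: "Models and methods behind myoturn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind myoturn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoturn)
```

# The measurement problem

Thick-filament myosin is continuously exchanged with the cytosolic pool.
Two fluorescence designs quantify that exchange. Photoconversion flips
every incorporated label from green to red at one instant: thereafter red
intensity in the converted region decays as labeled myosin is released,
and green intensity recovers as unconverted myosin is inserted.
Pulse-chase labeling instead colors pre-existing myosin green and myosin
synthesized during a short chase red, so the red distribution within a
sarcomere shows where new molecules were incorporated. `myoturn`
implements the complete quantification chain for both designs, plus a
simulator that generates ground-truthed synthetic inputs at the same
geometry, kinetics and noise scales.

# The exchange model

## Geometry

A bipolar thick filament of length 1.6 µm sits centred on the M-line of a
2.0 µm sarcomere (`filament_geometry()`). Its 300 myosin sites are
placed evenly along each half-filament in the normalized coordinate where
the M-line is 0 and the Z-bands are ±1; the filament tips then fall at
±`filament_length / sarcomere_length` = ±0.8, which is where fluorescence
support ends in normalized line scans. The sarcomere length is a
convention choice — it is the value that puts the tips at the ±0.8
coordinate the normalized waveforms exhibit.

## Kinetics

Each site exchanges as an independent Poisson process; at an event the
occupant leaves and a molecule carrying the current pool label takes its
place, so occupancy is conserved and the myosin molecule is the exchange
unit. Because sites do not interact, per-site exponential waiting times
are an exact simulation scheme (equivalent to a Gillespie simulation of
the whole filament). Rates come in two parameterizations
(`exchange_kinetics()`):

* a **pool model** `(A1, k1, A2, k2)`: fractions `A1` and `A2` of sites
  exchange at fast rate `k1` and slow rate `k2` (h⁻¹); the remaining
  `1 − A1 − A2` are immobile, which is what keeps recovery below 100%
  (mobile fraction < 1). The expected replaced fraction is biphasic,
  `f(t) = A1(1 − e^{−k1 t}) + A2(1 − e^{−k2 t})`. Fast sites are placed
  tip-ward, tying the fast phase to the tip region; whether the fast pool
  really coincides spatially with the tips is not observable in the FRAP
  data alone, so this is a modelling choice, recorded here.
* a **rate profile** `k(|x|) = k_center + (k_tip − k_center)(|x|/x_tip)^p`:
  smooth, monotone tip bias; `p` defaults to 2.

`calibrate_biphasic()` solves for `(A1, A2, k2)` given anchor points and
a fixed fast rate: for a candidate `k2` the two later anchors give a
linear 2×2 system in `(A1, A2)` solved exactly, and `k2` is found by
`stats::uniroot()` on the first-anchor residual after a log-spaced grid
scan locates a sign change. Anchors are reproduced to 10⁻⁶ or the
calibration aborts with the residuals. The shipped `"biphasic_red"`
preset is calibrated at run time to 20% replaced at 10 min, 30% at
60 min, 70% at 10 h with `k1 = 30` h⁻¹ (fast relative to the first
anchor).

## Shipped presets

| preset | form | parameters | role |
|---|---|---|---|
| `monoexp_green` | pool | `A1 = 0.5524`, `k1 = ln2/2.55` | green-channel recovery reference |
| `monoexp_red` | pool | `A1 = 0.6698`, `k1 = ln2/1.38` | red-channel decay reference |
| `biphasic_red` | pool | calibrated at run time | biphasic replacement curve |
| `tip_biased` | profile | `k_center = 0.06`, `k_tip = 0.15` h⁻¹, `p = 10` | pulse-chase insertion bias |
| `tip_biased_photoconv` | profile | `k_center = 0.1`, `k_tip = 1.2` h⁻¹, `p = 2` | photoconversion waveform series |

`tip_biased` models the insertion of *newly synthesized, chase-
labeled* myosin only — a small flux compared with total exchange, which
is why its rates are far below the photoconversion scale. It was
calibrated against noise-free ground-truth category mixes of simulated
populations (n = 150 per condition, repeated over seeds): the design
targets were a side-group share near 80% across 7–30 min chases with the
center share rising toward 20% by 30 min. Under monotone tip-biased
independent exchange those two targets cannot be met simultaneously at
their nominal values — the side zone (|x| ≥ 0.40 on both sides) contains
about twice as many sites as the center zone (|x| ≤ 0.25), and any red
molecule landing in it pre-empts a center call — so the preset maximizes
the worst-case margin instead, giving mean mixes of roughly 76% side at
15 min, 77% side and 13% center at 30 min in the classified output. The
sharp exponent (`p = 10`, against the generic default of 2) concentrates
the excess rate at the outermost sites, which both strengthens the
short-chase side signature and leaves mid-filament insertions rare enough
for center patterns to surface.

# Rendering

`render_line_scan()` draws each myosin as a unit Gaussian of width
`psf_sigma` (default 0.1 µm, a confocal-scale point spread) at its axial
position in the channel of its current label, samples at `pixel_size`
(default 0.05 µm), tiles neighboring sarcomeres so the scan contains the
inter-sarcomere intensity minima, then applies per-channel auto-gain
(each channel scaled to its own maximum, as acquisition software sets
detector gains independently), adds a uniform background (5% of peak) and
Gaussian read noise (2% of peak by default; a Poisson option is
deliberately absent — the read-noise-dominated confocal assumption).
Per-channel gain matters downstream: the classifier's no-incorporation
floor compares red and green dynamic ranges, which is only meaningful on
per-channel display scales.

`simulate_frap_trace()` renders ROI-level traces from the analytic
replaced-fraction curve of the kinetics: converted-area green recovers
with `f(t)`, converted-area red decays with `1 − f(t)`, a non-converted
reference ROI carries the multiplicative green photobleaching decay
(`bleach_rate_green`, fraction·h⁻¹), and the converted red ROI
additionally receives a linear instrument drift (`red_linear_drift`,
fraction·min⁻¹). A pre-conversion sample is prepended at −10 min.

# FRAP normalization and fitting

`normalize_green()` multiplies the converted-area signal by
`reference(pre)/reference(t)` — cancelling photobleaching exactly when
both ROIs bleach alike — then rescales affinely so pre-conversion ↦ 1 and
first post-conversion ↦ 0. On simulator output without noise this equals
the ground-truth replaced fraction to machine precision, which the tests
assert.

`normalize_red()` removes the linear drift using the late-trace slope:
the least-squares slope of raw converted-area red over 500–600 min is
negated into a correction value (intensity·min⁻¹) and
`correction_value · t` is added back, then the series is rescaled so the
first post-conversion sample ↦ 1 and the non-photoconverted-area red
level (taken per time point) ↦ 0. Two practical points:

* For traces shorter than 600 min the final 100 min are used, with a
  warning; fewer than 3 window samples is an error.
* The window slope of a single trace is noisy — with 2% noise its
  standard error is comparable to a realistic drift itself, and the
  600-min lever arm propagates that error into the fitted mobile
  fraction at the level of several percentage points per trace. Since the
  drift is an instrument artifact common to an imaging session,
  `estimate_red_correction()` pools the windows of all session traces
  (common slope, per-trace intercepts) and feeds one correction value to
  every `normalize_red()` call. The per-trace estimator remains the
  default for a lone trace. A residual bias remains in either case: by
  500–600 min the exchange decay has not completely flattened, so the
  correction absorbs a little genuine signal and the fitted mobile
  fraction lands a couple of percentage points below the generative
  value. This bias is a property of the correction procedure itself, not
  of its implementation.

`fit_recovery()` fits `FI(t) = Mf(1 − e^{−bt}) + c` to post-conversion
samples by bounded Levenberg–Marquardt (`minpack.lm::nlsLM`). The red
channel is first mirrored (`1 − value`) so both channels share the
increasing form and `Mf` is always the maximum change magnitude.
Initialization comes from the data (`Mf₀` = observed range, `b₀` = ln 2
over the half-range crossing time, `c₀` = first value) with up to five
restarts over scaled rate starts; bounds are `Mf ∈ [0, 1.5]`,
`b ∈ (0, 100]` h⁻¹, `c ∈ [−0.5, 0.5]`. Degenerate inputs are flagged
rather than fitted: a constant series returns `Mf = 0` with an
unidentifiable rate, and a rate landing on a bound marks the fit
non-converged. `t½ = ln 2 / b`; on the fitted curve the change reaches
`Mf/2` at `t½` identically. `compare_mf()` applies the classic two-sample
Student's *t* test (equal variances, two-sided) to the mobile fractions
and half-lives of converged fits, requiring at least two per group.

# Waveform extraction

`line_scan()` samples a two-channel image along a polyline at unit-pixel
arc-length steps, averaging `width_px` bilinear samples perpendicular to
the scan direction; pixel indices are 0-based. `fit_polynomial()` fits a
least-squares polynomial per channel (plus a green+red `total` channel)
on centred and scaled positions; degree 6 by default — enough for one
sarcomere peak with shoulders without inviting ringing, configurable
2–10 (hard range 0–12).

Z-bands are the turning points of the fitted green curve
(`find_turning_points()`): real roots of the derivative polynomial,
classified by the second derivative, ties between equal-height maxima
resolved leftmost. Two qualifications make the detection robust:

* only *deep* minima qualify (value ≤ `min_rel_depth` = 0.5 of the
  principal peak), so shallow shoulder dimples — which genuinely occur
  once part of the green label has been replaced — cannot truncate the
  sarcomere; the nearest deep minima on each side are taken;
* immediately after photoconversion the green channel is nearly empty,
  so the photoconversion series generator detects turning points on the
  `total` curve, which traces the filament at all times. The pulse-chase
  path keeps the green-channel convention.

A curve with no interior maximum or no flanking minima (truncated
sarcomere, monotone ramp) raises a boundary error and the sarcomere is
skipped.

`extract_sarcomere()` evaluates both channels between the turning points,
on the fitted curves *refitted locally to the in-window samples*: the
wide-window polynomial that locates the Z-bands underfits structure
inside one sarcomere (it must also describe the neighboring shoulders),
and without the refit, narrow red features near the tips are flattened
into the baseline. Per channel the straight line through the channel's
values at the two turning points is subtracted, values below the baseline
are clipped at zero, the channel is rescaled to max 1, and positions map
affinely to the 201-point grid on [−1, 1] (odd count keeps x = 0
on-grid). Green endpoints are exactly zero by construction. A channel
with no signal above its baseline is flagged empty instead of normalized.
With the default geometry the detected turning points sit slightly
outside the true Z-bands (the wide-window polynomial biases the minima
outward by a few percent), so the filament tips appear near ±0.75 — within
the 0.7–0.8 band normalized line scans show. Because each channel is
max-normalized independently, the difference `red − green`
(`subtract_waveforms()`, `build_difference_map()`) is a *shape*
comparison, not an abundance comparison; clipping keeps every difference
in [−1, 1]. Difference maps average channels across sarcomeres per time
point before subtracting.

# Incorporation-pattern classification

The eight categories are operationalized by explicit thresholds
(`classification_rules()`), every one recorded in the output:

| rule | default | meaning |
|---|---|---|
| `center_zone_halfwidth` | 0.25 | principal peak with smaller abs(x) → center |
| `side_zone_min` | 0.40 | minimum abs(x) for a side peak |
| `balance_ratio` | 0.60 | min height ratio for "both sides" |
| `shape_similarity_min` | 0.90 | red–green correlation for "random" |
| `red_signal_floor` | 0.15 | red/green dynamic range for "none" |
| `peak_prominence_min` | 0.20 | topographic prominence threshold |
| `peak_x_max` | 0.85 | peaks beyond the filament extent are artifacts |

The decision cascade: no-incorporation (range floor) → random fashion
(shape similarity, unless a side peak clearly exceeds green) → both
sides / predominantly (balanced vs unbalanced side peaks) → one side →
center (single principal central peak) → random fashion with a
low-confidence flag for anything unresolved (e.g. a principal peak in the
0.25–0.40 dead zone). `peak_x_max` exists because polynomial fitting of
narrow red features rings, and the ring lobes sit outside the
green-supported filament extent (beyond ±0.85); a fluorescence peak out
there cannot be filament-incorporated myosin. Peak prominence is the
standard topographic definition evaluated on the 201-point grid.

Peak shift (`peak_shift()`, `peak_shifts()`) records the absolute peak position for every
qualifying side-zone peak of the five side categories — both peaks of a
both-sides waveform count separately, matching per-peak distance
measurement; `summarize_patterns()` also emits histograms (bin width
0.05) and per-time medians. Frequency summaries compute proportions per
myotube first and report mean ± SE *across myotubes*, so the error bars
reflect biological replication, not sarcomere counts.

Ground truth for simulated populations is assigned by running the
identical render–extract–classify chain on a noise-free rendering of the
same label state. Noise-free classification therefore agrees with truth
by construction (the tests assert 100%), and the meaningful recovery
statement is the noisy one: with default noise, agreement stays above
85% (typically ~95%).

# What the simulator does and does not emulate

Emulated: per-molecule stochastic exchange with spatial bias, both
labeling protocols, PSF blur, sampling, background, Gaussian read noise,
green photobleaching, linear red drift, independent channel gains,
sarcomere tiling, between-myotube grouping.

Not emulated: optical sectioning and 3-D PSF structure, myofibril
curvature and segmentation (polylines are given, not traced),
sarcomere-length variability, chromatic misregistration, Poisson photon
statistics, cooperative or zone-structured binding chemistry (MybpC,
myomesin, titin enter only implicitly through the rate profile), and any
isoform selectivity. Passing recovery tests on synthetic data therefore
demonstrates correctness of the quantification chain under the stated
noise model, not robustness to every real-microscope artifact.

# Numerical choices and problem sizes

Anchor reproduction tolerance 10⁻⁶; polynomial conditioning guarded by a
QR rank check on scaled positions; derivative roots accepted with
imaginary parts below 10⁻⁷ relative; sub-stream seeds derived from the
master seed by a fixed linear map below 2³¹. The test suite runs
simulations at deliberately modest sizes — single populations of 18–60
sarcomeres for behavioral tests, pooled populations of 4 × 150 for the
pattern-mix recovery check, 4 × 7 traces for the FRAP recovery check, a
k × t grid at n = 300 sites for the closed-form property — sizes chosen
so the whole suite completes in well under a minute while keeping Monte
Carlo standard errors small relative to the tolerances being asserted.
The pooling in the two recovery checks exists because a single
n = 150 population (or a single 7-trace session) estimates a proportion
(or a session-corrected mean) with a standard error of a few percentage
points, an appreciable fraction of the acceptance band; pooling four
consecutive-seed replicates makes the test verdict reflect the estimator
rather than one draw.

# Known limitations

* The red drift correction is structurally biased low on the mobile
  fraction (it absorbs residual exponential decay in its window) and is
  the dominant variance contributor to red-channel estimates; both
  effects are inherent to the late-window linear correction, and the
  session-pooled estimator only reduces the noise, not the bias.
* The joint design point for the pulse-chase preset (side ≈ 80% with
  center ≈ 20% by 30 min) is geometrically unattainable under monotone
  tip-biased independent per-site exchange with the default zones; the
  shipped preset is the minimax compromise described above.
* Category decision boundaries are package conventions — the categories
  themselves are qualitative — and results should be reported together
  with the rule snapshot the output carries.
* Z-band positions from the default single-sarcomere window carry a
  small outward bias; a wider multi-sarcomere scan with a higher-degree
  fit reduces the spacing error below 2% where that matters.
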