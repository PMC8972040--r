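# myoturn

Quantification of myosin turnover in skeletal-muscle thick filaments from
two-channel fluorescence data.

A sarcomere's bipolar thick filament is built from roughly 300 myosin
molecules and is continuously renewed by protein turnover: individual
myosins are released and replaced by molecules from the cytosolic pool,
and the replacement is faster at the filament tips than at its center.
Two live-imaging designs make this measurable. In a **photoconversion
(FRAP-style) assay**, a photoconvertible tag flips green to red under UV,
so red decay reports myosin release and green recovery reports insertion.
In a **pulse-chase assay**, sequential ligands label pre-existing myosin
green and newly synthesized myosin red, so the red peak position within a
sarcomere reveals *where* new myosin is incorporated.

`myoturn` is for cell biologists and image analysts who want those
measurements as a tested, reproducible pipeline:

* **FRAP kinetics** — trace normalization exactly as the assay prescribes
  (green photobleaching correction by a reference region; red drift
  correction from the 500–600 min slope) and bounded nonlinear
  least-squares fitting of

  `FI(t) = Mf · (1 − e^(−b·t)) + c`

  yielding the mobile fraction `Mf`, rate `b` and half-life
  `t½ = ln 2 / b`, with Student's *t* group comparison.
* **Waveform extraction** — polyline line scans, polynomial smoothing,
  Z-band detection at the turning points of the green curve, baseline
  removal, per-channel max-1 normalization on the coordinate where the
  M-line is 0 and the Z-bands are ±1, and red−green difference maps over
  time.
* **Incorporation classification** — the eight red-peak pattern categories
  (both sides, predominantly right/left, right/left side, center, random
  fashion, no incorporation), red-peak-to-center distances for the side
  patterns, and per-myotube frequency summaries (mean ± SE).
* **A stochastic simulator** — per-myosin Poisson exchange on a bipolar
  filament (1.6 µm filament in a 2.0 µm sarcomere, tips at ±0.8) with
  pool-model or tip-biased rate profiles, photoconversion and pulse-chase
  protocols, and a renderer with realistic artifacts (PSF blur,
  background, noise, bleaching, red drift). Every synthetic dataset
  carries its ground truth, so parameter recovery is testable end to end.

All user-facing functions take and return tibbles, plot via
`autoplot()`/`plot_*()`, and fits have broom-style `tidy()`/`glance()`
methods.

## Worked example

Simulate a green-channel photoconversion trace at the reference kinetics
(mobile fraction 0.5524, half-life 2.55 h), normalize it, and fit the
recovery:

```r
library(myoturn)

kin <- kinetics_preset("monoexp_green")
tr  <- simulate_frap_trace(kin,
                           render_config(noise_sd = 0.02,
                                         bleach_rate_green = 0.02),
                           seed = 42)
glance(fit_recovery(normalize_green(tr)))
#> # A tibble: 1 × 7
#>      Mf     b      c t_half residual_rms converged     n
#>   <dbl> <dbl>  <dbl>  <dbl>        <dbl> <lgl>     <int>
#> 1 0.537 0.246 0.0270   2.82       0.0257 TRUE         61
```

One noisy 10-h trace recovers the generative mobile fraction (0.537 vs
0.5524) and half-life (2.82 h vs 2.55 h) to within single-trace noise;
averaging seven traces tightens both (see `run_pipeline()`).

The biphasic replacement preset is calibrated at run time so that 20% of
myosin is replaced at 10 min, 30% at 60 min and 70% at 10 h:

```r
replaced_fraction(kinetics_preset("biphasic_red"), c(10, 60, 600) / 60)
#> [1] 0.2 0.3 0.7
```

Generate a 15-min pulse-chase population with tip-biased insertion,
classify every sarcomere, and summarize the pattern mix:

```r
pop <- generate_pulse_chase_population(chase_time_min = 15,
                                       n_sarcomeres = 60, n_myotubes = 3,
                                       seed = 42)
summarize_patterns(classify_patterns(pop))$rollup
#> # A tibble: 4 × 5
#>   time_min group            mean_prop     se n_myotubes
#>      <dbl> <chr>                <dbl>  <dbl>      <int>
#> 1       15 center              0.05   0.0289          3
#> 2       15 no_incorporation    0.0167 0.0167          3
#> 3       15 random_fashion      0      0               3
#> 4       15 side_group          0.933  0.0167          3
```

Side-dominated incorporation (93% here) is the expected signature of
tip-biased insertion at short chase times. `run_pipeline()` chains all
stages (FRAP fits, photoconversion waveform series with difference map,
pulse-chase classification, markdown report) from a single configuration
list or YAML file, with one master seed and byte-identical re-runs.

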