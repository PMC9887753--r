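# catrace

Calcium-transient kinetics from paced cardiomyocyte fluorescence
recordings: an R package plus a small analysis workflow that turns raw
Fluo-4 time-lapse data (multi-page TIFF stacks or per-frame CSV traces)
into per-cell Ca²⁺-handling parameters and group-level statistics.

**Who it is for.** Cardiac physiologists running the standard
field-stimulation + caffeine protocol: cells paced at a fixed frequency
(here 0.5 Hz, imaged at 97 frames/s), pacing stopped for one minute, then
10 mM caffeine applied to dump the sarcoplasmic reticulum (SR).

**The quantities at its core.** Traces are background-subtracted and
normalized to ΔF/F₀, with F₀ the mean of the 10–40 frames preceding the
first Ca²⁺ rise. Each detected transient yields amplitude, time to peak,
and rate of rise (= amplitude / time-to-peak). Decay segments are fit to a
single exponential `y(t) = A·exp(−k·(t − t₀)) + C`. The caffeine protocol
separates the two Ca²⁺-removal systems:

- systolic decay rate `k_sys` (SERCA2 + NCX, from the final paced
  transient; a randomly chosen paced spike is fit as well),
- caffeine-induced decay rate `k_caf` (≈ NCX alone),
- **SERCA2 function** `= k_sys − k_caf`,
- **fractional release** `= paced amplitude / caffeine amplitude`
  (caffeine amplitude proxies SR content).

Cells are eligible when they show ≥ 30 paced spikes, no automaticity
(ectopic spikes of physiological size), and regular amplitude clearance
(CV ≤ 0.25). Group comparisons use the unpaired two-tailed t test and
one-/two-way ANOVA with Sidak or Tukey post hocs; a quartile
stratification with 1.5×IQR outlier exclusion handles expression-style
vectors.

Because no raw recordings are publicly deposited, the package includes a
ground-truth simulator (`simulate_trace`, `simulate_stack`,
`simulate_cohort`) that emulates the protocol — periodic transients with
linear rise and exponential decay at `k_serca + k_ncx`, a terminal
caffeine transient decaying at `k_ncx`, multiplicative baseline, camera
background, Gaussian or Poisson noise — so every stage is testable by
parameter recovery.

## Worked example

```r
library(catrace)

# one simulated cell at the study conditions: 97 fps, 0.5 Hz pacing for
# 3 min, 1 min pause, caffeine; SNR 20; k_serca 3.5 /s, k_ncx 1.5 /s
cfg <- sim_config(seed = 42)
sim <- simulate_trace(cfg)
trace <- subtract_background(sim$trace)

res <- analyze_trace(trace,
                     protocol_descriptor(pacing_freq_hz = 0.5,
                                         pacing_stop_s = 180),
                     analysis_params(rng_seed = 42))
res$summary[, c("n_spikes", "eligible", "mean_amplitude", "k_sys",
                "k_caf", "serca_function", "fractional_release")]
#>   n_spikes eligible mean_amplitude    k_sys    k_caf serca_function
#> 1       90     TRUE       1.004583 5.080412 1.496404       3.584008
#>   fractional_release
#> 1          0.7780296
```

90 paced spikes detected (one per stimulus), the cell passes QC, and the
decomposition lands on the generating parameters: systolic decay
5.08 s⁻¹ vs true 5.0, caffeine decay 1.50 s⁻¹ vs true 1.5, SERCA2
function 3.58 s⁻¹ vs true 3.5. Fractional release compares the final
paced amplitude (a noisy per-spike draw) to the caffeine amplitude; its
cohort mean recovers the true ratio 1.0/1.4 ≈ 0.71.

The `analysis/` directory holds the numbered workflow the package was
built around: `01_simulate.R` (two-group cohort, SERCA2 enhanced 1.5× in
group 2, plus example trace/stack files), `02_extract_traces.R` (TIFF →
ROI trace), `03_analyze_cells.R` (per-cell summaries, manifest),
`04_compare_groups.R` (t tests and ANOVA + Sidak), and
`05_stratify_expression.R` (quartile strata). Each writes its tables
under `results/`.

## Layout

```
R/                  implementation (simulator, I/O, normalization,
                    spike detection, kinetics, statistics, pipeline)
src/                C++ peak-prominence core (Rcpp)
analysis/           numbered workflow drivers (01..05)
scripts/acceptance.R  headline-number reproduction
tests/testthat/     unit, property and acceptance tests (oracle-based)
vignettes/          methods vignette: models, parameters, design choices
```
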