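---
title: "Methods: calcium transient kinetics from paced cardiomyocyte recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium transient kinetics from paced cardiomyocyte recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrace)
```

## The measurement problem

Isolated adult cardiomyocytes loaded with a fluorescent Ca^2+^ indicator
(Fluo-4) and field-stimulated at a fixed frequency produce one whole-cell
Ca^2+^ transient per stimulus: a fast upstroke as the sarcoplasmic
reticulum (SR) releases Ca^2+^, then a roughly exponential decline as
Ca^2+^ is removed from the cytosol. Two transport systems dominate that
removal: SERCA2, which pumps Ca^2+^ back into the SR, and the
Na^+^/Ca^2+^ exchanger (NCX), which extrudes it across the sarcolemma.
Their contributions can be separated with the classical caffeine protocol:
pacing is stopped for a quiescent interval, then a saturating caffeine
pulse locks RyRs open, releasing the entire SR content. During the
caffeine transient SERCA cannot produce net reuptake, so its decay reflects
NCX (plus minor pathways) alone, while a paced ("systolic") transient
decays through SERCA2 + NCX together. Writing the fitted rate constants
$k_\mathrm{sys}$ and $k_\mathrm{caf}$,

$$\text{SERCA2 function} = k_\mathrm{sys} - k_\mathrm{caf}, \qquad
  \text{fractional release} =
  \frac{\text{amplitude}_\mathrm{stim}}{\text{amplitude}_\mathrm{caff}} .$$

The caffeine amplitude serves as a relative proxy for SR content; no
absolute calcium concentrations are estimated.

`catrace` implements the full measurement chain for this protocol —
image-stack ROI extraction, $\Delta F/F_0$ normalization, spike detection,
QC, decay fitting, the SERCA/NCX decomposition, and group statistics —
together with a ground-truth simulator, so that every stage can be
validated by parameter recovery instead of by eye.

## The recording model behind the simulator

`simulate_trace()` generates raw intensities

$$F(t) = B + F_0\,\bigl(1 + s(t)\bigr) + \varepsilon(t),$$

where $B$ is the camera background, $F_0$ the resting fluorescence, and
$s(t)$ the summed transient signal on the $\Delta F/F_0$ scale. Each
stimulus contributes a transient that rises linearly over `time_to_peak`
and decays exponentially at $k_\mathrm{serca} + k_\mathrm{ncx}$; the
caffeine transient decays at $k_\mathrm{ncx}$ alone. Design choices:

* **Linear rise.** With a linear rise the definition
  rate-of-rise = amplitude / time-to-peak is exact by construction, which
  makes the detector's rise statistics directly checkable.
* **Additive Gaussian noise** (default) for the camera-dominated regime; a
  Poisson option exists for photon-limited data. The downstream operators
  are noise-model agnostic.
* **Linear superposition** when a transient has not fully decayed before
  the next stimulus — the simplest model consistent with non-overlapping
  transients at 0.5 Hz pacing (at the default rates a transient decays to
  $\sim 6\times 10^{-5}$ of its amplitude within one pacing interval).
* **Caffeine onset exactly at the end of the pause**, with an optional
  onset jitter for robustness experiments.

Defaults encode the study conditions: 97 frames/s acquisition, 0.5 Hz
pacing for 180 s, a 60 s stop-pacing pause, then caffeine. The kinetic
defaults $k_\mathrm{serca} = 3.5\,\mathrm{s^{-1}}$,
$k_\mathrm{ncx} = 1.5\,\mathrm{s^{-1}}$ give a systolic decay constant of
$5\,\mathrm{s^{-1}}$ ($\tau = 200$ ms), typical of healthy adult mouse
cardiomyocytes at room temperature. Values the source recordings do not
constrain were fixed once at plausible levels and not revisited:
amplitude $1.0\ \Delta F/F_0$ with 10% spike-to-spike CV ("regular
amplitude clearance"), caffeine amplitude $1.4$ (fractional release
$\approx 0.71$, in the usual rodent 0.6–0.8 range), 50 ms time-to-peak,
baseline $F_0 = 500$ counts over background 100, and noise sd 25 counts —
a signal-to-noise ratio of 20 on the $\Delta F/F_0$ scale.

What the simulator deliberately omits: SR/cytosol flux biophysics (RyR
gating, buffering, dye kinetics), photobleaching, and isoproterenol
pharmacodynamics (an isoproterenol condition is just an alternative
parameter set). Passing recovery tests on this generator therefore
validates the *estimators* under the stated statistical structure, not the
biophysical realism of any particular recording.

## Trace extraction and normalization

ROI traces are per-frame means: `extract_trace()` computes
`mean(cell pixels) − mean(background pixels)` frame by frame, so slow
illumination drift cancels; an optional top-percentile trim of the
background region discards bright debris. Pixel coordinates are 0-based
with half-open rectangles, stated once and used everywhere.

$\Delta F/F_0$ uses $F_0$ = mean of the 10–40 frames preceding the first
Ca^2+^ rise. The window length range is honored with a fixed default of 30
frames (~0.31 s at 97 frames/s, comfortably inside the diastolic interval
at 0.5 Hz); whether the original analysis chose lengths adaptively per
cell is unknowable, so a fixed default with a permitted range is an
explicit policy, not an inference. Normalization is a pure gain: scaling a
trace by any $g > 0$ leaves $\Delta F/F_0$ unchanged, while an additive
offset does not cancel — which is exactly why background subtraction must
precede normalization, and why the two steps are kept separate.

The first rise is located by a deterministic derivative-over-noise rule:
trailing 5-sample boxcar, first difference, threshold at 5× the MAD-based
noise scale, then backtracking to the start of the rising run. The
5-sample window was chosen so that a transient rising over ~5 frames
clears the threshold several-fold even at SNR 10; partial windows at the
trace start are excluded because their noisier derivative would otherwise
produce spurious early detections.

## Spike detection, stimulus assignment, and QC

Peaks are local maxima ranked by **topographic prominence** (height above
the higher of the two lowest points separating the peak from higher
terrain), thinned so no two retained peaks lie within `min_separation`
(higher peak wins; ties to the earlier sample). Prominence is invariant
under adding a constant, so detection is offset-free. The default
threshold is 5× the robust noise scale of the trace; the original
plugin's "noise tolerance" value is unreported, so this default is a
replacement, not a reconstruction, and is exposed in the configuration.
The hot loop (prominence over all local maxima of a 25k-sample noisy
trace) is implemented in C++; a brute-force R scan serves as the oracle in
the test suite.

Per spike, the onset is the last pre-peak sample below 10% of the local
rise (the common electrophysiology convention; the upstream text does not
define the start of time-to-peak), with the local baseline taken as the
median of the 10 samples before the onset, solved by a small fixed-point
iteration. Amplitude is peak minus local baseline — robust to incomplete
decay between beats and identical to raw peak $\Delta F/F_0$ once decay is
complete.

Spikes are assigned to stimuli by **peak time** (last stimulus within
0.2 s before the peak): the detected onset jitters by a sample or two
under noise and can land marginally before its stimulus, while the peak
cannot. Unassigned spikes in the paced phase, anything in the pause, and
secondary peaks in the caffeine phase are labeled ectopic.

Eligibility mirrors the protocol's inclusion rules: at least 30 paced
spikes, amplitude CV ≤ 0.25 (an explicit operationalization of "regular
amplitude clearance" — a chosen value, not a reported one), and no
automaticity. Automaticity counts only ectopic spikes reaching 50% of the
median paced amplitude. The qualifier matters: over a ~26,000-sample
recording the most extreme noise excursion in the pause grows like
$\sqrt{2\log n}$ and will eventually clear *any* fixed multiple-of-noise
prominence threshold, so an unqualified ectopic count would disqualify
essentially every real-noise cell; a genuine spontaneous transient, which
releases SR Ca^2+^ like a paced one, still disqualifies. Sub-threshold
ectopic labels are reported separately (`n_ectopic_minor`).

## Decay fitting and the caffeine decomposition

`fit_decay()` fits $y(t) = A e^{-k (t - t_0)} + C$ by Levenberg–Marquardt
with $A, k \ge 0$ and $C$ free. The free offset matters because diastolic
$\Delta F/F_0$ need not return to the pre-recording baseline; on
offset-free simulations $C$ fits to ~0, so no bias is introduced.
Initialization: $A_0 = y(t_0) - \min y$, $C_0 = \min y$, and
$k_0 = \ln 2 / t_{1/2}$ from the first crossing of $A_0/2 + C_0$. A fit is
`converged` only if the optimizer converged, $k$ sits away from its lower
bound, and RMSE $< 0.2 A$ — a constant or rising segment therefore returns
`converged = FALSE` rather than an error. Rates are reported as rate
constants $k$ (s^-1^) with $\tau = 1/k$ alongside, since "decay rate" is
not dimensionally pinned down in common usage.

The systolic rate is computed twice, deliberately: from one **randomly
chosen** paced spike (`select_systolic_spike()`, uniform and reproducible
under a mandatory seed) and from the **final** paced transient before
caffeine; both appear in the cell summary (`k_sys_random`, `k_sys`)
because the source description mentions both and does not disambiguate
which fed the downstream figures. The SERCA2 subtraction uses the final
paced spike, whose fit shares the segment structure of the caffeine fit. A
paced decay segment ends at the next spike's onset (not after a fixed
duration), maximizing points without contaminating the fit with the next
rise; the caffeine segment runs from the caffeine peak to the end of the
recording. `serca_function()` subtracts the two fitted rate constants
literally; a negative difference is reported and flagged rather than
censored. Cells with unconverged fits are excluded from group statistics
and logged — never imputed.

If the protocol descriptor does not give the caffeine time,
`segment_protocol()` detects it as the onset of the largest-prominence
peak after pacing stops, and errors if none is found.

## Group statistics and stratification

`compare_two_groups()` is the classic unpaired two-tailed Student t test
with mean ± SEM reporting. `compare_multi_groups()` covers one-way and
full-factorial two-way ANOVA; pairwise post hocs use the pooled residual
variance with Sidak adjustment $1-(1-p)^m$ (or Tukey's studentized range),
matching the combinations used in the source figure legends. Cell-level
tests are the default (animal identity is carried in the summaries;
per-animal aggregation is the user's choice) — mirroring how such data are
commonly analyzed, at the known cost of treating cells as independent.

`stratify_quartiles()` computes Q1/Q3 on the full vector (type-7 linear
interpolation — the most common convention; configurable and recorded in
the output), assigns values ≤ Q1 / ≥ Q3 to the low/high groups, then
excludes members outside [Q1 − 1.5 IQR, Q3 + 1.5 IQR]. Applying the
outlier screen after group assignment, with full-vector quartiles, is one
reading of an ambiguous order of operations; it is explicit here and both
the pre- and post-exclusion memberships are returned.

## Numerical and testing choices

* Determinism: every stochastic step (amplitude draws, noise, cohort
  jitter, the random systolic spike) flows from explicit integer seeds;
  helper RNG scopes restore the caller's RNG state.
* The separation rule compares sample gaps with a 1e-9 tolerance so that
  peaks exactly `min_separation` apart are retained on every platform.
* Degenerate inputs fail loudly and specifically: empty/overlapping ROIs,
  non-monotone time axes, windows outside 10–40 frames, non-positive
  $F_0$, constant groups in ANOVA, degenerate quartiles.
* Validation is oracle-based: the decay fitter is checked against a
  grid-search over $k$ with $(A, C)$ profiled by linear least squares and
  golden-section refinement; the detector against a brute-force prominence
  scan; the statistics against closed-form hand computations and analytic
  power; the whole pipeline against simulator ground truth.
* Problem sizes in the heavier recovery checks are the package's choice:
  500 decay segments; 50 full-protocol cells (3 min paced + 1 min pause)
  for end-to-end recovery; 200 seeded runs for count exactness; 100
  replicate cohorts of 2 × 12 cells with a 90 s paced phase (45 stimuli,
  well above the 30-spike QC floor) for the direction-of-effect check.

## Known limitations

* No sub-frame peak interpolation: at 97 frames/s a sampled apex can sit
  up to ~1% below the true apex at the default kinetics.
* No Ca^2+^ spark (sub-cellular event) detection; the analysis is
  whole-cell.
* No automated cell segmentation — ROIs are provided by the user or a
  fixture, as in the original manual workflow.
* The simulator's amplitude variability and noise levels are plausible
  placeholders (no variability statistics were published for the real
  recordings), so recovery results quantify estimator behavior under the
  stated conditions only.
* No hierarchical cell-within-animal model; strong per-animal effects
  would require aggregating summaries before testing.
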