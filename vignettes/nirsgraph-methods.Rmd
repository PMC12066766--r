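---
title: "From raw fNIRS intensities to brain-graph statistics: the nirsgraph methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw fNIRS intensities to brain-graph statistics: the nirsgraph methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsgraph)
library(dplyr)
```

# The problem

Continuous-wave functional near-infrared spectroscopy (fNIRS) measures
cortical hemodynamics through the attenuation of near-infrared light at two
wavelengths per source-detector channel. In psychomotor-training
experiments, a cohort trains on a set of selection interactions (here:
poking, raycasting, scrolling, moving) under one of two modalities (hands-on
AR practice vs. video observation), and the neural question is whether the
trained groups — and the two sexes — differ in task-evoked activation of
motor-related cortex, in functional connectivity between channels, and in
the efficiency and community structure of the resulting weighted brain
graph.

`nirsgraph` implements that full analysis chain as tested, reusable code:
preprocessing of raw two-wavelength intensities to oxygenated-hemoglobin
(HbO) concentration changes, trial-wise region-of-interest (ROI) activation,
thresholded Pearson connectivity with Monte Carlo threshold calibration,
weighted graph-theory metrics, and normality-gated factorial statistics.
Because no human recordings ship with the package, a first-class synthetic
cohort generator reproduces the study design (33 participants, 17 m/16 f,
AR 8m/8f vs. video 9m/8f) with injectable group-by-sex effects, so every
stage — and the group-level inference — is testable end to end.

# Preprocessing model

The chain follows the standard fNIRS toolbox order; every step is a
`preprocess_config()` field.

**Optical density.** Per channel and wavelength,
`OD(t) = -ln(I(t) / mean(I))`. The natural-log convention must match the
extinction coefficient table; the shipped defaults (a published 760/850 nm
tabulation in 1/(mM·cm)) are on that scale.

**Kurtosis-guided wavelet despiking.** Each OD series is decomposed with a
5-level periodized Daubechies-5 transform (implemented in the package; its
perfect-reconstruction property is unit-tested). Motion spikes concentrate
energy in few large detail coefficients, making a level's raw kurtosis
(Gaussian = 3) exceed the threshold of 3.30; the largest-magnitude
coefficient of such a level is zeroed repeatedly until the level's kurtosis
is at or below threshold. The raw-kurtosis convention is deliberate: a 3.30
threshold is meaningful only on the scale where a Gaussian level sits at 3.
The guarantee — every processed level ends at or below threshold — is a
statement about the corrected coefficient state, which
`wavelet_despike(diagnostics = TRUE)` exposes.

**Hybrid spline / Savitzky-Golay correction.** Baseline shifts are detected
from the moving standard deviation (1 s window) via a robust z-score
(threshold 3) with a multiplicative floor (2x the median moving std) so
smooth, nearly noise-free stretches are never flagged. Each detected
segment is modelled by a cubic smoothing spline (about 2 df per second),
the trend is subtracted, the residual is re-anchored to the mean of a short
pre-segment window, and everything after the segment is shifted to restore
continuity; a 10 s, order-3 Savitzky-Golay filter then smooths residual
fast transients. Window-mean (rather than single-sample) anchoring matters:
it keeps the re-levelling error at the noise-mean scale instead of the
noise scale.

**Band-pass.** A 3rd-order Butterworth band-pass (0.010-0.50 Hz) applied
forward-backward (`signal::filtfilt`) with mirror padding: exactly zero
phase, squared magnitude response, DC removed by demeaning. Cardiac
(~1.1 Hz) noise and slow drift fall outside the band; the acceptance suite
measures the contract by FFT (0.1 Hz gain in [0.95, 1.05], 1.2 Hz gain
below 0.1, zero lag).

**Modified Beer-Lambert law.** Per channel, the 2x2 linear system
`dOD_w = (eps_HbO,w dHbO + eps_HbR,w dHbR) * d * DPF_w` is inverted with
the source-detector distance `d` (cm) and a differential pathlength factor
of 6.0 at both wavelengths (overridable); results are in uM. The default
chain filters OD before conversion; since the conversion is linear the
alternative order gives the same signal, and both are supported.

Two ordering/convention points are deliberately configurable because the
field is split on them: filter-before vs. filter-after conversion, and the
wavelet/spline steps can be disabled individually (`correct_wavelet`,
`correct_spline_sg`), which also defines the *deterministic inversion
chain* used for forward/inverse validation.

**A limitation worth knowing.** The two artifact correctors are adaptive:
they estimate what "background" looks like from the series itself. On
degenerate, strictly noise-free input they misread the task response as the
anomaly (the kurtosis of an almost-silent detail level is meaningless, and
the moving-std detector is scaled by a near-zero MAD). The package
therefore validates (i) the corrections on their intended inputs — spike-
and step-contaminated noisy series — and (ii) inversion fidelity through
the deterministic chain, where a noise-free recording is recovered to
machine precision (relative RMSE far below the 5% contract). Real
recordings always carry physiological noise, so the degenerate case does
not arise in practice, but scripted pipelines on synthetic noise-free data
should use the deterministic chain.

# Activation model

Trial windows come from the headset log as half-open intervals
`[t_start, t_end)` on the recording clock (the sample at `t_end` belongs to
the next event, so consecutive trials never share a sample). Per channel,
trial activation is the mean HbO over the trial window minus the
participant's global baseline — the mean over the second two minutes
(`[60 s, 180 s)`) of the three-minute rest. ROI values average
channels-within-trial first, then trials within an interaction; baseline
subtraction commutes with both averages, so channel-level subtraction (the
implementation) and ROI-level subtraction are identical. A region whose
channels are all missing is flagged missing, never coerced to zero.

Outliers are flagged per measurement family (by default each
interaction-by-region cell, across participants) with the 1.5x
interquartile-range rule, quartiles by linear interpolation (type 7) —
documented because fence placement depends on the quartile convention.
Which family Bonferroni and the outlier filter run over is an explicit
argument everywhere, never a hidden default.

# Connectivity and the spuriousness threshold

Connectivity uses the evaluation phase only: the four interactions' trial
segments are spliced into one continuous series per channel (rest removed,
task order preserved), because individual interactions are too short for
stable correlation estimates. Pearson correlations between all channel
pairs form the connectivity matrix; pairs with `|r|` at or below the
spuriousness threshold are discarded from connection counts (strictly
greater than the threshold is kept). Counts are reported within the motor
block (LM1, RM1), within the frontal block (FEF/CG, SMA, LPMC, RPMC), and
between blocks; with the six default regions the three counts partition the
retained pairs.

The default threshold 0.291 is the conventional calibrated value for this
chain; `calibrate_threshold()` reproduces the calibration: the empirical
99th percentile of `|r|` between independent simulated series at the
chosen length and noise model. For white noise it matches the analytic
t-distribution critical value (the acceptance suite demands agreement
within 0.01 at n = 200, 10,000 simulations); band-passed noise is
autocorrelated, has fewer effective degrees of freedom, and yields a
strictly larger threshold — the reason calibrated fNIRS thresholds exceed
the textbook white-noise value.

# Weighted graph metrics

Graph metrics intentionally use the *unthresholded* correlations to avoid
threshold-choice bias. Nodes are channels; the default edge weight is
`|r|` because the weighted formulas (geometric means, inverse path
lengths) require weights in [0, 1] and the sign convention for negative
correlations is unsettled; clipping negatives to zero is available and
recorded in provenance. Path lengths use `length = 1/w`.

- Global efficiency: mean inverse shortest weighted path length over node
  pairs; 1 on a complete unit graph, 0 with no paths.
- Local efficiency: per node, the efficiency of its neighborhood subgraph
  with cube-rooted stub weights and cube-rooted path lengths restricted to
  the neighborhood, normalized by `k(k-1)`; the normalization is chosen so
  a complete unit-weight graph scores exactly 1 and a star exactly 0 (the
  printed forms of this metric differ across sources; the package fixes
  the one with these closed-form anchors and brute-force-verifies it).
- Clustering coefficient: geometric-mean triangle intensity,
  `t_i = (1/2) sum_jh (w_ij w_ih w_jh)^(1/3)`, `C_i = 2 t_i / (k_i (k_i - 1))`,
  averaged over nodes.
- Modularity: Louvain community detection (igraph) under 20 random-order
  restarts — Louvain is order-dependent, restarts stabilize it — with the
  returned Q always *recomputed* by the package's own weighted Newman
  formula on the returned partition, never taken from the optimizer.

Every metric is verified against an independent brute-force implementation
(Floyd-Warshall paths, exhaustive triangle and partition enumeration) on
random graphs of 4-8 nodes to 1e-9, and Louvain against the exhaustive
optimum on a planted two-community fixture.

# Group-level statistics

Each dependent measure passes a Shapiro-Wilk gate: p at or above 0.05
routes to the parametric branch, otherwise to the aligned-rank branch.

The parametric branch is a two-way between-subjects ANOVA with type-III
sums of squares under sum-to-zero effects coding — the appropriate choice
for the unbalanced 8/8/9/8 design — reporting F, degrees of freedom, p and
partial eta squared `SS_effect / (SS_effect + SS_error)`. For a 2x2 design
each effect has one degree of freedom, so the type-III F is the squared t
of the effects-coded coefficient; the implementation is cross-checked in
the tests against an independent type-III computation (`car::Anova`).

The aligned-rank branch follows the published aligned-rank-transform
construction: for each effect, subtract the cell-mean estimates of every
*other* effect (unweighted marginal means), rank the aligned values with
average ranks on ties, run the full factorial ANOVA on ranks, and report
only that effect's row. Diagnostics carried with the fit verify the
construction: aligned responses sum to zero on balanced designs, and the
other effects' F statistics vanish on each aligned response.

Spearman correlation is Pearson on average ranks with the t
approximation; Bonferroni is the capped monotone map `min(1, m p)` with
the family size an explicit argument; pairwise cell contrasts use Welch t
tests on raw values or on global ranks, Bonferroni-adjusted within the
emitted family, with singleton cells flagged rather than dropped.

Calibration is part of the acceptance suite: at the 8/8/9/8 design both
branches hold a 5% type-I error within three-sigma Monte Carlo error over
2000 null cohorts, and both exceed 80% power against a 1-SD crossed
group-by-sex interaction. A note on that effect definition: a "1-SD
interaction" here displaces every cell mean by one within-cell SD in the
crossed `+/-` pattern. A *single-cell* 1-SD shift is a strictly weaker
signal (noncentrality about 2 at n = 33, power about 0.29) and no
procedure could detect it reliably at this sample size; the measure-level
simulator exposes both parameterizations.

# The synthetic cohort: what it emulates, and what it does not

`cohort_spec()` defines the reference study: per-group completion-time
parameters for the four interactions (AR faster and less variable than
video on every one), three consecutive evaluation trials per interaction
with rest periods between interaction blocks, counterbalanced block order
(poking/raycasting always before moving/scrolling), and a three-minute
baseline rest opening each recording. Per-trial durations are drawn as
`Normal(mean/3, sd/3)` truncated above 1 s, so interaction totals match
the completion-time scale. Training-phase recordings are generated only on
request (`include_training = TRUE`); the neural analysis uses the
evaluation phase, and observational (video) training has no in-headset
log.

Recordings are built by a forward model: a unit-area canonical
double-gamma HRF (peak near 6 s, undershoot near 16 s) convolved with the
trial boxcar, scaled by a regional amplitude (1 uM base, 0.25 uM
between-participant SD, uniform per-channel gain, and a per-channel
hemodynamic latency jitter of +/-1.5 s reflecting regional vascular
delays); shared AR(1) latent signals (one global, one per region) plus
sinusoidal cardiac/respiratory/Mayer components, random-walk drift and
idiosyncratic in-band noise; HbR as -0.25 x HbO; the Beer-Lambert forward
model to two-wavelength optical density; spike and baseline-shift
artifacts added in OD space; exponentiation around per-channel reference
intensities. Ground truth (amplitudes, clean series, latent loadings,
artifact times) is stored with every participant, and all randomness flows
from the cohort seed through per-participant sub-seeds, so any participant
regenerates in isolation.

Injected effects define the recoverable structure: by default AR females
receive a +3 uM SMA/LM1 activation boost and males a +0.45 uM boost to the
global latent loading (more and stronger inter-channel coupling). Both
magnitudes were fixed by a design-stage power analysis, before the
recovery checks were written, with one target: a single 33-participant
cohort should detect each injection with probability well above 95%, so
that repeated-cohort recovery rates (the 90%-of-50-cohorts checks) are
stable rather than coin flips.

Two properties of the *measurement* model shaped those choices and are
worth understanding when interpreting recovery results:

1. **Duration-driven capture noise.** Trial-mean activation of a short
   trial captures only the rising fraction of the lagged hemodynamic
   response, so the measured value is roughly `c x amplitude` with a
   capture factor `c` that varies with each participant's drawn trial
   durations. This variance scales with the amplitude itself, which caps
   the attainable effect size on raw per-interaction endpoints no matter
   how large the injected boost — and a very large boost starts feeding
   the 1.5x IQR filter, which then deletes precisely the boosted
   participants. The recovery endpoint for the activation interaction is
   therefore the evaluation-pooled SMA activation *referenced to the mean
   of the four non-injected regions*: the capture factor is common to all
   regions of a participant and cancels in the difference. That referenced
   contrast is analyzed without IQR trimming (trimming a deliberately
   large injected effect removes its carriers by construction); the
   pipeline's standard statistics keep the trimming exactly as specified.
2. **Task-evoked correlation floor.** All channels share the task
   regressor, so task data carry a correlation floor that rises with
   activation amplitude — an injected activation boost leaks into
   connectivity. The latency jitter keeps this floor realistic rather
   than degenerate, and the coupling effect is sized to dominate it.

What the generator does *not* emulate: optical photon transport and
anatomy (channel sensitivities are abstract gains), systemic physiology in
the superficial scalp layer (no short-separation channels — deliberately,
as the modelled chain has no such regression), non-stationary artifact
statistics, and any real relation between completion times and neural
amplitudes. Passing the recovery tests therefore shows the *pipeline*
is correct and calibrated under the modelled signal structure; it is not
evidence about effect sizes in real cohorts.

# Numerical choices and degenerate inputs

- Half-open time windows everywhere; the sample grid is `t = (i-1)/fs`.
- A constant response in the factorial core yields F = 0, p = 1,
  eta_p2 = 0 exactly (round-off-scale sums of squares are snapped to
  zero); a zero-error effect yields eta_p2 = 1.
- Zero-variance channels propagate as missing correlations, never as 0;
  graph construction refuses missing entries rather than guessing.
- The periodized DWT reflection-pads to a multiple of `2^levels` and
  truncates after reconstruction; series shorter than `2^levels` are
  errors.
- Quantile type 7 for all quartiles; ties get average ranks.
- Louvain uses best-of-20 restarts with the seed recorded; reruns are
  seed-identical.
- Reported problem sizes in the validation suite: 100 random graphs of
  4-8 nodes for the metric oracles, 10,000 simulations for threshold
  calibration, 2000 null and 200 alternative cohorts for statistical
  calibration, and 50 seeded cohorts (reduced recording profile: 5 Hz,
  20 s rests) for end-to-end recovery — sizes chosen so the whole suite
  runs comfortably on a laptop while keeping Monte Carlo error well below
  the margins being tested.

# A worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_participants = 12, profile = "reduced", seed = 42)
run <- run_pipeline(spec, out_dir = "run42")

# per-region activation by group and sex
plot_activation(run$activation)

# thresholded connection counts and weighted graph metrics
plot_connection_counts(run$connections)
plot_graph_metrics(run$metrics)

# the gated factorial statistics, Bonferroni-adjusted within family
run$stats |> dplyr::filter(p_adj < 0.05)
```

The run directory contains `activation.tsv`, `network.tsv`,
`graph_metrics.tsv`, `stats.tsv`, `behavior.tsv`, a markdown report, the
archived `run_spec.yml` (which reproduces the run exactly), and a
MANIFEST.
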