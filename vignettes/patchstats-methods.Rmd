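---
title: "Methods: feature extraction, event detection, and cohort statistics in patchstats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature extraction, event detection, and cohort statistics in patchstats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchstats)
```

# Scope

`patchstats` implements the computational core of a whole-cell patch-clamp
study of intrinsic excitability in aging hippocampal CA1 pyramidal neurons:
per-cell feature extraction from current-clamp step protocols (passive
properties, action-potential waveform, firing metrics, and the post-burst
afterhyperpolarization, AHP), spontaneous EPSC detection in voltage-clamp
traces by scaled-template matching with recording-quality gates, and the
cohort-level statistical battery (Grubbs outlier screening, one-way and
split-plot repeated-measures ANOVA with Tukey post hoc, Pearson correlation
panels, water-maze block averaging, delayed-matching-to-place improvement,
2^-ddCt relative quantification and densitometry fold changes).

No raw recordings accompany the study this pipeline targets, so validation
is property-based: a built-in simulator produces current-clamp and
voltage-clamp recordings with exact ground truth, and every stage is tested
on its ability to recover that truth under realistic noise.

# The measurement definitions

All traces are handled in canonical units — mV, pA, ms, MOhm — at 20 kHz
(`dt = 0.05` ms); unit conversion happens only at the I/O boundary
(`read_recording()` rescales manifests declared in V or nA).

* **Spike times** are upward 0 mV crossings of the membrane potential,
  linearly interpolated between the bracketing samples. Crossings closer
  than 1 ms are merged, which guards against noise-split crossings.
  Instantaneous frequency is 1/ISI per consecutive spike pair.
* **Resting potential** is the mean of a stimulus-free segment of at least
  100 ms.
* **Input resistance** comes from the -50 pA step: the steady-state
  deflection divided by the injected current. "Steady state" is
  operationalised as the mean over the final 20% of the step, since a raw
  extremum would be noise-inflated.
* **Membrane time constant** is the first time at which the voltage change
  reaches 63% of the steady-state change, linearly interpolated. Two
  numerical choices make this robust on noisy traces: the target level is
  63% of the *steady-state* deflection (not of a raw maximum, which grows
  with noise), and the crossing is located on a centred 4 ms moving average
  (`smooth_ms`, configurable; 0 restores the literal sample-level
  definition, which is also the exact limit for an instantaneous step).
  On a noiseless exponential with tau = 20 ms the estimator returns
  19.89 ms — the small systematic offset of the 63% convention relative to
  the e-fold point (63.2%) is retained deliberately, because the 63%
  definition is the protocol's.
* **AP threshold** is the voltage at the maximum of the third time
  derivative just before the peak of the first elicited action potential
  (the first spike of the lowest-amplitude sweep that spikes, matching
  protocol order). Derivatives are repeated central differences with a
  light 3-point moving average per stage (`smooth_pts`); the test-suite
  oracle computes raw unsmoothed differences and the two agree to one
  sample on noiseless traces. Amplitude is peak minus threshold; half-width
  is the interpolated width at threshold + amplitude/2.
* **Firing metrics**: maximum firing frequency is the largest instantaneous
  frequency across all sweeps; the F/I slope is an ordinary least-squares
  fit of the first instantaneous frequency against step amplitude,
  restricted to sweeps with a defined positive first frequency (at least
  two spikes); the adaptation index is last/first instantaneous frequency
  of the sweep nearest to 250 pA above the first spiking step (exact on the
  default 50 pA grid). Each metric reports its own undefined state without
  failing the others.
* **AHP**: the qualifying sweep is the lowest-amplitude step that fires at
  least 12 spikes during the 250 ms step — 12 spikes in 250 ms is 48 Hz,
  which is how the "~50 Hz" qualification is implemented; no separate
  frequency check is applied. Baseline is the mean over a 100 ms window
  starting 600 ms after step end; the trough is the raw minimum over the
  first 175 ms after step end; the amplitude is reported as the positive
  magnitude baseline - trough ("increased AHP" = larger magnitude).
  Because the trough is a minimum statistic, any amount of recording noise
  biases it downward by roughly two standard deviations of the band-limited
  noise; this is a property of the literal definition, and the simulator's
  noise level (below) is chosen so the bias stays well inside the 0.3 mV
  recovery budget.
* **Intrinsic QC**: cells that never reach 12 spikes are flagged
  `insufficient_spiking`; "excessive synaptic input during the AHP" is
  operationalised as the RMS of the high-pass residual (trace minus a 50 ms
  moving average, i.e. fluctuations faster than ~20 Hz) in the post-step
  epoch exceeding 0.5 mV (configurable). Excluded cells are flagged but
  still reported.

# sEPSC detection

Detection is the scaled-template (Clements-Bekkers) method: at every lag
the template is fitted to the trace by least squares in scale and offset,
and the detection criterion is the fitted scale divided by its standard
error. The default criterion threshold is 4.0 and the default template is a
peak-normalised difference of exponentials with rise 0.7 ms and decay 5 ms,
typical of CA1 sEPSCs at 32-34 degrees C; `build_template()` constructs an
averaged-event template from at least 10 aligned snippets instead. The
commercial tool named in the protocol publishes neither its exact criterion
formula nor its threshold, so only the method class can be matched.

Three guards turn criterion maxima into events:

* a candidate must hold the criterion at or above threshold for at least
  0.5 ms (`min_above_ms`) — single-sample noise excursions cross for far
  less time than any real event, so this debounce suppresses false
  positives without an amplitude floor (the criterion, and hence all
  guards, are invariant to rescaling the trace);
* two peaks are distinct events only if separated by at least the
  template's rise+decay span *and* the criterion dips between them (below
  threshold or below 75% of the smaller peak) — otherwise they are one
  ridge and the stronger wins;
* within the template span of an accepted event, candidates whose fitted
  amplitude is below 20% of it (`tail_guard`) are discarded as decay-tail
  artifacts, which otherwise dominate on very low-noise traces while
  genuinely overlapping events (comparable amplitudes) are retained.

Recording QC applies the three standard gates: access resistance never
above 30 MOhm, baseline change (median of last 10 s minus first 10 s)
below 50 pA, and event-free noise below 8 pA RMS, estimated robustly as
1.4826 x MAD of the >1 Hz residual so that events do not inflate it.
Summaries apply the first-250-events rule; when the cap binds, the
frequency denominator is the elapsed time to the 250th event (the
alternative — always dividing by the full 4 minutes — would understate the
frequency of active cells; the elapsed-time convention is declared here).

# The synthetic-data generator

The study deposits no raw data, so the generator defines the test bed. It
is an emulation designed to expose exactly the quantities the extractor
must recover, not a biophysical model of CA1 neurons.

**Current clamp.** An exponential integrate-and-fire neuron with a
spike-triggered AHP conductance and optional subthreshold adaptation:

$$C\,\dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T} + I
            - w - g_{AHP}(t)\,(V - E_K),$$

with $\tau_w \dot w = a(V-E_L) - w$ and $\tau_{AHP}\,\dot g_{AHP} =
-g_{AHP}$, $g_{AHP} \mathrel{+}= b_{AHP}$ at each spike. Integration is
fixed-step Euler at the acquisition rate (0.05 ms); stability is enforced
by parameter validation rather than adaptive stepping. When $V$ crosses
`v_cut` a stereotyped 2 ms action-potential waveform (linear rise to
+30 mV in 0.5 ms, fall to `v_reset`) is pasted into the trace so that the
0 mV-crossing spike detector is genuinely exercised — integrate-and-fire
upswings would otherwise never reach 0 mV. Ground truth (spike times from
the integrator's own log, Rin = 1/g_L, tau = C/g_L with the default
`a_w = 0`, and the AHP of the noiseless replicate measured by the package's
own AHP operator) is exact because noise is added *after* integration.

Recording noise is additive and band-limited: an Ornstein-Uhlenbeck
process with 2 ms correlation time and stationary SD `noise_sigma`,
defaulting to 0.1 mV — the baseline noise of a good whole-cell current
clamp recording. White noise at 20 kHz would be both unrealistic and
pathological for the AHP's raw-minimum trough. Spike-detection robustness
is exercised separately at 2 mV noise. The protocol default is the study's:
20 steps, -250 to 700 pA in 50 pA increments, 250 ms duration, with 150 ms
before the step and 720 ms after it so the AHP windows (which end 700 ms
after the step) always fit.

The named presets differ only in $b_{AHP}$ (young 0.14 nS, old 0.35 nS,
across-neuron SD 0.16 nS in `simulate_intrinsic_cohort()`, plus a 5% CV on
$g_L$ and $C$). They were calibrated once against the package's own
extractor on noiseless traces so that cohort mean AHP magnitudes are
~2 mV (young-like) and ~4 mV (old-like) with ~1.5 mV SD — a 2 mV group
difference, the effect scale the statistics layer must detect at the
study's group sizes. No printed AHP value anchors these numbers (the
source reports the effect only graphically), so the presets are labelled
synthetic.

**Voltage clamp.** Inward events at Poisson times with log-normal
amplitudes (median 20 pA, log-SD 0.5) and a peak-normalised
difference-of-exponentials kernel, on white Gaussian baseline noise
(default 2 pA RMS) with optional linear drift and a linear
access-resistance trajectory sampled every 10 s; 4 minutes at -75 mV is
the default regime. Amplitudes are stored positive; polarity is applied at
synthesis.

**Cohort tables.** Per-subject Gaussian features at stated group means/SDs;
correlated feature pairs are produced through a Gaussian copula whose
correlation matrix carries the target r values (attained in expectation,
exactly at |r| = 1 via the eigendecomposition factor; a non-PSD request is
an explicit error).

What the generator does *not* emulate: biophysically detailed channel
kinetics, sag/rebound, electrode artifacts, seal instability in current
clamp, correlated (non-Poisson) synaptic bombardment, and rundown. Passing
tests therefore demonstrate that the measurement definitions are
implemented correctly and recover known truth under realistic noise — not
that the pipeline is robust to every pathology of real recordings.

# Statistics

Standard tests are delegated to base R — `oneway.test(var.equal = TRUE)`,
`aov()` with an `Error(subject)` stratum for the split-plot design,
`t.test(var.equal = TRUE)`, `cor.test()` — and the package adds the pieces
base R lacks: the Grubbs screen (two-sided, single pass, at most one
exclusion per group, with the t-quantile critical value), Tukey-Kramer q
statistics and adjusted p from `ptukey()` with the within-group df, and
the scalar derived measures. Design choices where the protocol is silent:

* Grubbs at alpha = 0.05, no iterative re-testing (the protocol states at
  most one animal per cohort was excluded).
* The repeated-measures ANOVA applies no sphericity correction by default;
  Greenhouse-Geisser epsilon is available (`gg_correction = TRUE`) but off,
  since the protocol names none.
* The t test is pooled-variance, matching the unqualified "Student t-test".
* Correlation panels report unadjusted per-marker p values, matching the
  per-marker reporting convention; Benjamini-Hochberg adjustment is
  available but off by default.
* Undefined metrics propagate as missing values; correlations drop pairs
  pairwise and report n per pair.
* Fold changes: 2^-ddCt normalises each sample's target Ct to the
  reference gene and the calibrator group's mean dCt (the calibrator's
  geometric mean fold is 1 by construction, and plate-wide Ct shifts
  cancel); densitometry divides band by loading control and normalises to
  the reference-group mean ratio.
* DMP improvement uses per-day trial means (day-20 mean minus day-23
  mean), the day-mean convention of the group-level figures.

# Validation strategy and problem sizes

The test suite checks every operation against hand-computed examples,
closed-form constructions (an imposed -4 mV, tau = 150 ms post-step decay
yields an AHP of 3.9466 mV under the literal windows), and independent
brute-force oracles (raw finite differences for the threshold, dense
resampling for the half-width, normal equations for the F/I slope, direct
sums of squares for all ANOVA variants, `stats::TukeyHSD` for the Tukey
p values). Property-based blocks run at the following sizes, chosen to
give stable Monte Carlo estimates at desk scale: 50 neurons per preset for
ground-truth recovery (recovery tolerances are read as mean absolute error
across the cohort — for a min-statistic like the AHP trough a per-neuron
worst-case bound is not meaningful under any nonzero noise); 10 seeds per
rate for sEPSC recovery at 0.5/2/5 Hz; 2000 null tables for type-I and
family-wise error calibration; and 500 pipeline replicates for the power
property at the study's 10/12/19 neurons per group. `scripts/acceptance.R`
recomputes the same quantities from scratch (at 300 power replicates and 5
seeds per detection rate) and writes them as JSON.

# Known limitations

* The AHP-vs-$b_{AHP}$ response of the simulator is locally non-smooth
  because the qualifying sweep (lowest step with 12 spikes) changes
  discretely as adaptation strength grows; cohort-level calibration
  averages over this.
* The detector's criterion threshold of 4.0 is a convention, not a matched
  reproduction of the commercial tool's unpublished threshold; operating
  characteristics (false-positive rate versus sensitivity) are validated
  against the package's own simulator only.
* `ap_threshold` assumes the first elicited action potential is clean;
  overlapping spikes within the 2 ms search window would confound the
  third-derivative maximum.
* The split-plot ANOVA requires a complete design; missing cells are an
  error rather than an imputation.
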