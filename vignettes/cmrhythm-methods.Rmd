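---
title: "Methods: models, estimators and conventions in cmrhythm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and conventions in cmrhythm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrhythm)
```

# Scope

`cmrhythm` analyses arrhythmogenic behaviour of cardiomyocytes at three
scales — single cells (patch-clamp action potentials, fluorescence Ca²⁺
transients, two-channel micrographs), beating networks (microelectrode-array
electrograms) and whole hearts (ECG beat series) — and ships seeded
synthetic generators for every modality so each analysis stage can be
validated against ground truth without experimental data. This vignette
records the models, the estimator choices, the default parameters and their
provenance, and the known limits.

Conventions throughout: time in seconds, 0-based sample indices (sample *i*
of a trace lives at `t0_s + i/rate_hz`), half-open analysis windows
`[t_start, t_end)`, intracellular voltage as recorded (negative diastole,
no rescaling), and the sample standard deviation (n − 1 denominator)
wherever a "SD" is reported.

# The synthetic action potential

`gen_ap_train()` builds a phenomenological, not biophysical, waveform from
four interpretable parameters: MDP (default −70 mV), peak (+35 mV), APD₉₀
(300 ms) and maximal upstroke velocity (40 V/s) — values in the range of
spontaneously firing iPSC-derived cardiomyocytes, digitized at 10 kHz.
Three pieces make closed-form feature checks possible:

* **Upstroke**: a raised cosine whose maximal slope equals the
  `upstroke_vps` parameter exactly at its centre. A linear ramp has no
  unique derivative maximum, which makes "activation time" ill-defined at
  one-sample precision; the raised cosine keeps the stated slope as a
  sharp, measurable extremum.
* **Peak**: a shallow parabolic dome (1 mV drop at the edges) instead of a
  flat plateau, so the peak sample is unique under noise and detected beat
  times do not wander along a plateau.
* **Repolarization**: a normalized exponential,
  $V(t) = \mathrm{MDP} + R\,\frac{e^{-t/\tau} - E}{1 - E}$ with
  $E = e^{-T_{rep}/\tau}$, which lands exactly on the MDP at the next beat
  onset. The time constant is solved per diastole (1-D root finding) so
  that the crossing of $\mathrm{peak} - 0.9\,\mathrm{APA}$ falls exactly
  APD₉₀ after activation. Without the normalization the exponential tail
  biases the measured MDP by ~0.01 mV and the APD₉₀ crossing by about one
  sample — visible at the tolerances the closed-form tests use.

Injected events are half-sine subthreshold bumps: DADs as damped runs
(amplitude drawn uniformly from 5–15 mV, damping 0.65/cycle, 1–3
oscillations), OPPs as growing runs (3–6 oscillations, +25 %/cycle) ending
just before an AP, failed beats as a single bump replacing a scheduled AP.
The source protocols describe these morphologies only qualitatively;
amplitudes and run lengths are generator conventions, declared here and in
the docs. Events that would collide with the next AP's refractory window
are rejected with an error. Band-limited Gaussian noise (default SD 0.5 mV)
is shaped by the same quadratic smoother used elsewhere and rescaled to the
requested SD.

# AP feature extraction

`compute_ap_features()` reads amplitudes off a **running-median** filtered
copy of the trace (window 5 samples): the running median is the identity on
monotone segments, so closed-form waveform values survive exactly, and it
has no overshoot at step-like transitions, where a polynomial smoother
rings by several mV. The derivative for dV/dt<sub>max</sub> instead uses
Savitzky–Golay smoothing (quadratic, window 5) followed by central
differences — at 10 kHz the attenuation of an upstroke spanning ~40 samples
is far below 1 %. The dV/dt maximum is refined to sub-sample precision by
parabolic interpolation and the APD₉₀ crossing by linear interpolation, so
the APD₉₀ error on noise-free traces is well under one sample.

APD₉₀ is referenced to **activation** (the dV/dt<sub>max</sub> time), not
to the peak. The underlying protocols do not state the reference; the
activation convention is standard in cellular electrophysiology, it is
recorded in the result object, and `apd_reference = "peak"` is available.
The MDP search window runs from the previous beat's 90 %-repolarization
crossing to just before the current upstroke; the first beat searches from
the trace start.

# Event detection and classification

`detect_subthreshold_events()` searches the diastolic intervals (everything
outside activation → APD₉₀ crossing, ± 30 ms margin; trace edges that the
smoother leaves raw are excluded) of a heavily smoothed copy (5 ms window —
the events are ≥ 50 ms wide, so this suppresses noise without attenuating
them). Candidates are local maxima whose **topographic prominence** (height
above the higher of the two key cols toward the nearest higher ground) lies
between 2 mV and 0.5× the median APA. Prominence is computed against the
full relief rather than between adjacent candidates; the latter collapses
when spurious noise maxima sit on a slope.

`classify_events()` applies the rules in order, per diastolic run:

1. **OPP** — ≥ 3 candidates, strictly increasing amplitudes, a following
   AP exists;
2. **failed beat** — a candidate within ±25 % of the expected beat time
   (previous beat + running median of the preceding 10 IBIs) whose
   enclosing IBI exceeds 1.5× that median;
3. **DAD** — any remaining run with non-increasing amplitudes (0.5 mV
   noise slack) after a normally timed AP.

Anything else is kept as `unknown` with a warning — classification is
exhaustive and nothing is dropped silently. The strict
increasing-amplitude, run-length ≥ 3 rule is this package's resolution of
the qualitative boundary between "a few damped oscillations" (DAD) and an
OPP run; it is surfaced in the documentation as a convention. The running
median tolerates slow rate drift. All thresholds live in
`default_config()` with per-key provenance (`config_provenance()`).

The ≥ 3-events/cell arrhythmogenic rule and the events/min occurrence are
protocol-stated definitions and are tested as exact arithmetic.

# Beat-rate variability

With IBIs $x_1 \dots x_n$:
$\mathrm{SD1}^2 = \tfrac12\,\mathrm{Var}(x_{i+1} - x_i)$,
$\mathrm{SD2}^2 = 2\,\mathrm{Var}(x) - \mathrm{SD1}^2$ (floored at 0),
$\mathrm{CV} = 100\,\mathrm{SD}(x)/\bar x$, all with sample variances.
These are the Poincaré-ellipse semi-axes (SD1 perpendicular to the identity
line, SD2 along it, centred at the centroid). The identity
$\mathrm{SD1}^2 + \mathrm{SD2}^2 = 2\,\mathrm{Var}$ and agreement with
brute-force variance sums to 1e−12 relative are tested. The 40-bin IBI
histogram is display-only; no decision uses it.

**Bimodality** is declared when a 2-component Gaussian mixture beats the
1-component fit by BIC *and* the component means are separated by more than
twice the pooled within-component SD — the "two clouds with minimal
overlap" signature. Variances are floored at (1 ms)²; an effectively
constant series short-circuits to unimodal. **Poincaré cloud counting**
fits 2-D mixtures with k = 1…4 and returns the BIC-selected k. Mixture
fits use `mclust`, whose EM initialization from model-based hierarchical
clustering is deterministic, so no random restarts are needed; ties in BIC
resolve to the smaller k by the order mclust evaluates models.

The bimodal IBI generator is a two-state process with a configurable switch
probability (default 0.5), not an i.i.d. mixture: with switching at 1 the
lag-1 plot shows only the two off-diagonal clouds, with 0.5 all four
combinations appear — the four-cloud Poincaré pattern of bimodally firing
preparations. Presets for the figure-level runs use a tight unimodal
process (mode 1.0 s, SD 0.03 s) against a bimodal one (0.8/1.6 s, SD
0.04 s).

# Ca²⁺ transients

`gen_ca_trace()` emulates fura-2-style ratio recordings at 100 samples/s
(the conventional fluorescence acquisition rate). Each beat produces a
normalized exponential rise reaching exactly baseline + A after
3 τ_rise (defaults: A = 0.8 ratio units, τ_rise = 0.15 s — iPSC-CM
transients are slow) and a normalized exponential decay (τ_decay = 0.40 s)
returning exactly to baseline at the next beat, at a default period of
1.5 s. The normalization keeps amplitudes exact by construction while the
maximal rates stay closed-form
($A/(\tau_r(1-e^{-3}))$ at onset, $A/(\tau_d(1-E))$ at the peak); both are
stored per transient in the ground truth. Beats are snapped to the sample
grid so ensemble averaging is exact. A caffeine bolus yields one transient
of amplitude `f_caf`·A with a slower decay, then quiescence such that the
first resumed transient peaks exactly `gap_s` after the caffeine peak.

Estimator choices, all driven by the 100 Hz resolution:

* **Per-transient maximal rates** use raw first differences. A numerical
  study at the design stage showed that Savitzky–Golay smoothing (window
  5) followed by central differences biases the rise-rate maximum of an
  exponential onset (τ = 0.12–0.15 s) by about −22 % at 100 Hz — the
  smoother straddles the onset corner — while the forward difference stays
  within −4 %.
* **Ensemble averaging** aligns 20 consecutive transients at the mid-rise
  crossing, where the slope is steepest: alignment jitter under 2 % noise
  stays below one sample there, whereas peak-aligned averaging (the naive
  choice) wanders by several samples on the slow exponential top and
  visibly rounds the averaged peak.
* **Ensemble rates and kinetics** come from a least-squares fit of the
  transient model (with a free time-offset parameter, because the averaged
  top is rounded and its argmax is a poor time origin) to the average;
  the reported maximal rates are the fitted waveform's analytic
  derivatives. Numerical differentiation of the average is unbiased only
  noise-free: its extrema collect extreme-value noise of order
  $\sigma\sqrt{2}\,f_s/\sqrt{20}$, which at 2 % noise is comparable to the
  decay rate itself. The fit pools all ~150 samples of the average
  instead. The cost is a model assumption (single-exponential rise and
  decay), which is the standard phenomenological description of
  fluorescence transients; for waveforms far from it the per-transient
  first-difference rates remain available.

The caffeine parameters follow their definitions directly: recovery time
from the caffeine peak to the first *measurable* subsequent transient peak
(measurable = amplitude ≥ 25 % of the mean pre-caffeine amplitude, a
declared convention, configurable); % amplitude change against the mean
pre-caffeine amplitude; area fold change with trapezoidal areas above each
transient's own baseline, integrated from onset to 95 % return. Whether
per-recording rates should come from single transients or the 20-average
is left open by the protocols; both are emitted.

# Imaging

The synthetic cell is an ellipse with a disk nucleus strictly inside it;
the nuclear channel is nonzero only on the nucleus, and the signal
channel's expected intensity is ρ_C on the cytoplasm and
`nc_ratio`·ρ_C on the nucleus, with Gaussian (default 5 % of the mean) or
Poisson noise. Named presets pin the N/C ratio at 1.30, 0.25, 2.66 and
2.36 — the nuclear-retention, cytoplasmic-export and nuclear-sequestration
regimes of the proteasome-distribution experiments this pipeline serves.

Segmentation uses *fixed* thresholds (the analysis convention is one
constant threshold across a dataset): nucleus = largest connected
component above the nuclear threshold, holes filled; cell = largest
component above the signal threshold that contains the nucleus;
cytoplasm = cell − nucleus. `suggest_threshold()` proposes a value from
the intensity histogram but never applies it. Densities follow the
raw-integrated-density convention (summed intensity / area in pixels);
N/C is their ratio, invariant to rescaling the signal channel. One cell
per tile (largest-component rule); multi-cell fields must be pre-tiled.
Whether the original cell outlines came from a cytoskeletal-marker channel
or manual ROIs is not stated in the protocols; this package outlines the
cell from the signal channel with the containment rule, which is exact on
the synthetic geometry and is documented as a difference.

# Whole-heart VA scoring

`detect_va_episodes()` works on beat times only: baseline RR = median RR
over the first 60 s; a VA beat is an RR below baseline/1.5; consecutive VA
intervals merge into episodes and episodes closer than 2 s merge.
*Sustained* means strictly longer than 30 s — a protocol-stated rule — and
the fractional duration is the episode time as a percentage of the
recording. VT and VF are deliberately not distinguished; both pool into
VA. The ECG generator produces rat-range sinus rhythm (5 Hz, 2 % RR
jitter) with injected fast episodes (12 Hz, 8 % jitter) and records true
boundaries; episode boundaries are recovered within one beat interval.

# Pacing protocol

`paced_epochs()` labels 20-pulse trains at 0.5/1.0/1.5/2.0 Hz with 20 s
pauses (the protocol's structure; wrong pulse counts are an error) and
`score_pacing_response()` flags a rate as arrhythmic when a classified
event falls in its post-train pause or firing ceases for more than twice
the median pre-pacing IBI (cessation factor 2, a package convention).

# Group statistics

`compare_groups()` reproduces the figure-legend decision tree: per-group
normality by the one-sample Kolmogorov–Smirnov test against a normal with
estimated mean/SD (the protocol names KS but not the variant; the
estimated-parameter KS is anti-conservative, and the Lilliefors-corrected
variant is available via `lilliefors = TRUE` — both are documented with
that caveat). All groups normal → ANOVA + Tukey (≥ 3 groups) or pooled t
test (2 groups); otherwise Kruskal–Wallis or Mann–Whitney. Pairwise post
hocs only on the parametric ≥ 3-group branch. Constant groups force the
non-parametric branch with a warning. No multiple-testing correction is
applied across features by default (matching the source analyses); Holm is
available via `p_adjust`. Under a three-group Gaussian null the tree's
empirical type-I error is checked against 0.05 ± 0.01 over thousands of
simulated cohorts.

# Problem sizes

The defaults used by the test-suite and the acceptance script are sized
for a desk-scale replication: AP traces of 30–60 s at 10 kHz, MEA runs of
~120 spikes at 1 kHz, ECG feature traces of 60–120 s at 500 Hz with
whole-heart scoring on 90-min *beat series* (not sampled traces), Ca²⁺
traces of 40–60 s at 100 Hz, 128×128 px image tiles, IBI series of 200–400
intervals, cohorts of 3–8 recordings per group, 20-seed replication for
detection and directional checks, and 2000–5000 simulations for the
statistics calibration. These are the package's choices for fast, exact
validation; every generator scales to longer recordings by its arguments.

# What the generators do and do not emulate

They reproduce: spontaneous AP trains with the three event morphologies;
unimodal and alternation-structured bimodal IBI processes; biphasic
extracellular spikes over wander and band-limited noise; rat-range sinus
ECG with abrupt fast-rate episodes; per-beat Ca²⁺ transients with a
caffeine response; disk-in-ellipse cells with prescribed compartment
densities. They do not reproduce: ionic-current dynamics (no rate
adaptation, alternans or restitution), EADs, multi-electrode conduction,
ECG morphology (P/QRS/T shape, supraventricular vs ventricular origin),
photobleaching or motion artefacts, or irregular cell geometry and uneven
illumination. Passing tests therefore demonstrate correctness of the
*measurement definitions and decision rules* on signals whose ground truth
is known — not robustness to every pathology of real recordings.

# Known limitations

* Amplitude extrema (MDP, per-transient Ca amplitudes) are order
  statistics and acquire a small positive bias under noise; the ensemble
  fit avoids this for Ca kinetics, and the noise-free tests pin the exact
  values.
* The ensemble Ca rates are model-based (see above); per-transient
  nonparametric rates are reported alongside.
* The bimodality rule (BIC + 2×pooled-SD separation) targets
  well-separated modes; heavily overlapping regimes will be called
  unimodal by design.
* HDF5 trace I/O is not included; CSV/TSV (with `# key=value` metadata
  headers) are the interchange formats.
* Frequency-domain variability (LF/HF), APD at other repolarization
  levels, and template-matching spike sorting are out of scope.
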