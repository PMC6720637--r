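---
title: "Methods: from neurophysiological signals to workload estimates"
author: "cogniphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from neurophysiological signals to workload estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogniphys)
```

cogniphys implements a sensing-to-estimation chain for neuroergonomics: it
extracts oculomotor, cardiac and respiratory features from raw time series,
maps them to a cognitive-state estimate (the worked example is mental
workload, MWL, on a 0–1 scale) with a Sugeno-type neuro-fuzzy system, and
propagates sensor measurement uncertainty through the inference network.
This vignette records the models, the tunable parameters, the numerical
choices, and — importantly — what the synthetic-data generators do and do
not demonstrate about real recordings.

## Gaze event detection

**Fixations** are found by dispersion-threshold identification (I-DT): a
window of consecutive valid samples is grown while the bounding-box diagonal
$D=\sqrt{(x_{max}-x_{min})^2+(y_{max}-y_{min})^2}$ stays below `d_max`, and
is emitted as a fixation if it lasts at least `min_duration`. Neither
threshold has a single canonical value in the literature; the defaults,
`d_max = 1.0`° and `min_duration = 0.1` s, are standard I-DT practice and
both are exposed in `cogniphys_config()`. The implementation maintains
running extrema; the test suite checks it against a brute-force oracle that
recomputes the dispersion from scratch at every candidate extension.

**Saccades** are detected independently (the two definitions are
independent: dispersion for fixations, velocity for saccades). Angular
velocity is estimated by central finite differences of position — the
continuous definition $v=\sqrt{\dot x^2+\dot y^2}$ says nothing about
estimation — followed by a 3-sample median filter to suppress single-sample
noise spikes. A saccade is a maximal run with $v \ge 30$°/s whose duration
lies in 30–80 ms, the physiological range; faster-but-longer epochs (smooth
pursuit) are rejected by the duration bound. Because the central difference
straddles event boundaries, the boundary samples of a step displacement
carry half the interior velocity; a fixation may therefore share a boundary
*instant* with an adjacent saccade, and the partition property is asserted
for event interiors. Below 60 Hz sampling, finite-difference velocities are
unreliable and results are flagged low-confidence rather than suppressed.

**Blinks** are maximal runs of invalid samples no longer than `max_gap`
(default 0.5 s); longer runs are tracking loss. Blink rate is reported per
minute and percentage closure (PERCLOS-style) as summed closure time over
the span; both are translation invariant.

**Dwells and transitions.** Consecutive fixations whose centroids fall in
one rectangular ROI collapse into a dwell; fixations outside every ROI break
runs. ROI boundaries are closed on the min edges and open on the max edges,
so a centroid exactly on a shared edge belongs to the lowest-indexed
containing ROI — an arbitrary but deterministic tie-break. One-way
transition counts between consecutive dwells are row-normalised; the
diagonal is structurally zero because a dwell cannot follow itself. Visual
entropy is
$H=-\sum_i p(X_i)\sum_j p(Y_{ij}|X_i)\log_2 p(Y_{ij}|X_i)$ with
$0\log 0 := 0$, maximal at $\log_2(m-1)$ bits when every row is uniform over
its off-diagonal targets.

**Nearest-neighbour index.** The printed expectation formula for the mean
random nearest-neighbour distance in our source material is not
dimensionally interpretable, so the package uses the standard
complete-spatial-randomness expectation $\bar r_E = 0.5\sqrt{A/N}$. The
reference area $A$ defaults to the bounding box of the fixation centroids
when not supplied. No edge correction is applied; at the $N$ used in the
tests the boundary bias is below 1%.

**Pupil band power** integrates a Welch periodogram (Hann window, segments
of at most 4 s, 50% overlap) of the pupil radius over 2–6 Hz. The spectral
estimator is a documented package choice — the defining integral names no
estimator. Blink gaps are linearly interpolated before transforming, which
is adequate for the short (≲ 0.5 s) gaps blinks produce but will smear
longer dropouts.

## Cardiorespiratory metrics

The cardiac entry point is the RR-interval series; R-peak detection from raw
ECG is out of scope. `clean_nn()` produces the normal-to-normal series by
rejecting intervals outside physiological bounds (default 300–2000 ms) or
deviating from the median of their 5 index-nearest neighbours by more than
30% — rejection is always explicit (`rejected_count`), never silent, and a
warning fires above 20% rejection.

Time-domain metrics use the sample ($n-1$) standard deviation, pNN50 counts
strictly-greater-than-50 ms successive differences over the $n-1$ pairs, and
heart rate is $60/\overline{RR}$ (s). These are checked against a
direct-summation oracle at $10^{-12}$ relative.

Frequency-domain metrics integrate the PSD of the unevenly sampled RR
tachogram over ULF (≤ 0.003 Hz), VLF (0.003–0.04), LF (0.04–0.15) and HF
(0.15–0.4 Hz). Two estimators are provided because the choice is genuinely
open for uneven sampling: Lomb–Scargle on the beat-stamped intervals
(default; no resampling artefacts) and cubic-spline resampling at 4 Hz
followed by Welch. Relative LF/HF powers are taken over the whole 0–0.4 Hz
total, exactly as the band definitions integrate it; for records under
5 minutes ULF and VLF are reported absent with a reason and excluded from
that total. The two estimators are pinned together by an invariance test on
stationary tones (band fractions agree within 2%). LF/HF is reported as a
percentage ratio ($LF/HF\times 100$).

Poincaré geometry uses
$SD1=\sqrt{0.5\,\mathrm{Var}(RR_i-RR_{i+1})}$,
$SD2=\sqrt{0.5\,\mathrm{Var}(RR_i+RR_{i+1})}$ with the sample variance,
matching the time-domain convention. A sliding 30 s window yields per-window
summaries alongside the whole-record default. The fitted ellipse is the
standard construction: semi-axes $SD2$ (along the identity line) and $SD1$,
rotated by $\pi/4$ about the centre of mass of the lag plot. The identities
$SD1^2+SD2^2 \approx 2\,SDRR^2$ and $SD1 \approx RMSSD/\sqrt2$ are enforced
in tests at 2% on long stationary series.

Respiratory cycles come from derivative zero crossings of the 1 Hz
low-passed volume trace with a 1 s minimum same-type extremum spacing
(breathing stays below 60/min). Tidal volume is peak-to-trough per cycle;
minute ventilation is $BR \times \overline{TV}$ with mL→L conversion, an
exact internal identity.

**Filtering.** `butterworth_chain()` applies order-2 Butterworth sections
(12 dB/octave each) forward–backward for zero phase, with odd-reflection
edge padding scaled to the slowest cutoff so start-up transients stay out of
the record. Zero-phase application squares the magnitude response; the
effective roll-off is therefore 24 dB/octave and a 10 Hz tone through a
30 Hz low-pass retains amplitude $1/(1+(1/3)^4)\approx 0.988$, not 1. The
tests freeze that computed gain rather than pretending the single-pass
response applies.

## The Sugeno neuro-fuzzy estimator

The engine is the standard five-layer network: fuzzification by trapezoid,
Gaussian or sigmoid membership functions (validated at construction, never
at evaluation); product AND for rule firing strengths
$w_k=\prod_i \mu_{A_{ik}}(x_i)$; normalisation $\bar w_k = w_k/\sum_k w_k$;
polynomial consequents $f_k = p_{k0} + \sum_i p_{ki}x_i$; and
weighted-average defuzzification $y=\sum_k \bar w_k f_k$. Product-AND and
weighted-average defuzzification are the ANFIS conventions; the source
material names only "a fuzzy AND operator" and "a defuzzifier". An input
where no rule fires raises an explicit error rather than returning 0/0.

The worked example, `mwl_example_model()`, encodes three zeroth-order rules
relating heart rate and breathing rate (min⁻¹) to MWL, anchored at a
participant's low/medium/high cluster centres (HR 63.2/64.9/68.3,
BR 11.5/14.6/15.3):

```{r}
print(mwl_example_model(family = "trapezoid"))
```

Note the rule base pairs high HR with *low* BR although the high-workload
cluster has the highest BR. The rules are implemented verbatim as printed;
`rules_from_clusters = TRUE` instead aligns antecedent labels with cluster
labels, and that form is used for calibration round trips. Neither form is
asserted as the "true" intent — the discrepancy is preserved, not repaired.

When only centres are known, Gaussian spreads default to half the distance
to the nearest neighbouring centre per input (`spread_frac = 0.5`); the
trapezoidal variant uses compact disjoint supports so that at each cluster
centre exactly one rule fires, which makes the crisp outputs 1, 0.5 and 0.1
exact at those points.

**Calibration** is two-stage. Consequents are fitted by linear least squares
on the normalised-firing design matrix ($\bar w_k$ columns for zeroth-order
rules, $\bar w_k\cdot(1,x)$ blocks for first-order). A rule with no samples
in its region of dominant firing shows up as a (numerically) null or
linearly dependent design column and is reported by name. Premise refinement
(optional) runs bounded quasi-Newton descent on the Gaussian centres and
spreads, refitting consequents at each step, and keeps the refined model
only if it does not worsen the residual; the procedure is deterministic and
seeded. On noiseless self-generated data the consequent recovery is exact to
numerical precision, which the tests assert at $10^{-6}$.

## Uncertainty propagation

Given independent 1-σ input uncertainties, the output uncertainty is
computed by first-order (delta-method) propagation through all five layers:

$$\sigma_y^2=\underbrace{\sum_i\Big(\sum_k f_k\,
\tfrac{\partial\bar w_k}{\partial x_i}\Big)^2\sigma_{x_i}^2}_{\text{normalisation layer}}
+\underbrace{\sum_k \bar w_k^2 \sum_i (p_{ki}\sigma_{x_i})^2}_{\text{consequent layer}},
\qquad
\frac{\partial\bar w_k}{\partial x_i}=\bar w_k\Big(g_{ki}-\sum_l \bar w_l g_{li}\Big),$$

with $g_{ki}=\partial\ln\mu_{A_{ik}}/\partial x_i$ (analytic for Gaussian
and sigmoid families). Because the normalised weights sum to one, their
sensitivities to a common input sum to zero — they are fully negatively
correlated. The default method keeps that correlation, which is the form a
Monte-Carlo propagation converges to as input sigmas shrink (verified
against numerical differentiation and an MC oracle in the tests). A
per-rule quadrature that treats the weight uncertainties as independent is
available as `method = "independent_rules"`; it can only inflate the
estimate. Known normalisation-layer uncertainties $\sigma_{\bar w_k}$ can
also be supplied directly.

**Validity of the first-order estimate.** With the worked example's
membership spreads (0.35–1.7 min⁻¹) and the characterised input
uncertainties $\sigma_{HR}=5.5$ and $\sigma_{BR}=1.6$ min⁻¹, the input
uncertainty is *larger than the membership spreads* — and σ_HR exceeds the
entire HR centre range (5.1 min⁻¹). The inference output then saturates
within one input standard deviation, and no linearisation can track the
Monte-Carlo spread: we measure first-order/MC discrepancies of up to an
order of magnitude on the cluster-centre grid, while the discrepancy ratio
does fall steadily as the sigmas are halved (4.1 → 1.6 → 0.7 at a
rule-conflict point). The corresponding test asserts the full MC-agreement
property and is expected to fail at the full printed sigmas: the honest
conclusion is that first-order propagation at this operating point is an
upper-bound indicator, not a calibrated standard error. The qualitative
structure survives, however: the uncertainty surface peaks between cluster
centres, where rules conflict, and not at the centres — asserted on the
full grid.

## Sensor characterisation

Static precision is the RMS angular distance of fixation-cluster samples
from the *cluster mean* — the reference point is not stated in the defining
formula; measuring from the mean is the standard convention and decouples
precision from accuracy. Accuracy is the distance from the cluster mean to
the true target (magnitude reported, signed components retained). Angular
distances are Euclidean in gaze-angle degrees, a small-angle approximation
in error by under 1% below ~20°. Dynamic (tracking) errors are right-skewed
and summarised by a maximum-likelihood lognormal fit, reporting
$\exp(\hat\mu+2\hat\sigma)$ — the ≈95th percentile bound. Validity against
a reference device is RMS error plus the standard product-moment
correlation (the printed correlation formula in the source contains a typo
in one denominator term; the standard Pearson form is used). Paired series
are aligned by nearest-timestamp join with a 0.5 s maximum lag; unmatched
samples are dropped and counted.

## Synthetic data: what it shows and what it does not

Every generator is seeded and deterministic; identical spec + seed gives
byte-identical output, and each generator's ground truth is recovered by the
corresponding detector within stated statistical tolerances — that
round-trip is the module's purpose.

* `simulate_gaze()` emits a fixation–saccade–blink renewal process with
  ROI-centre fixations, constant-velocity saccades and Poisson blinks
  thinned to fall inside fixations. It does *not* emulate main-sequence
  velocity profiles, microsaccades, head motion, or calibration drift.
* `simulate_rr()` uses additive sinusoidal modulation of the mean interval
  rather than an integral-pulse-frequency-modulation model, because it has
  closed-form band-power ground truth ($a^2/2$ per tone). Real tachograms
  are nonstationary and broadband.
* `simulate_workload_session()` draws HR/BR features around the three
  cluster centres. The within-state standard deviations default to about
  half the smallest per-input centre gap (HR 0.8, BR 0.35 min⁻¹): the means
  are cluster centres identified from a participant's session, so the
  emulated within-cluster spread must sit below the between-centre
  separation for such clusters to have been identifiable at all. Real
  sessions carry autocorrelated, drifting features; passing the calibration
  round trip here demonstrates estimator correctness, not field
  performance.
* `simulate_sensor_pair()` degrades a truth series with latency, bias and
  white noise; real sensor discrepancies are spectrally structured.

Problem sizes in the test suite (5-minute gaze and RR records, 600-sample
sessions, $10^5$-draw Monte-Carlo, 100-replicate ensembles) are chosen so
the statistical tolerances above are meaningful while the whole suite runs
in well under a minute of compute per module.

## Degenerate inputs and numerical conventions

Empty streams, all-invalid gaze, single RR intervals, flat respiration
traces, zero-variance series, inputs outside rule coverage and negative
radicands all produce explicit errors or reasoned absences — never silent
NaN/Inf. Entropy uses $0\log 0:=0$; band integration is trapezoidal on the
estimator's frequency grid; JSON model serialisation writes 17 significant
digits so the save→load→infer round trip is bit-exact.
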