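---
title: "Gray-zone ROC evaluation of dynamic preload indices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray-zone ROC evaluation of dynamic preload indices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidroc)
```

## The clinical question

In mechanically ventilated patients, positive-pressure breaths cyclically
reduce left-ventricular preload. On the steep part of the Frank–Starling
curve this respiratory swing shows up as beat-to-beat variation of stroke
volume (SVV), pulse pressure (PPV) and the pulse-oximeter pulse index
(the pleth variability index, PVI). Large variation suggests that a
fluid bolus will raise stroke volume — the patient is *fluid
responsive*. Different monitors measure these indices with different
algorithms and time windows, so the practical question is how well each
index, on each device, predicts responsiveness, and over which range of
index values the prediction is inconclusive (the *gray zone*).

`fluidroc` implements the full evaluation pipeline: index computation
from beat series, responder classification after a standardized fluid
challenge, per-index ROC analysis with two gray-zone estimators, AUC
comparison across indices, and the power design of such a study. A
synthetic cohort generator makes the whole pipeline testable end to end
without patient data.

## Dynamic indices and device windows

The indices follow the standard definitions

$$\mathrm{SVV} = 100\,\frac{SV_{max}-SV_{min}}{SV_{mean}},\qquad
  \mathrm{PPV} = 100\,\frac{PP_{max}-PP_{min}}{PP_{mean}},$$

computed over a trailing device window: 30 s with four-sub-window
averaging for calibrated pulse-contour analysis (`device_policy("picco")`),
a single 20 s window for the uncalibrated systems
(`"lidco"`, `"flotrac"`). The "average of four extreme values" behaviour
is interpreted as partitioning the 30 s window into four equal time
sub-windows, computing `100 * (max - min) / mean` in each, and averaging
the four ratios; this reproduces the intended smoothing of single-beat
outliers. An alternative reading (averaging the two largest maxima and
two smallest minima before one global ratio) exists; the time-based
partition was chosen because it needs no respiratory-cycle detection and
behaves identically on stationary input. Sub-windowing is purely
time-based: window ends and membership are decided by beat times, with
no interpolation.

PVI has no published closed formula; the package uses the
manufacturer-standard normalization by the maximum,
$100\,(PI_{max}-PI_{min})/PI_{max}$, which makes it scale-invariant in
the pulse index.

For a noiseless sinusoid with relative modulation amplitude $m$ about
its mean, $(max-min)/mean = 2m$, so every variation index should read
$200\,m$ percent; this closed form anchors the index tests (at the
default heart rate of 86 min⁻¹ and respiratory rate of 12 min⁻¹ the
discrete beat sampling keeps the error under a few percent for 20 s and
30 s windows, both integer multiples of the 5 s respiratory cycle).

## Responder classification

The fluid challenge compares stroke volume before and after a
standardized bolus; a patient is a responder when
$100\,(SV_{after}-SV_{before})/SV_{before}$ exceeds 15 — strictly, so a
change of exactly 15% does not qualify. Before/after comparisons of the
hemodynamic channels use the paired t-test; zero-variance differences
are reported as degenerate rather than as p-values.

## ROC analysis with two gray-zone estimators

`roc_grayzone()` is the package's central fit. Higher index values
predict responders (all dynamic indices fall after volume loading);
direction is fixed, not auto-detected.

**AUC.** Midrank pair counting (ties count one half) — identical to the
normalized Mann–Whitney statistic — with the Hanley–McNeil standard
error, a normal-approximation confidence interval clipped to [0, 1],
and a normal test against AUC = 0.5. With perfect separation the
Hanley–McNeil SE degenerates to zero; the p-value is then reported as 0
(or 1 at AUC = 0.5).

**Threshold grid.** Candidate decision thresholds are midpoints between
adjacent distinct scores; the ROC curve additionally carries one
sentinel on each side of the observed range (at half the minimal score
gap) so that it reaches both corners. The Youden-optimal threshold —
maximizing $J = Se + Sp - 1$, ties broken toward the smallest cut — is
searched over the true midpoints only: a decision cut outside the
observed values carries no information, and this keeps all reported
thresholds inside the observed range.

**Gray zone A (bootstrap).** 2000 resamples stratified by responder
status (class sizes preserved); the Youden threshold is recomputed in
each, and the zone is the 2.5–97.5 percentile interval of the replicate
thresholds. Percentile intervals were chosen over BCa as the simplest
estimator consistent with common practice for this procedure.
Degenerate resamples (a class collapsing onto a single value) keep
their defined threshold so that exactly 2000 replicates contribute.

**Gray zone B (diagnosis tolerance).** On a two-graph ROC (Se and Sp
against the threshold), values with both Se and Sp below 90% (tolerance
0.10) are inconclusive: the band runs from the largest threshold
keeping Se ≥ 90% to the smallest threshold reaching Sp ≥ 90%. The band
is evaluated on the empirical curve and on a smooth binormal curve
fitted by class-wise moments ($a = (\mu_1-\mu_0)/\sigma_1$,
$b = \sigma_0/\sigma_1$, $AUC = \Phi(a/\sqrt{1+b^2})$). The method's
zone covers values inconclusive on *either* curve — the interval hull
of the two bands. The hull always contains the wider band and, unlike
selecting the wider band alone, is exactly monotone in the tolerance
(a 5% band always contains the 10% band); that monotonicity is a
property the estimator should have and the selection rule can violate
when the wider family switches between tolerances. A curve that is
conclusive everywhere contributes a zero-width band at the midpoint of
its crossed bounds. All bounds are clamped to the observed score range
extended by half the minimal gap. The binormal band is skipped when the
model is undefined (fewer than three per class or zero within-class
variance).

**Final zone.** The wider of zones A and B, ties keeping A — the
conservative "widest gray zone" rule.

In reported tables, threshold A is the Youden-optimal cut with zone A
as its interval; threshold B is reported as the center of zone B, a
convention chosen because the tolerance method yields a band, not a
point estimate.

## Comparing AUCs and designing the study

Pairs of indices are compared with
$z = (AUC_1-AUC_2)/\sqrt{SE_1^2+SE_2^2}$ on Hanley–McNeil standard
errors and a two-sided normal p-value, without multiplicity adjustment.
The statistic treats the curves as independent although they are
estimated on the same patients; ignoring their positive correlation
overstates the variance of the difference, making the test
conservative. A correlated-curves test (DeLong) is deliberately out of
scope.

The sample-size design uses the two-group normal approximation
$n = \lceil 2 (z_{1-\alpha/2}+z_{1-\beta})^2 (\sigma/\delta)^2 \rceil$
evaluable patients plus planned dropouts; at $\alpha = 0.05$, power
0.8, $\sigma = 20\%$ and $\delta = 15\%$ with 2 dropouts this yields
28 + 2 = 30. A paired one-sample variant (dropping the factor 2) is
available behind `paired = TRUE` but is not the default, because only
the two-group form reproduces the conventional total of 30 under these
parameters. `simulated_power()` checks the design by Monte Carlo: it
draws the group-mean difference from its exact sampling distribution
under the design assumptions (normal changes, known SD) and applies the
two-sided z-test; the closed form
$\Phi(\sqrt{n/2}\,\delta/\sigma - z_{1-\alpha/2}) +
\Phi(-\sqrt{n/2}\,\delta/\sigma - z_{1-\alpha/2})$ agrees within
Monte-Carlo error.

## The synthetic cohort model

No per-patient data are published for studies of this design, so the
generator emulates the statistical structure the analysis assumes.

One latent severity $z \sim N(0,1)$ per patient drives everything:

* the relative stroke volume change is
  $\Delta SV\% = 19.2 + 12.7\,z$ (% — the default moments of the
  postoperative cohort the defaults emulate), and the after-fluid
  stroke volume is $SV_{before}(1+\Delta SV/100)$;
* each baseline index is
  $\mu_j + \sigma_j\,(\beta_j z + \sqrt{1-\beta_j^2}\,e_j)$ with
  $e_j = \sqrt{w}\,u + \sqrt{1-w}\,\varepsilon_j$, where $u$ is a
  measurement/ventilation factor shared by all seven indices and
  $\varepsilon_j$ is idiosyncratic. $\beta_j$ is therefore the
  index–severity correlation and the marginal SD stays at $\sigma_j$
  for any loading.

Defaults: per-index means and SDs in the 15–19 ± 5–9 % range typical of
ventilated postoperative patients; loadings $\beta$ calibrated once
(large-sample inversion of the model's AUC–$\beta$ map) so that the
marginal AUCs span 0.68 (PVI) to 0.92 (monitor PPV); shared-noise
fraction $w = 0.5$, chosen so that near-duplicate measurements of the
same physiology correlate realistically (for the two PPV channels the
model then gives ≈ 0.85, against ≈ 0.68 under fully independent noise —
implausibly low for two devices reading the same arterial waveform).
After-fluid index values are the baseline plus the configured mean
shift (all indices fall after the bolus) plus noise at 30% of the
channel SD; physical quantities are truncated at zero, a negligible
correction at the default parameters.

Two deliberate properties of this design:

* **Responder status is never stored by the generator.** It is always
  re-derived from the paired stroke volumes by the analysis stage,
  mirroring the study design and preventing any leakage of generator
  truth into the evaluation.
* **Moments win over the responder fraction.** A Gaussian
  $\Delta SV\%$ at moments (19.2, 12.7) implies a responder probability
  of ≈ 0.63, while the empirical calibration target is 17/30 ≈ 0.57
  (real change distributions are skewed). The generator reproduces the
  moments exactly — the documented invariant — and the resulting
  fraction remains well inside binomial sampling error of 0.57 at
  cohorts of 30. `responder_fraction_target` records the target; it is
  not a generative parameter.

The beat-series generator represents each channel as a sinusoid at the
respiratory frequency plus white noise, sampled at the cardiac
interval. It does not model baroreflex dynamics, arrhythmias (excluded
in the emulated setting), ventilation-synchronized heart-rate
variability, or raw waveform shape; passing tests therefore demonstrate
correctness of the index arithmetic and windows, not robustness to
real-device artifacts. Likewise, the cohort model's single-factor
correlation structure is a modeling choice with no claimed fidelity to
the true (unpublished) inter-index correlations.

## Numerical and design choices

* All randomness flows through explicit `seed` arguments; a run seed is
  split deterministically per stage (and per index for the bootstrap),
  so every result is bit-reproducible and the RNG state of the calling
  session is never disturbed.
* Windows are trailing and closed on both ends; beats are assigned by
  beat time.
* Ties in scores are handled by midranks in the AUC and by midpoint
  thresholds in the ROC grid; Youden ties break toward the smallest
  cut.
* Problem sizes in the shipped tests and acceptance script — cohorts of
  30 patients, 400–1500 replicate cohorts, 50 000 power replicates,
  2000 bootstrap replicates — were chosen to keep Monte-Carlo error
  well below the tolerances being checked.

## Known limitations

* Hanley–McNeil inference and the independent-curves z-test are
  normal approximations; at very small samples or AUC near 1 the CI
  clips and the SE degenerates.
* The binormal fit is a moment fit, not maximum likelihood over the
  ROC; with heavy ties or skewed scores the smooth curve is only an
  approximation.
* The generator emulates marginal structure, not device physics:
  nothing is claimed about pulse-contour algorithms, calibration drift,
  or pulse-oximeter signal quality.
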