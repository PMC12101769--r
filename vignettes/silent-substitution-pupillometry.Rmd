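---
title: "Silent-substitution pupillometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silent-substitution pupillometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilsub)
```

## The scientific problem

Intrinsically photosensitive retinal ganglion cells (ipRGCs) express the
photopigment melanopsin and drive non-image-forming responses such as the
pupillary light reflex. Because melanopsin's spectral sensitivity (peak
near 480 nm) overlaps heavily with the cone opsins, no narrowband light can
stimulate melanopsin alone: isolating the melanopsin-driven component of
the pupil response requires *silent substitution* — a pair of spectra whose
exchange produces large Weber contrast on melanopsin while producing
(near-)zero contrast on the cones. `pupilsub` implements the full
computational chain for such experiments: stimulus design on a calibrated
multi-primary light source, alpha-opic radiometry, pupil-trace cleaning,
response-metric extraction including the post-illumination pupil response
(PIPR), and two-group diagnostic statistics, together with a synthetic
cohort generator so every stage is testable without raw recordings.

## Alpha-opic radiometry

A stimulus is a spectral radiance $L_e(\lambda)$ (W·m⁻²·sr⁻¹·nm⁻¹) on the
canonical 380–780 nm grid at 1 nm (inputs on other grids are resampled by
linear interpolation; radiance outside the measured band is taken as zero).
The alpha-opic radiance for receptor $\alpha$ is the trapezoidal integral

$$R_\alpha = \int_{380}^{780} L_e(\lambda)\, s_\alpha(\lambda)\, d\lambda,$$

with $s_\alpha$ the receptor's peak-normalized sensitivity, and luminance is
$683 \int L_e(\lambda) V(\lambda)\, d\lambda$ in cd·m⁻². Weber contrast of
a pulse against its background is $100 (R_\alpha^{pulse} -
R_\alpha^{bg})/R_\alpha^{bg}$ percent; it is scale-invariant and requires a
strictly positive background radiance. Small negative measured radiances
(instrument noise) are clipped to zero before integration; this is
configurable.

**Sensitivity curves.** No authoritative tabulation of the standard
10°-field alpha-opic sensitivities is shipped with this package's
dependency set, so the curves are *generated in code* from the Govardovskii
et al. (2000) A1 visual-pigment nomogram (alpha plus beta absorbance bands)
at the field-standard alpha-opic peak wavelengths (S 448, melanopsin 490,
rhodopsin 507, M 542, L 570 nm), and $V(\lambda)$ from the standard
closed-form Gaussian approximation $1.019\,e^{-285.4(\lambda_{\mu m} -
0.559)^2}$. These are synthetic approximations, not the published standard
tables: they reproduce the qualitative overlap structure that makes silent
substitution necessary and keep all internal computations self-consistent,
but absolute alpha-opic radiances computed against real spectroradiometric
data will differ at the few-percent level from values computed with the
standard tabulations. Analyses that compare a pulse with its background
(contrasts) are much less sensitive to this than absolute radiances.

## Stimulus design

The device forward model assumes superposition across primaries and
piecewise-linear radiance response within each primary's measured input
levels — an explicit approximation of real LED nonlinearity, mitigated by
calibrating at several levels. The design problem is solved jointly over
the background and pulse settings ($2 n_{primaries}$ variables in $[0,1]$):

* **maximize mode** — maximize the mean Weber contrast across the target
  receptors subject to every silenced receptor's absolute contrast staying
  within the silencing tolerance (default 6%, the design envelope these
  stimuli are built to; the optimizer itself aims at zero);
* **match mode** — drive the summary target contrast to a requested value
  (e.g., the melanopsin contrast achieved by the first design) under the
  same silencing constraint.

"Summary LMS contrast" is defined as the *mean* of the L, M and S Weber
contrasts. The three cones need not be equal at the optimum — matched
designs typically show the cone contrasts straddling the requested value —
and per-cone values are always reported so the spread is visible. A
per-cone equality constraint can be emulated by passing each cone as its
own matched target; the mean-summary definition was chosen because it is
the weakest constraint consistent with "overall LMS contrast", leaving the
most gamut for the silencing constraint.

The search is a stochastic multi-start scheme: random interior starting
points, box-constrained quasi-Newton local optimization (`optim`,
L-BFGS-B), and a penalty-continuation ladder (weights 1 → 10⁶ on the
squared silenced contrasts) that tightens silencing as the local solve
progresses. Candidates are ranked feasible-first, then by target score
minus a residual-silencing penalty, so a cleanly silenced pair beats a
sloppier one that merely clears the tolerance. A fixed seed makes the
whole search reproducible; the restart count (default 20) and iteration
cap (default 300 per penalty stage) are configuration, and the incumbent
objective is non-decreasing in the restart budget by construction. Neither
overall luminance nor rhodopsin is constrained (rhodopsin contrast can be
reported post hoc).

Narrowband red/blue stimuli are built from two single primaries matched
for *unweighted* total radiance over 380–780 nm by bisecting the brighter
primary's drive level.

## Preprocessing

Cleaning follows a fixed order: mask → interpolate → smooth → normalize.

* **Masking.** A sample is masked when tracking confidence falls below
  0.95 or the first derivative of diameter (first difference divided by
  the sampling interval, attributed to the later sample of the pair) falls
  outside mean ± 3 SD of that trial's derivative distribution. The SD is
  per-trial (a per-session variant would pool trials; the per-trial choice
  is self-normalizing when trials differ in noise level).
* **Interpolation.** Interior masked runs are linearly interpolated
  between flanking good samples; runs touching the trace ends take the
  nearest good value, since two-sided interpolation is impossible there.
* **Smoothing.** Third-order Butterworth low-pass at 4 Hz (120 Hz
  sampling), applied forward–backward. Zero-phase filtering was chosen so
  that the filter's group delay cannot bias latency metrics; the effective
  amplitude response is the squared one-pass magnitude,
  $|H(f)|^2 = 1/(1 + (f/4)^6)$. Timestamps are resampled to an exact
  uniform grid first, because the filter assumes uniform sampling.
* **Normalization.** The trace is expressed as percent of the mean
  diameter in the 1 s window before pulse onset; by construction the
  baseline-window mean is exactly 100.

Because the derivative threshold is *scale-relative* (±3 SD of the
trial's own derivative distribution), the pipeline is idempotent only up
to that rule: re-cleaning an already-smoothed trace can re-flag the
steepest part of the physiological constriction itself, since smoothing
has removed the noise that previously dominated the SD. In practice this
touches only the constriction onset and is why the rule is intended for
raw, noise-dominated recordings.

Trials with more than 25% masked samples are excluded (threshold
configurable; the cut-off balances keeping data against trusting long
interpolated stretches), as are trials that cannot be reconstructed,
filtered, or baselined; each exclusion carries a reason code.

## Response metrics

On each participant's mean trace (averaging trials first suppresses noise
before the nonlinear argmin/min operations; a per-trial-then-average mode
is available through the per-trial API):

* **a** — time to maximum constriction: argmin of the normalized trace
  over the pulse-on interval (0, 3] s, in ms; ties break to the earliest
  time.
* **b** — diameter at maximum constriction (%).
* **c** — redilation rate: least-squares slope of the trace from the
  within-pulse minimum to pulse offset (%·s⁻¹, positive = redilating);
  undefined when the minimum falls at offset.
* **d** — diameter 6 s after pulse offset (9 s after onset), linearly
  interpolated between neighbouring samples (nearest-sample mode
  available).

PIPR is the red-minus-blue normalized diameter at a stated time after
pulse offset (default 6 s); it is antisymmetric under swapping the traces.
The timepoint of maximal between-group PIPR difference is located on the
group-mean difference curve over a 0–12 s post-offset window, ties to the
earliest time.

## Statistics

Between-group comparisons use Welch's t-test (Satterthwaite df) with
per-group t-based 95% CIs; within-participant stimulus comparisons use the
paired t-test; correlations use Spearman's rank correlation (midranks,
exact p below n = 10 without ties). Bonferroni correction is applied
within each stimulus's family of four parameter comparisons with a strict
inequality (p < 0.05/4 = 0.0125). ROC analysis uses the Mann–Whitney AUC
with DeLong 95% confidence intervals via the pROC package; the case class
is the glaucoma group, direction is auto-detected, and the raw
("higher-score-is-case") orientation is reported alongside so AUC below
0.5 is not hidden. The binormal analytics connect an operating point to
the group separation it demands, $d = \Phi^{-1}(sens) +
\Phi^{-1}(spec)$, and two-sample power is computed exactly from the
noncentral t distribution.

## The synthetic generator

The generator emulates the trial protocol: a 400–600 ms dark
synchronization flash, a uniformly random 10–12 s background interval, a
3 s pulse and a 15 s post-pulse period, sampled at 120 Hz. The
ground-truth normalized response is a piecewise curve — flat 100% until
the response latency, exponential constriction with time constant
$\tau_c$ reaching its minimum when 95% saturated (at latency
$+ 3\tau_c$), linear within-pulse redilation, and post-offset exponential
recovery toward $100 - \text{sustained}$ with time constant $\tau_r$. The
parametric form is invented: it is the simplest piecewise-smooth curve
exhibiting every feature the four metrics measure, with the
condition-dependent recovery encoding the sustained constriction that
distinguishes melanopsin-weighted from cone-weighted stimulation.
Measurement noise is Gaussian on diameter; blinks are Poisson events of
fixed duration that collapse the diameter toward a lid-occlusion value
and zero the confidence channel — exactly the artifact classes the
masking rules are designed to catch.

Condition defaults were calibrated once, on the noiseless analytic curve,
so that group means land on values typical of each stimulus class
(melanopsin-directed: minimum ≈ 84%, 6-s-post-offset diameter ≈ 97.5%;
LMS-directed: ≈ 99.5%; narrowband red/blue giving a healthy-eye PIPR of
≈ 13 percentage points). Between-participant variability is normal on
each model parameter (sustained constriction SD 3 percentage points,
amplitude SD 2, redilation SD 1, latency SD 50 ms), with the sustained
parameter truncated at zero; the truncation slightly raises the realized
group mean relative to the nominal value, which matters for exact
reproduction of printed group means but not for the null/effect-recovery
properties the generator is used for. Injected group effects (Cohen's d
per metric) shift the glaucoma group's generating parameter by d times
the metric-scale between-participant SD, so the empirical standardized
difference recovered by the pipeline estimates the injected d directly.
Synthetic clinical covariates (visual-field Mean Deviation, Pattern
Standard Deviation, mean cpRNFL thickness) are drawn with group-typical
means and correlated with the participant's latent deficit at a
configurable rho (default 0.3, giving the weak correlations typical of
such data).

What the generator does *not* emulate: consensual/direct response
asymmetries, pharmacological dilation, gaze-dependent pupil
foreshortening, slow drifts in arousal, and any true biophysical
melanopsin dynamics. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline's code is correct under the stated
statistical structure, not that the underlying physiology is modelled.

## Numerical choices and problem sizes

Trapezoidal quadrature on the 1 nm canonical grid (halving the step
changes contrasts by far less than 0.1 percentage points); linear
interpolation everywhere a value is needed off-grid; earliest-time
tie-breaks for argmin and argmax searches; strict inequality at the
Bonferroni threshold; degenerate zero-variance tests return p = 1 by
convention when the means agree. The package's own test suite runs the
generator at reduced scale (4–5 trials per participant and 20 null
replicates for the calibration checks) — sizes chosen so the full suite
completes in a few minutes while keeping Monte-Carlo error well inside
the asserted tolerances; all defaults remain at the full study layout
(30 trials per stimulus, 15 + 15 red/blue, 20 + 15 participants).

## Known limitations

* Sensitivity curves are nomogram approximations (see above); swap in
  tabulated standards via `sensitivity_function` objects for
  metrologically exact alpha-opic radiances.
* The matched design constrains only the mean cone contrast; individual
  cone contrasts can spread widely on devices with strongly overlapping
  primaries.
* The device forward model ignores primary interaction and thermal
  drift.
* Reproduction of the published per-participant analyses requires the
  study's deposited trace tables, which are not distributed with the
  package; `reproduce_supplementary()` runs the full chain when pointed
  at them.
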