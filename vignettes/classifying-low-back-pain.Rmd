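---
title: "Classifying low back pain subgroups from repositioning errors with a Dempster-Shafer classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying low back pain subgroups from repositioning errors with a Dempster-Shafer classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(spinedst)
```

## The problem

Non-specific low back pain (NSLBP) is clinically heterogeneous. Classification
schemes used by physiotherapists subgroup patients by posture and movement
pain behaviour into, among others, a flexion pattern (FP), an active extension
pattern (AEP) and a passive extension pattern (PEP); matched exercise therapy
then targets the subgroup. Assigning these labels reliably takes extensive
clinical training, which motivates objective classifiers built from
biomechanical measurements.

One informative measurement family is *repositioning sense*: a blindfolded
subject memorises a mid-range spinal posture and reproduces it several times,
and the deviations between reproduced and target angles quantify
proprioceptive function. Measured per spinal region (thoracic, lumbar,
pelvis) and test position (sitting, standing), and summarised by three error
statistics each, this yields 18 variables per subject. `spinedst` implements
the full pipeline from such data to subgroup classification: error-statistic
computation, optional curvature extraction from sagittal marker traces, a
two-class Dempster-Shafer (DST) belief-function classifier, leave-one-out
cross-validation (LOOCV), variable ranking, and a synthetic-cohort generator
for end-to-end testing.

## Repositioning-error statistics

For one region/position, a subject produces $k$ repositioning attempts
$x_1,\dots,x_k$ toward a target angle $T$ (degrees; positive = flexion,
negative = extension; the study protocol uses $k = 4$). The package computes
the three classical motor-control statistics, all with the population divisor
$k$:

* constant error $CE = \bar{x} - T$ — signed bias (overshoot positive),
* absolute error $AE = \tfrac{1}{k}\sum_i |x_i - T|$ — error magnitude,
* variable error $VE = \sqrt{\tfrac{1}{k}\sum_i (x_i - \bar{x})^2}$ —
  attempt-to-attempt consistency.

These satisfy the decomposition $\tfrac{1}{k}\sum_i (x_i - T)^2 = VE^2 +
CE^2$ and the inequality $AE \ge |CE|$, both of which are asserted as
property tests. Published formula notation for AE and VE is ambiguous in the
source literature of this design; the package deliberately uses the standard
motor-control definitions above — the only readings that keep $AE \ge 0$
everywhere and make VE a pure consistency measure — and documents the
divisor-$k$ (population) choice. Whether the original analysis divided by
$k$ or $k-1$ for VE cannot be recovered from the printed formulas; with
$k = 4$ the difference is a fixed factor $\sqrt{4/3}$ that the classifier's
data-driven calibration absorbs.

```{r}
ts <- trial_set(target = 4, attempts = c(5, 7, 3, 9))
error_triple(ts)
```

## Curvature geometry

When the input is a traced sagittal spinal curve rather than precomputed
angles, regional curvature is measured from signed turn angles of an
equidistantly resampled polyline. The source protocol subdivides the curve
into 19 equidistant points and sums "12 angles between C7 and T12 and 6
angles between T12 and S1" — but 19 points have only 17 interior angles, so
the printed counts cannot all hold at once. The package resolves this by
resampling to **20** points (19 segments, 18 interior turn angles) with T12
pinned exactly on the shared vertex: 13 equidistant points span C7→T12 and 8
span T12→S1. The thoracic sum is the first 12 turn angles (including the
angle at the T12 vertex) and the lumbar sum the remaining 6, preserving the
12/6 regional split that feeds the classifier. Positive turn angles indicate
flexion (posterior convexity); mirroring a curve about the vertical axis
flips every sign. Pelvic tilt is the angle of the PSIS→ASIS line to the
horizontal, positive for anterior tilt (ASIS below PSIS) — a convention
chosen so that anterior pelvic tilt matches positive overshoot, not a fact
recoverable from the protocol description.

Correctness is checked against the inscribed-polygon identity: for $m$ equal
chords of a circular arc with central angle $\Theta$, the $m-1$ interior
turn angles sum to $\Theta\,(m-1)/m$, which the implementation reproduces to
below $10^{-6}$ degrees.

## The classifier

The classifier works on a two-class frame of discernment
$\{\text{case}, \text{control}\}$ and represents each piece of evidence as a
*body of evidence* (BoE): masses $m(\{\text{case}\})$,
$m(\{\text{control}\})$ and $m(\theta)$ on the whole frame, nonnegative and
summing to one, where $m(\theta)$ is uncommitted belief (uncertainty). Three
stages:

1. **Confidence factor.** Each variable value $v$ is mapped through a
   logistic sigmoid $cf(v) = 1/(1 + e^{-r\,(v - s)})$. The shift $s$ is
   always the midpoint of the two training-class means, so the
   single-variable decision boundary sits halfway between the classes
   regardless of all other settings (a property the tests scan explicitly).
2. **Belief mapping.** The confidence factor becomes a BoE through a
   piecewise-linear map with controls $A$ and $B$ derived from two
   interpretable bounds: the uncertainty equals $\theta_U$ at $cf = 0.5$
   (maximally ambiguous evidence) and $\theta_L$ at $cf \in \{0, 1\}$
   (decisive evidence): $m(\{\text{case}\}) = \max(0, B\,(cf - A)/(1 - A))$,
   $m(\{\text{control}\}) = \max(0, B\,(1 - A - cf)/(1 - A))$, with
   $B = 1 - \theta_L$ and $A$ solving $1 - \theta_U = B(1 - 2A)/(1 - A)$.
   Defaults are $\theta_L = 0.1$, $\theta_U = 0.8$ (hence $A = 0.4375$,
   $B = 0.9$), shared across variables and configurable.
3. **Combination.** The per-variable BoEs are fused with Dempster's rule of
   combination (conjunctive fusion renormalised by one minus the
   conflicting mass), which is commutative and associative with the vacuous
   BoE $(0, 0, 1)$ as identity; the package combines in the canonical
   variable order and tests order-invariance to $10^{-9}$.

The final BoE is visualised in a simplex plot (equilateral triangle, control
vertex left, case vertex right, uncertainty apex). The predicted class is the
larger singleton mass — equivalently, the side of the vertical median on
which the point falls — and the decision is *dominant* when the winning mass
also exceeds $m(\theta)$. Ties are resolved to control, deterministically and
conservatively for the case class.

```{r}
b <- combine_dempster(boe(0.6, 0.2, 0.2), boe(0.5, 0.3, 0.2))
b
classify_boe(b)
```

## Calibrating the sigmoid rate

The source description fixes neither the sigmoid steepness nor the
uncertainty bounds; both are package design decisions exposed as
configuration. Two calibrations are provided:

* `calibration = "posterior"` (default): $r = (\mu_\text{case} -
  \mu_\text{control})/s^2$ with $s^2$ the pooled within-class variance
  (mean of the two class variances, population form). With this rate the
  sigmoid is exactly the equal-prior posterior probability of case
  membership under univariate normal class models with common variance.
* `calibration = "anchored"`: $r = 2\ln(a/(1-a))/(\mu_\text{case} -
  \mu_\text{control})$, so that $cf$ equals the anchor $a$ (default 0.9) at
  the case mean and $1 - a$ at the control mean.

The anchored rule is appealingly simple but has an inverted relationship to
evidence quality: the *smaller* the gap between class means, the *steeper*
the sigmoid, so a variable that barely discriminates votes with full
confidence on what is mostly noise. With many weak variables — exactly the
situation in the between-subgroup contrasts, where only a handful of the 18
variables differ — those confident noise votes accumulate through Dempster's
rule and degrade the combined decision. The posterior calibration restores
the intended semantics of the belief mapping: heavily overlapping classes
give $cf \approx 0.5$ and therefore uncertainty near $\theta_U$, while well
separated classes give decisive confidence. It is the package default for
this reason; the anchored rule remains available and fully tested. Both
calibrations share the midpoint shift, so single-variable decisions,
variable rankings and their accuracies are identical under either.

## Evaluation

* **LOOCV** (`dst_loocv()`): for each subject the control variables are
  refit on the other $n-1$ subjects and the held-out subject is classified;
  accuracy is the fraction of subjects on the correct side of the decision
  boundary, dominant or not. Equivalence with an independently coded naive
  hold-one-out loop is tested on a 12-subject cohort, per-subject masses
  included.
* **Variable ranking** (`rank_variables()`): each variable alone, fit on
  all $n$ subjects and resubstituted, sorted by accuracy with ties broken
  in canonical variable order. Resubstitution (rather than LOOCV) for the
  ranking mirrors the study design.
* **Seven comparisons** (`run_seven_comparisons()`): FP, AEP and PEP each
  against pain-free controls; the three subgroups pooled against controls;
  and the three between-subgroup contrasts. Reports include
  dominant/non-dominant tallies per true class (`tally_regions()`), the
  per-comparison ranking, and simplex plots.

## The synthetic-cohort generator

No subject-level data are distributed with the published study, so the
generator (`generate_cohort()`) emulates the cohort from its printed
group-level statistics: group sizes 28 (no-LBP), 49 (FP), 23 (AEP) and 14
(PEP), and per-group means and standard deviations for all 18 variables.
Each variable is drawn independently from its group's normal distribution;
AE and VE, nonnegative by definition, are redrawn until nonnegative
(rejection preserves the unimodal truncated-normal shape, where clipping
would pile an atom at zero). Marginal fidelity is tested against the
truncated-normal closed form at $10^4$ subjects per group. Where the study's
abstract and tables disagree on group sizes (50 vs 49 FP, 31 vs 28
controls), the defaults follow the tables; any sizes can be configured.

Only marginal moments are published, so variables are generated
independently by default; an equicorrelation knob (`rho`) adds a shared
within-subject component for robustness experiments. This is the central
caveat for interpreting results on synthetic cohorts: real repositioning
errors are correlated across regions, positions and statistics (AE, VE and
CE of one trial set are functionally related), and independent marginals
overstate the joint information available to a multivariate classifier.
Synthetic LOOCV accuracies should therefore be read as optimistic relative
to the published real-data accuracies, which is also why the package's
acceptance checks treat the published values as floors rather than targets.
Passing them demonstrates that the pipeline extracts the separation the
printed statistics imply; it does not certify performance on real,
correlated data.

## Numerical and design choices

* Uncertainty bounds validated as $0 \le \theta_L < \theta_U \le 1$; at
  $\theta_U = 1$ the derived control reaches $A = 0.5$, where the linear
  map remains well defined.
* Total conflict in Dempster's rule ($K = 1$, possible only when two
  variables are each fully decisive in opposite directions) raises an
  explicit error naming both BoEs; near-conflict is guarded at
  $1 - K < 10^{-12}$.
* A variable whose class means coincide gets rate 0 and contributes the
  vacuous BoE — the combination identity — rather than an arbitrary
  direction; a zero-variance, nonzero-gap variable saturates the sigmoid.
* Ties ($m(\{\text{case}\}) = m(\{\text{control}\})$) classify as control
  and are flagged per subject.
* Rejection sampling retries are bounded (100 rounds) so pathological
  specifications (an AE mean far below zero) fail loudly instead of
  looping.
* Problem sizes in the shipped tests and acceptance script: 20 replicate
  cohorts of 114 subjects for the seven-comparison LOOCV means, 50
  replicates for the single-variable check, $10^4$ subjects per group for
  marginal-fidelity checks, 1,000 random trial sets for the error-statistic
  oracle — sizes chosen so the full suite runs in about a minute on one
  CPU while keeping Monte-Carlo error well inside the asserted margins.

## Limitations

* Two-class frames only; multi-class subgrouping is expressed as a battery
  of pairwise comparisons, as in the study design. No alternative
  combination rules (Yager, PCR) and no plausibility/commonality
  transforms.
* The generator does not model within-subject correlation (beyond the
  equicorrelation knob), session-to-session variability, or measurement
  error in the curvature extraction.
* Curvature extraction is strictly sagittal-plane and assumes a
  head-to-sacrum monotone trace; no 3-D marker processing, gap filling or
  vendor file formats.
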