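---
title: "Simulating and decoding reach-to-grasp fMRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding reach-to-grasp fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graspdecode)
```

This vignette documents the models behind `graspdecode`, the parameters
that matter, and the design decisions taken where more than one
reasonable choice existed. It is the package's reference for *why* the
code does what it does; the README shows *how* to run it.

## 1. What is being modelled

The package targets a classic event-related motor fMRI design: six
conditions crossing action type (precision grasp PG, whole-hand grasp
WHG, reaching-only R) with object size (small/large), 45 trials per
condition grouped into mini-blocks of five same-condition trials, four
runs of 117 volumes at TR = 3 s, and object size blocked by run parity
(odd runs small, even runs large). The scientific question is whether
the *multivoxel pattern* of a region of interest carries information
about six binary contrasts (grasp type, action type, object size,
grasp/size congruence), over and above any overall activation change.

Because no public dataset accompanies this design, the package pairs the
analysis chain with a generator that produces BOLD time series with
exactly the statistical structure the analysis assumes — including a
known ground truth, so recovery and calibration are testable.

## 2. The trial schedule

**Stimulus-onset asynchrony (SOA).** Onset-to-onset intervals follow an
exponential distribution truncated to [3, 8] s. The truncated family is
parameterised by its *mean*; the rate is solved numerically (bisection on
the closed-form truncated mean). The default mean is 4.9 s: with 65–70
trials per run this makes the expected schedule length fit a 351 s run
with a comfortable tail. Achievable means lie strictly between 3 s and
the uniform midpoint 5.5 s; targets outside that interval are rejected
with an error. "ISI" is interpreted as onset-to-onset (the trial's
duration is absorbed in it) — the only reading under which 270 trials fit
4 × 351 s.

**Mini-block allocation.** Each condition owns 9 mini-blocks, split as
evenly as possible over that condition's runs; leftover blocks go to the
currently least-loaded run, so run totals stay balanced (13/14 under the
default design). Block order within a run is randomised.

**Schedule rejection sampling.** A drawn onset sequence occasionally
overruns the run (roughly one run in ten at the default mean SOA, since
69 random gaps have a standard deviation of ~11 s). The generator redraws
the intervals for that run — up to `max_schedule_attempts = 100` — and
errors, naming the run, only if no draw fits. Conditioning on "fits the
run" shortens the realised mean SOA by well under 0.1 s, a bias we accept
in exchange for schedules that always respect the acquisition length.

**Trial duration** is not fixed by the design description; it defaults to
2 s (a comfortable reach-and-return) and is a config knob, used for the
neural boxcar and the end-of-run fit check.

## 3. The signal and noise model

For ROI voxel $v$, volume time $t$ in one run:

$$ y_v(t) = b_v + \sum_c s_c(t)\,\bigl(u_c + W_{vc}\bigr) + \varepsilon_v(t) + d_v(t) $$

* $s_c(t)$: the condition-$c$ boxcar (trials of `trial_duration`)
  convolved with a canonical double-gamma HRF (peak 6 s, undershoot 16 s,
  peak:undershoot 6:1 — the field-standard shape; the design description
  is silent on the HRF, so the convention is adopted and made
  configurable). Convolution is computed on a 0.1 s grid and sampled at
  the TR.
* $u_c$: a *univariate* per-condition amplitude applied equally to all
  voxels. The default gives every task condition the same $u_c = 1$, so
  overall activation never separates the classes.
* $W_{vc}$: the *multivoxel* weight matrix — the information the
  classifiers are supposed to find. It is built as a sum of
  feature-level patterns: each named effect (`object_size`,
  `grasp_type`, `action_type`, `congruence`, or fully `condition`-
  specific) draws one zero-mean, unit-SD voxel vector per feature level,
  scales it by the effect's amplitude β (BOLD units), and assigns it to
  the conditions at that level. Columns are zero-mean by construction:
  with β = 0 everywhere the class-conditional distributions are
  *identical*, which is what makes the null calibration tests meaningful.
* $\varepsilon_v$: AR(1) noise (innovation SD 1, coefficient 0.3) —
  independent across voxels, runs and subjects.
* $d_v$: a sinusoidal drift, amplitude 1, period 128 s, random phase per
  voxel and run. Its frequency (0.0078 Hz) sits below the 0.01 Hz
  high-pass cutoff, so the preprocessing chain has a real drift to
  remove.

**Between-subject variability.** Subjects share a group-level template
$W$; each subject's weights are the template plus Gaussian jitter
(SD 0.3, columns re-centred). This is what gives the group t-test a
realistic between-subject accuracy variance — without it, 16 subjects
would be 16 replicates of the same experiment.

**Hierarchical seeding.** One master seed spawns per-subject, per-ROI and
per-run integer streams (Lehmer-style mixing), so enlarging the subject
set or ROI list never changes draws already made. Identical (config,
seed) pairs give byte-identical outputs end to end.

## 4. Preprocessing

Applied per run and per voxel, in the order standardize → detrend →
high-pass (the order in which the steps are conventionally listed):

1. **Standardize** to zero mean, unit SD, with the *N − 1* denominator.
   Constant series are mapped to zeros with a warning instead of NaN,
   keeping downstream matrices dense and classifiers defined.
2. **Detrend**: residual of an OLS fit on intercept + linear time.
3. **High-pass at 0.01 Hz**: projection onto the complement of a
   discrete-cosine basis, keeping components at or above the cutoff
   (k ≤ ⌊2·N·TR·f_c⌋ cosines are removed, plus the constant). A DCT
   projection rather than an IIR filter: zero phase distortion, exact
   nulling of modelled drifts, and trivially unit-testable (a 0.002 Hz
   tone is attenuated > 90%, a 0.05 Hz tone preserved > 95% at the
   default run length).

No step ever mixes runs; this is verified by perturbation tests.

## 5. From volumes to classifier samples

A volume belongs to the mini-block whose first-trial onset most recently
preceded its acquisition time (the last block of a run extends to the run
end). This onset-interval rule is the package's choice — any such rule
must be stated explicitly because the unit of classification is the
mini-block, and the assignment determines sample independence. An
optional `lag_volumes` shifts the partition for sensitivity analyses; it
defaults to 0 because the next step already discards 12 s per block.

Each sample is the voxelwise mean of its block's volumes after dropping
the first `discard_volumes = 4` (12 s at TR 3 s) — letting the
haemodynamic response stabilise and decoupling the sample from the
previous block. A block that would retain no volume raises an error
naming the block. Under the default schedule blocks span ~8 volumes
(never fewer than 5 in 100 tested seeds).

The six shipped contrasts label the selected samples ±1; all six are
exactly balanced under the default design (e.g. N = 36, 18 per class,
for grasp type).

## 6. Decoding

The classifier is a soft-margin linear SVM with C = 1 and **no internal
feature scaling** (the runwise standardization is the only normalisation;
adding another would change the published pipeline). The quadratic
program is solved by libsvm via `e1071`; the decision function is
extracted into explicit `(w, b)` form, with the orientation normalised so
that f > 0 always means the +1 class — libsvm itself orients decision
values by the class of the *first training sample*, a classic trap that
the tests pin down. A decision value of exactly 0 predicts +1 (documented
tie-break; a measure-zero event for continuous data).

**Leave-one-pair-out cross-validation**: per-class sample sequences are
ordered chronologically (run, then mini-block); fold *k* holds out the
k-th positive and k-th negative sample. The pairing rule is a package
choice — only "one sample of each class per fold" is inherent to the
scheme — so a seeded random pairing is available as an option
(`pairing = "random"`). Classes must be balanced; unbalanced input is an
error rather than a silently re-weighted analysis. On 1-D fixtures the
whole loop is verified against hand-enumerated folds with the analytic
two-point SVM boundary.

## 7. Group inference

* **Per-cell test**: one-tailed one-sample t of per-subject accuracies
  against 0.5 (direction fixed at accuracy > chance). Zero-variance
  inputs yield a flagged degenerate result (±Inf), never a silent NaN.
* **FDR**: Benjamini–Hochberg step-up at q = 0.05 within each
  classification's family. The family *includes the control ROI* by
  default (15 tests under the full ROI set) — the conservative reading —
  but `include_control_in_family = FALSE` is available since the family
  definition is a genuine open choice. The realised "corrected α" is
  reported in the field's idiom: the largest raw p still rejected.
* **ROI × hemisphere RM-ANOVA** per classification, sphericity assumed
  (df = (levels − 1, (levels − 1)(n − 1)), e.g. (6, 90) for 7 ROIs and 16
  subjects), partial η² = SS_effect / (SS_effect + SS_error) per effect,
  with FDR-corrected paired post-hoc t-tests on the ROI factor. Sums of
  squares come from `stats::aov` with `Error()` strata and are verified
  against a manual decomposition to 1e-10.
* **Classification comparison**: per ROI, a one-way RM-ANOVA over the
  three action-related contrasts plus a linear trend contrast with
  weights (−1, 0, +1): per-subject score −m₁ + m₃, F = t² against zero,
  partial η² = F / (F + df).

## 8. The shipped scenarios and their calibration

`default_roi_set()` provides the seven bilateral frontoparietal ROIs
(SPOC, SPLap, hAIP, BA 1/2/3ab, BA 4p, BA 6, BA 44/45) plus an
out-of-skull control ROI (no task response at all: $u_c = 0$, β = 0).

The `"planted"` preset is a *synthetic* scenario qualitatively shaped
like the findings such experiments report: an action-type (grasp vs
reach) pattern in every brain ROI, a grasp-type pattern everywhere
except SPOC and right hAIP, nothing for object size or congruence, and
left-hemisphere amplitudes 25% above right. The amplitudes
(β_action = 0.8, β_grasp = 0.6 on the left, 80% of that on the right,
against unit-SD AR(1) noise, 100-voxel ROIs) were fixed once, during
package design, so that group mean accuracies land in the 0.6–0.75
band typical of significant ROI decoding with these sample sizes —
strong enough for reliable FDR significance at n = 16, far from
ceiling. They are defaults of a demonstration scenario, not estimates
of any real effect.

The `"null"` preset zeroes every β. With equal univariate amplitudes,
decoding can then only perform at chance; the test suite confirms the
group mean stays within 3 SE of 0.5 over 50 subjects, and that the
one-tailed group t-test rejects at ~5% under the global null.

## 9. Problem sizes used by the test suite

The statistical tests run at sizes chosen to make their Monte-Carlo error
small relative to the tolerance being asserted while keeping the suite
quick to run routinely:

* *Null calibration*: 16 subjects, full default design, 100-voxel
  control ROI (the configuration of the acceptance benchmark).
* *Signal recovery*: 20 replicate experiments, 16 subjects each, full
  design, two informative left-hemisphere ROIs + control at 50 voxels.
* *Type-I error*: 500 simulated groups of 8 subjects through a reduced
  null pipeline (2 runs of 80 volumes, 15 trials/condition, 12 voxels) —
  the rejection rate of a t-test does not depend on the ROI size or run
  count, so the reduction only buys speed.
* *Monotonicity in β*: 5 amplitudes × 20 replicates on the reduced
  design.

## 10. Known limitations

The generator emulates the *statistical* structure the decoder cares
about, not MR physics. It has no spatial autocorrelation between voxels
(each voxel's noise is independent — real BOLD noise is spatially
smooth), no motion, no physiological cycles, no susceptibility artifacts,
no multi-echo; noise is Gaussian. Passing the suite therefore shows the
*pipeline* is correct and calibrated — not that any particular real
dataset would yield the planted effect sizes. Geometric ROI masks use
voxel-center membership and perform no template-space conversion: sphere
and cube coordinates are taken in the space of the grid they are applied
to (`space_label` is metadata only), and atlas-based masks must be
supplied as NIfTI files. Single-trial estimation (beta series, LS-S) is
out of scope: the unit of classification is the mini-block average.
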