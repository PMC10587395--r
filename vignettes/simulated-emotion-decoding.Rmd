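---
title: "Decoding emotion and modality from simulated multivoxel fMRI: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding emotion and modality from simulated multivoxel fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question this package operationalises

When people see an angry face, an angry body, or hear an angry voice, does
the brain hold a *supramodal* representation of the emotion — a multivoxel
pattern that codes "anger" the same way whatever the sensory channel — or are
emotion codes locked inside each modality? The decisive test is
cross-modal decoding: train a classifier on one stimulus category's trials
and test it on another's. Above-chance generalization implies a shared code;
chance-level generalization alongside successful *within*-modality decoding
implies modality-specific codes.

`emodecode` implements the complete analysis chain for that test — trial-wise
GLM response estimation, Gaussian Naive Bayes (GNB) searchlight decoding,
group inference with a shared-label permutation scheme, and ROI/RDM
summaries — together with a simulator for the slow event-related
face/body/voice design the chain is meant to analyse. Because the simulator
plants *known* modality-specific or supramodal pattern structure, every stage
can be validated by parameter recovery rather than by eyeballing maps.

## The simulated experiment

`experiment_design()` encodes the emulated protocol:

* 2 scan sessions × 6 runs, 160 volumes per run at TR = 3 s;
* each run split into an auditory half (voice clips) and a visual half
  (body clips in session 1, face clips in session 2); visual-first in odd
  runs, auditory-first in even runs, so half order is counterbalanced;
* each half: 18 one-second trials — 16 regular (4 × anger, happy, neutral,
  fear, order randomised) plus 2 catch trials of the orthogonal
  change-detection task, interleaved at random slots;
* inter-stimulus intervals jittered uniformly in 10.7–11.3 s;
* 4 actors assigned round-robin.

Catch trials occupy schedule slots and enter the GLMs as a pooled nuisance
regressor, but carry no condition signal: the behavioural task is orthogonal
to the decoded labels, and simulating its content (tone modulation, fixation
luminance) would add nothing the analysis can see. Emotions are balanced
exactly within each run half; emotion × actor combinations are *not*
balanced, only cycled — the protocol specifies balance for emotions only.
Voice trials record their session, because several report columns (and the
cross-modal pairing) distinguish voice-of-the-body-session from
voice-of-the-face-session.

```{r}
library(emodecode)
design <- experiment_design()
events <- build_design(design, seed = 1)
table(events$stimulus_type, events$session)
```

## Ground truth and the signal model

`ground_truth_config()` names up to five effect regions, each a sphere (in
voxel coordinates) or an explicit voxel set:

* `modality_region` — one pattern per stimulus type, shared across emotions:
  only modality is decodable;
* `emotion_face/body/voice_region` — four independent per-emotion patterns,
  evoked *only* by that stimulus type: within-modality emotion codes;
* `supramodal_emotion_region` — four per-emotion patterns applied
  identically whatever the stimulus type: the signature cross-modal decoding
  should detect.

Pattern vectors are zero-mean, unit-L2-norm Gaussian draws over the region's
voxels, scaled by a per-region `amplitude`; an amplitude $a$ over an
$n$-voxel region therefore gives per-voxel signal RMS $a/\sqrt{n}$ in the
same units as the noise standard deviation. The positive-control experiments
(`dissociation_truth()`) use radius-2 spheres (33 voxels) with amplitude 6 —
per-voxel effects of about one noise SD, i.e. a strong but not absurd
multivoxel effect; the point of those runs is ground-truth *recovery*, not
power estimation at realistic effect sizes.

A run's voxel time series is

$$ y_v(t) = \sum_{\text{trials } i} A_{iv} \, x_i(t) + \varepsilon_v(t) + d_v(t), $$

where $x_i$ is the trial's 1 s boxcar convolved with the canonical
double-gamma HRF (below), $A_{iv}$ the ground-truth amplitude of trial $i$'s
condition at voxel $v$, $\varepsilon_v$ stationary AR(1) Gaussian noise
(marginal SD `sigma`, default 1; lag-1 autocorrelation `ar1`, default 0.3),
and $d_v$ a cosine-basis drift with Gaussian coefficients
(`drift_amplitude`, default 1). AR(1)-plus-drift is deliberately the
*minimal* noise model that exercises the GLM's drift regressors and leaves
serial correlation in the residuals; the simulator does not attempt
physiological or motion artefacts, spatial noise correlations beyond the
signal itself, or multiband acquisition physics. Consequently, passing tests
demonstrate the *analysis code* is correct and calibrated under its stated
assumptions — not that the pipeline is robust to every nuisance structure of
real fMRI.

## GLM choices

* **HRF**: difference of two gamma densities, peak delay 6 s, undershoot
  delay 16 s, unit dispersions, peak:undershoot 6, 32 s support, peak
  normalised to 1 (`hrf_spec()`); sampled at `ceiling(length / dt)` points.
  The kernel's mode sits near 5 s.
* **Trial-wise model**: least-squares-all — one model per run containing
  every regular trial as its own regressor, plus a pooled catch regressor,
  cosine drifts and a constant. At ISIs ≥ 10.7 s and TR 3 s the trial
  regressors are nearly orthogonal (condition number of the interest block
  < 10), so the simpler joint model is preferred over per-trial
  (least-squares-single) fitting. Motion and drift nuisances are toggleable
  arguments.
* **High-pass filtering** is implemented *inside* the GLM as discrete-cosine
  drift regressors with a 128 s cutoff, the standard GLM-equivalent of
  preprocessing-stage filtering (preprocessing itself is out of scope).
* **Condition model** (univariate path): 12 condition regressors (4 emotions
  × 3 categories) plus block-start, catch, six motion parameters (smooth
  random-walk stand-ins when none are supplied), drifts, constant. Conditions
  absent from a run are *flagged*, never zero-filled. Data for this path may
  be smoothed (6 mm FWHM Gaussian, `smooth_volume()`); the multivariate path
  always consumes unsmoothed betas.
* **Estimation** is ordinary least squares per voxel via one QR
  decomposition; no prewhitening. OLS with drift regressors is unbiased
  under the simulated AR(1) noise, and the group stage works on accuracies,
  not on single-subject variance estimates, so prewhitening would buy
  nothing for these analyses.
* **Repeated-measures ANOVA** (`anova_factor_map()`): per voxel, subject ×
  level means with subjects as the blocking factor,
  $F = MS_{\text{factor}} / MS_{\text{factor} \times \text{subject}}$.

## GNB searchlight

`gnb_fit()` estimates per-class, per-feature Gaussian means and
maximum-likelihood variances with empirical class priors (uniform under this
balanced design). Variances are floored at $10^{-9}\times$ the mean of all
class variances so degenerate features never divide by zero. Prediction is
the arg-max of log prior plus summed log densities; exact ties resolve to the
earlier class in the ordered label set (emotions in design order; visual
before auditory), making results reproducible to the bit.

The searchlight is the set of integer voxel offsets with
$\|v\|^2 \le r^2$, $r$ in *voxel* units (radius 5 → 515 voxels when
uncut). Implementation detail worth knowing: per fold, the per-voxel class
log densities of every test trial are computed once, and a sparse
centre × voxel membership matrix sums them over every sphere
simultaneously — mathematically identical to fitting a GNB in each sphere,
but hundreds of times faster in R. Centres whose sphere ∩ mask falls below
`min_voxels` (default 10) are *undefined* (NA) and excluded from group
statistics, never zero-filled.

Decoding tasks (`task_modality()`, `task_emotion_all()`,
`task_emotion_within()`, `task_emotion_crossmodal()`) carry their trial
filter, ordered class set and analytic chance level (1/classes). Modality is
decoded per session pairing (body vs voice in session 1, face vs voice in
session 2) and reported as their average. Within-visual emotion pools face
and body trials across sessions. Cross-modal tasks train on one category and
test on another, with voice trials drawn from the session paired with the
visual category, so train and test sets are disjoint by construction and a
single split (no cross-validation) is valid. All other tasks use
leave-one-run-out cross-validation with equal fold weights (folds are
equal-sized by design) and pooled accuracy — correct predictions over total
predictions, not class-balanced.

## Group inference

One-sample t against the analytic chance level, one-sided (above-chance is
the only direction of interest), per voxel; a voxel where every subject sits
exactly at chance reports t = 0, p = 0.5. Multiple-comparison control:

* **FWE**: Bonferroni over defined voxels (default), or a max-statistic
  permutation threshold when permutation t-maps are available. Random-field
  theory is intentionally not implemented: Bonferroni is conservative but
  exact to state, and the max-statistic route is the standard
  permutation-based alternative.
* **FDR**: Benjamini–Hochberg step-up via `stats::p.adjust`.
* **Cluster extent**: uncorrected voxel p < 0.001 with minimum cluster size
  k = 25, components by 26-neighbour connectivity by default (6 and 18
  available; the choice is not dictated by the protocol, and 26 is the most
  inclusive). Cluster-level p is reported only under the permutation method
  (fraction of permutations with a larger max cluster); without permutations
  it is NA rather than an approximation.

The **shared-label permutation test** draws `n` relabelings of the emotion
labels (shuffled within run, which preserves per-run class counts and hence
fold balance exactly), applies the *same* relabelings to every subject,
reruns the full leave-one-run-out decoding per subject and permutation, and
compares true vs permuted accuracy with a paired t-test across subjects. The
n per-permutation t-maps are then averaged into a single group map and
thresholded at t > 3.9. Averaging *after* the paired test is the only
reading under which a single averaged group t-map exists, and it is what
`permutation_group_test()` does. With few subjects, voxels can show
zero-variance paired differences (infinite t); downstream summaries should
use the finite bulk.

## ROI analysis and RDMs

Spherical ROIs (radius in voxel units, default 5) are placed at packaged
peak coordinates (`roi_table()`, a fixture of published Talairach-frame
peaks); hemispheric rows sharing a name (A1, amygdala) are united into one
bilateral mask. The synthetic grid carries an affine, so mm → voxel mapping
is exercised even though synthetic "anatomy" is arbitrary; the published ROI
*sizes* come from subject-specific localizers and are deliberately not
reproduced. One source ambiguity — A1 described both as a 5 mm sphere and
ROIs generally as 5-voxel spheres — is resolved by making the radius
per-ROI configurable with the 5-voxel default.

`roi_decode()` uses all ROI voxels as one feature set (no searchlight),
leave-one-run-out per subject (single split for cross-modal), a one-sample
t against chance per ROI × task cell, and BH-FDR across the *whole* ROI ×
task grid (the per-column alternative is defensible; whole-table is the more
conservative reading and is flagged in the report's attributes). The ten
report columns are: modality; emotion from all stimuli; emotion within body,
face, voice session 1, voice session 2; and the four cross-modal directions.

RDMs are 1 − Pearson r between condition-averaged patterns, 16 × 16 in the
fixed block order body, face, voice-session-1, voice-session-2 × anger,
happy, neutral, fear; entries lie in [0, 2] with a zero diagonal.
Zero-variance patterns yield flagged NAs. Per-subject RDMs are averaged for
display; `rdm_block_contrast()` summarises modality structure as
between-block minus within-block mean dissimilarity.

## Problem sizes, seeds, reproducibility

Every stochastic stage takes a seed; `derive_seeds()` spawns per-stage seeds
from one master seed, so any stage can be re-run in isolation.
`run_pipeline()` writes a manifest (file, md5, stage, seed) and identical
(config, seed) pairs produce hash-identical outputs.

The validation suites run at desk scale by choice: chance calibration uses
8 simulated subjects on a 12³ grid with the full 12-run schedule (≈ 14,000
defined-voxel accuracies per task); the dissociation experiments use 8
subjects, 12³ grids and radius-2 signal spheres; the permutation null check
uses 25 permutations on an 8³ grid. These sizes keep each suite in the
minutes range while leaving Monte-Carlo error well inside the tolerances
being asserted. The full cortical grid of a real study is larger by two
orders of magnitude but changes nothing structural: all algorithms are
linear or near-linear in voxels × trials.

## Known limitations

* The noise model omits physiological fluctuations, motion, scanner drift
  beyond smooth cosines, and spatial noise correlation; calibration results
  transfer to real data only insofar as those nuisances are handled upstream.
* No prewhitening: single-subject t-statistics on betas would be mildly
  optimistic under strong serial correlation; the package never uses them.
* Ground-truth patterns are shared across subjects (a perfectly aligned
  group), so between-subject anatomical variability is not modelled.
* Cross-modal single-split accuracies have few effective degrees of freedom
  per subject (same-emotion test trials share one pattern); their
  *group-level* tests are calibrated, but single-subject cross-modal maps
  are noisier than their within-modality counterparts.
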