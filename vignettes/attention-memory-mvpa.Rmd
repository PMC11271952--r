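---
title: "Decoding attentional modulation of memory representations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding attentional modulation of memory representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnrep)
```

# The scientific problem

When two pictures from different categories are shown at once and a cue
marks one of them as the target, selective attention decides what is
encoded into working memory and, a day later, what is still
recognizable. The cue can arrive before the pictures (perceptual or
*prospective* attention, filtering at encoding) or after them
(reflective or *retrospective* attention, operating on working-memory
contents — a retro-cue). `attnrep` implements the complete analysis
chain used to study this question with ROI-level fMRI multivoxel
pattern analysis:

1. **Behavior** — hit and false-alarm rates on a 4-point old/new scale,
   confidence of remembered items, attentional modulation
   (hit(attended) − hit(ignored)), and memory capacity
   (hit(attended) + hit(ignored) − 2·FA for two-item trials,
   hit − FA for baseline trials).
2. **Single-trial estimation** — least-squares-separate (LSS) GLMs with
   double-gamma HRF regressors, six motion parameters, the framewise
   displacement (FD) trace, and one-hot censor regressors for every
   volume with FD > 0.3 mm.
3. **Decoding** — a four-class (three picture categories + Gabor/rest)
   one-vs-rest L2-regularized logistic classifier trained on a separate
   block localizer, applied to the attention task after a fixed
   z-scoring chain, with leave-one-run-out validation; renormalized
   class probabilities are sorted into attended / ignored / other /
   rest roles per trial.
4. **Pattern similarity at retrieval** — Fisher-z Pearson correlations
   between the recognition-test t-maps of items that were co-presented
   in one attention trial (within-trial, WT) versus matched items from
   different trials (between-trial, BT); WT < BT indicates
   representational repulsion between a target and its paired
   distractor.
5. **Group statistics** — paired t-tests, fully within-subject two-way
   ANOVA, Benjamini–Hochberg FDR within declared families, and
   Cousineau–Morey within-subject error bars; brain–behavior relations
   are reported as Pearson correlations alongside a robust
   (bisquare-weighted) regression slope.

Because raw fMRI data for this paradigm cannot be packaged, the pipeline
ships with a first-class synthetic-data module whose ground-truth
parameters encode the effect structure under study, so every downstream
stage is testable by parameter recovery.

# The synthetic cohort

`simulationConfig()` fixes the study geometry; defaults reproduce the
published layout: trials of 1-s fixation, 1-s cue, 2-s encoding and 4-s
maintenance at TR = 2 s; six attention runs with 30 non-catch trials
each, balanced over the five cue-attention item groups (BL, PA, PI, RA,
RI), plus catch probes on one-sixth of all trials; each picture shown
twice, once per screen side, under the same attention status and with a
different-category partner; three localizer runs of nine 10-picture
mini-blocks separated by 8-s Gabor blocks; a recognition test of all
old items plus an equal number of foils (2-s fixation + 4-s picture).

`groundTruth()` holds the injected effects:

* **Attentional gains.** The neural response of a trial is an
  HRF-convolved boxcar times gain times (category prototype + item
  component + a shared stimulus-evoked component). Prospective trials
  apply `gainAttended`/`gainIgnored` from the picture onset onward;
  retrospective trials process both items equally during encoding
  (`gainRetroEncoding`) and apply their gains only in maintenance,
  mirroring when the effective cue is available. Defaults
  (PA 1.0, PI 0.3, RA 0.8, RI 0.5, BL 1.0, retro-encoding 0.7) encode
  the reported ordering: prospective attention filters more effectively
  than retrospective attention.
* **Filtering dissociation.** `ignoredRoiScale` multiplies the
  prospective-ignored gain per ROI; the default (dLPC 0, vLPC 0, VTC 1)
  encodes the finding that parietal cortex filters the distractor
  completely while ventral temporal cortex retains it, so PI−PO > 0
  only in VTC.
* **Pair-specific repulsion.** At retrieval, each old item's signal
  loses the fraction `repulsionRho` (per cue condition) of its
  component parallel to its co-presented partner's signal. Repulsion is
  injected at retrieval only, where it is measured; a flag
  (`repulsionAtEncoding`) propagates it to the attention task for
  sensitivity analyses.
* **Shared stimulus-evoked component.** All stimuli in an ROI share a
  common response direction (`commonAmp`, default 1, the same scale as
  the category prototypes). Real trial-pattern correlations are
  positive on average because all stimulus-evoked maps share global
  response structure; without this component, projection-removal
  repulsion would merely orthogonalize pairs around a zero-mean
  baseline and the WT−BT statistic would have no systematic sign. The
  component is identical across categories, so it does not affect
  category decoding.
* **Behavior.** Hit probabilities per cue-attention group, a
  false-alarm rate, and per-group probabilities that a hit is
  high-confidence. Published studies of this paradigm report orderings and
  test statistics rather than raw rates, so the defaults encode those
  orderings at plausible levels: hit BL = PA = 0.80 > RA = 0.70 >
  RI = 0.55 > PI = 0.35 with FA = 0.20 (so modulation is larger
  prospectively, while capacity is comparable between cue conditions
  and lowest at baseline), and high-confidence probabilities
  PA = BL = 0.70 > RA = 0.55.
* **Nuisance structure.** Motion follows an AR(1) with occasional
  step-like spikes; FD is derived from the motion derivatives
  (translations + 50 mm-scaled rotations), so censoring is exercised;
  per-voxel loadings couple motion into the data; i.i.d. Gaussian noise
  (`noiseSd`) is added per volume.

Two generator-level calibrations were fixed once and not revisited:
`noiseSd = 18` places leave-one-run-out localizer accuracy at the
default geometry (60 voxels, 3 runs) near 65%, inside the 50.0–77.5%
range reported for the real data; and item components have unit SD so
that item identity is decodable in principle, which pair-specific
similarity requires.

Everything is seeded: regenerating any schedule, behavioral table or
BOLD run from the same `SimulationConfig` is bit-identical, and
per-subject/task/run streams are derived deterministically from the
single `seed` slot.

# Timing conventions

All onsets lie on the TR grid. With a trial starting at volume index
$v_0$ (1-based):

* the **encoding** volume is the third TR after picture onset,
  i.e. $v_0 + 3$ (the picture appears 2 s into the trial); this is the
  volume beginning 4 s after the picture, accommodating hemodynamic
  lag. The off-by-one alternative can be obtained by selecting per-TR
  volumes directly.
* **maintenance** uses the mean of the two TRs beginning 4 s after the
  second-cue onset ($v_0 + 4$, $v_0 + 5$); averaging precedes
  classification.
* **per-TR** mode returns TR0–TR3 of the trial (TR0 covers the 1-s
  fixation plus 1-s first cue), each with the same two-TR shift.
* **localizer** pictures use the third TR after each picture onset.

The recognition LSS epoch is 2 s. The package models the 2-s window
from trial start (fixation up to picture onset, `lssEpoch = "trial"`);
the HRF is broad enough that the epoch regressor still tracks the
trial's response, and amplitudes are recovered up to a common scale.
The alternative reading — the first 2 s of the 4-s picture — is
`lssEpoch = "stimulus"`. The choice shifts all target regressors by
2 s and does not change any of the pipeline's comparative statistics.

# Normalization and classification

The z-scoring chain is applied in a fixed order: (1) each voxel is
z-scored across time within each run; (2) each volume is z-scored
across voxels; (3) the phase-specific volumes are selected (maintenance
TR pairs averaged); (4) each voxel is z-scored across all selected
volumes of the task, separately for the localizer and the attention
task. Constant voxels or volumes are mapped to zeros with a warning
rather than propagating NaNs.

The classifier is one-vs-rest L2-penalized logistic regression with
C = 0.01 under the convention that C multiplies the data-fit term and
the intercept is unpenalized. The four classes are the three picture
categories plus the Gabor/rest class — the only reading consistent with
four binary classifiers, three picture categories, and a 25% chance
level. The solver is a damped Newton iteration on the strictly convex
penalized log-likelihood (gradient tolerance 1e-10), so training is
deterministic; a small in-package solver was preferred over a penalized
path algorithm because the fit must be exact at a single fixed penalty
under the liblinear C convention. The four sigmoid outputs are
renormalized to sum to one; an option renormalizes over the three
picture categories only.

In leave-one-run-out validation all data-dependent statistics — the
task-level z parameters of step 4 — are estimated on the training folds
only and applied to the held-out run, avoiding leakage. When the
classifier is applied to the attention task, the attention volumes are
z-scored within their own task, matching the stated procedure for the
real data.

Two desk-scale facts are worth knowing when interpreting test output.
First, with a 2-s picture train and hemodynamic lag, volumes at block
edges mix neighboring conditions (late Gabor volumes carry the next
mini-block's rising response), which caps noiseless localizer accuracy
below 1; this mirrors the real block design rather than a defect.
Second, the encoding-phase volume is a single TR while maintenance
averages two TRs of a longer epoch, so maintenance contrasts are better
powered; desk-scale recovery checks therefore evaluate the attention
ordering and the filtering dissociation in the maintenance phase.

# Matched-pair similarity

Within-trial pairs are the (attended, ignored) item pairs of non-catch
prospective/retrospective trials. For each WT pair, between-trial
candidates are (attended item, ignored item) combinations that were
never co-presented with each other or with either WT member, agree
exactly on the category pair and on both members' memory outcomes, come
from trials with the same attended side (and the same cue condition by
default), and lie within `lagTol` recognition trials of the WT pair's
lag. One BT pair is selected per WT pair (greedy, smallest lag
difference first, seeded tie-breaking); WT pairs without candidates are
excluded from both sides, preserving the paired structure.

The lag tolerance defaults to 10 recognition trials, chosen for the
full 300-trial recognition test; analyses on shortened synthetic
recognition runs keep the same absolute tolerance, which is then
proportionally more permissive — appropriate, since lag effects scale
with list length. Correlations are clipped to ±(1 − 1e-7) before the
Fisher z so degenerate synthetic inputs keep finite z.

Group inference on WT−BT uses a paired t-test across subjects per
ROI × condition with BH-FDR over that family. Brain–behavior relations
report the Pearson correlation and, side by side, an iteratively
reweighted least-squares fit with bisquare weights (tuning constant
4.685, the standard default) whose slope t-statistic is robust to
outlying subjects; "memory performance" in that correlation is the mean
hit rate of targets and distractors.

# Group statistics

The original group analyses used linear mixed-effects models with
Satterthwaite degrees of freedom. This package deliberately replaces
them with paired tests and fully within-subject ANOVA on subject-level
means: the scientific claims under test here are sign, ordering and
calibration properties on synthetic cohorts, for which classical
within-subject inference is exact and auditable, and mixed-model
degrees of freedom would not be comparable anyway at desk scale. The
two-way repeated-measures ANOVA tests each effect against its own
subject × factor error stratum; its F values are verified against an
independent sums-of-squares decomposition in the test suite. Error
bars use Cousineau subject-centering with the Morey
$\sqrt{c/(c-1)}$ correction.

# Numerical and design choices

* HRF: canonical double gamma (peak delay 6 s, undershoot delay 16 s,
  unit dispersions, peak:undershoot 6), sampled on a 0.1-s grid for
  convolution, kernel normalized to unit peak. Parameters are
  configurable via `hrfParams()`.
* FD censoring is strict (> 0.3 mm); equality is not censored. An LSS
  target counts as fully censored when every volume from its onset to
  the hemodynamic peak of its epoch is censored; its pattern is then
  flagged missing rather than estimated.
* All-zero confound traces are dropped from designs (they carry no
  information and would make the model singular); rank deficiency
  among remaining columns is an error naming the collinear columns.
* High-pass filtering is available as a discrete-cosine basis
  (100-s cutoff) for runs simulated with drift; synthetic runs without
  drift do not need it and the flag defaults to off.
* Trial-level evidence is averaged over a picture's two presentations
  before condition averaging (disable with
  `evidenceContrasts(..., averageRepetitions = FALSE)`).
* Baseline trials have no distractor: the two absent picture
  categories fold into the "other" role so probabilities still sum
  to 1.

# What passing tests do and do not show

The generator emulates the study's timing, design structure, nuisance
processes and effect directions, not real anatomy or physiology: there
is no anatomical geometry or spatial autocorrelation, no scanner drift
or physiological noise unless enabled, category prototypes are random
Gaussian directions of equal norm, and behavioral responses are
conditionally independent Bernoulli draws. Parameter-recovery results
therefore validate the *implementation* — that each stage measures what
it claims to measure, with calibrated error rates, at the effect sizes
injected — and cannot certify preprocessing choices, anatomical ROI
definitions, or effect sizes in real data.

Problem sizes in the test suite are deliberately small (typically 4–10
subjects, 16–30 voxels per ROI, 6–12 items per cue-attention group,
2 attention runs) so the full suite runs in minutes; grid comparisons
(attentional-gain and repulsion grids) hold every seed fixed across
grid points, so differences between points reflect the injected
parameter rather than simulation noise. The chance-calibration and
type-I checks use 50 and 100 independently seeded replicates
respectively.

# Known limitations

* The attention-schedule pairing uses a fixed rotation scheme over
  categories, not a randomized Latin square; partner categories are
  balanced but not randomized.
* The matcher is greedy one-to-one; a many-to-one mode that averages
  several BT candidates per WT pair is not implemented.
* Behavioral confidence for correct rejections is simulated but not
  summarized in headline outputs (the analysis focuses on remembered
  items).
* Whole-brain univariate group maps, cluster-level correction,
  searchlight decoding and cross-phase generalization are out of
  scope.
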