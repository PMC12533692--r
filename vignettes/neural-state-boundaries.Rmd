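---
title: "Detecting neural state boundaries and their propagation between brain areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting neural state boundaries and their propagation between brain areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statebound)
```

## The problem

During naturalistic stimulation (e.g. movie watching), local cortical
activity moves through *neural states*: periods in which the multivariate
pattern across electrodes is temporarily stable, separated by abrupt
transitions (*neural state boundaries*). Two questions drive this package:

1. Do state boundaries extracted from intracranial (ECoG) recordings align
   with linguistic features of the stimulus (word and clause on/offsets) and
   with each other across brain regions?
2. When a boundary is shared between a low-level language region (superior
   temporal / primary auditory cortex) and a high-level one (inferior
   frontal, temporo-parietal), which region's boundary comes first? A
   high-level lead indicates top-down propagation; a low-level lead indicates
   bottom-up propagation.

At 64 Hz resolution these timing questions become answerable: a lag of one
sample is ~16 ms, far below anything fMRI can resolve.

The package implements the full chain — preprocessing, data-driven
segmentation, boundary-timeline alignment statistics, and group inference —
and ships a ground-truthed synthetic-cohort generator, so every stage is
validated end to end without access to patient data.

## Segmentation: greedy state boundary search

A 30-s speech block is a `T x C` matrix (1920 samples x electrodes, each
channel z-scored). The segmentation objective is the **fit criterion**: the
mean, over timepoints, of the Pearson correlation between the timepoint's
channel pattern and the mean pattern of its state. State means are computed
over spatially standardized patterns; a single-timepoint state contributes a
correlation of 1. With per-timepoint standardization the summed correlation
of a segment reduces to the across-channel standard deviation of the
segment's channel-sum vector, which makes each candidate evaluation O(C)
from a prefix-sum matrix — this algebraic identity, not an approximation, is
what keeps full-block searches fast.

The greedy search starts from one state and repeatedly inserts boundaries:

* **Single boundaries**: every possible split of every current state is
  scored; the best split is the candidate.
* **Full states (pairs)**: a state lying strictly inside an existing state
  can only be found by placing two boundaries at once. After locating the
  best single split, the best *completing* boundary within the same state is
  sought. The pair is placed instead of the single boundary when its fit
  gain **per added boundary** exceeds the single boundary's gain. Comparing
  raw fit would always favor the pair (an extra boundary never lowers the
  fit criterion — the triangle inequality on centered segment sums), so the
  per-boundary normalization is what makes the choice meaningful: a pair
  must earn its second boundary. An exhaustive O(T^2) pair search is
  available (`pair_search = "exhaustive"`) and agrees with the two-stage
  default on noiseless two-change instances; the two-stage search is the
  default for tractability.
* **Fine-tuning**: after each iteration every boundary may shift by one
  sample if that improves the fit (one sweep per iteration). Ties during
  placement go to the earliest candidate index, making the algorithm fully
  deterministic.

The greedy path records a segmentation for every number of states k from 1
to `kmax` (default: half the number of timepoints). When a pair is placed,
the intermediate single-boundary solution is recorded before fine-tuning, so
no k is skipped — this keeps the cross-block k grid complete.

## Choosing the number of states

The **t-distance** of a segmentation is a two-sample Student t statistic
comparing correlations of timepoint pairs *within* a state against pairs
spanning two *consecutive* states (pairs spanning non-adjacent states are
excluded; raw correlations, no Fisher transform). Its maximum over k
estimates the number of states, but on single-subject electrophysiology the
per-block argmax is noisy. The package therefore stabilizes the choice
across blocks:

1. average the t-distance curves of all blocks of a subject/ROI on the
   shared k grid and take the argmax (`select_nstates_global`);
2. per block, move to the nearest *peak* of that block's own curve
   (`select_nstates_block`). A peak is a point — or a pair of adjacent
   points with exactly equal value — with lower values on both sides;
   plateau pairs are represented by the lower k, equidistant peaks resolve
   to the smaller k, and a monotone curve falls back to the block argmax
   with a warning. Plateau runs longer than two points are not treated as
   peaks; with continuous-valued data they occur with probability zero.

## The Gaussian boundary match

Boundary timelines (binary marks on the 64 Hz grid, per 30-s speech block)
come from two sources: stimulus annotations (a mark at every word or clause
onset and offset, merged when they coincide on the grid) and state
segmentations (a mark at the first sample of each new state). The **Gaussian
match** between a *seed* timeline and another timeline is

$$\mathrm{match} = \frac{1}{N}\sum_{i=1}^{N}
  \exp\!\left(-\frac{\Delta_i^2}{2\sigma^2}\right),\qquad \sigma = 332\ \mathrm{ms},$$

where $\Delta_i$ is the distance from seed mark $i$ to the closest mark of
the other timeline *within the same block*. The statistic is deliberately
asymmetric: comparing stimulus features to neural boundaries seeds on the
stimulus (extra neural boundaries must not penalize the match); comparing
two neural timelines seeds on the one with fewer boundaries. The kernel SD
is a fixed design constant of the method, not a tuned parameter; no
alternative kernels or SD sweeps are provided. Seed marks in a block where
the other timeline has no marks are excluded from the mean (their count is
logged) rather than given near-zero weights that would dominate the average.

**Delays.** Conduction and processing delays shift neural boundaries
relative to the stimulus. `delay_scan` shifts the seed timeline across a
grid of whole samples — 0 to 600 ms for stimulus-vs-neural (the stimulus can
only precede the response), −600 to +600 ms for neural-vs-neural — and takes
the delay maximizing the match. 600 ms is not a multiple of 1/64 s, so the
grid ends at 38 samples (593.75 ms). Marks shifted past a block edge are
dropped, never wrapped. Tied maxima resolve to the smallest absolute delay,
then the smallest delay. `inter_roi_delay` fixes the sign convention:
negative delays mean the high-level region leads (top-down).

**Chance normalization.** The raw match is positive even for unrelated
timelines, and its chance level depends on the number and durations of
states. `relative_match` builds a permutation null by shuffling, per block,
the sequence of state durations (boundaries rebuilt from cumulative sums —
mark count and duration multiset are preserved exactly) and recomputing the
max-over-delays match, 1000 times by default. With `match_null` the mean of
the permuted maxima,

$$\mathrm{relative} = \frac{\mathrm{match_{data}} - \mathrm{match_{null}}}
 {1 - \mathrm{match_{null}}}$$

is ~0 at chance and 1 at perfect alignment. The shuffled timeline defaults
to the neural one (the stimulus timeline is an observed property of the
stimulus); the choice is exposed as `shuffle_target`.

## Group inference

Group tests are Wilcoxon signed-rank tests on per-subject quantities:
one-tailed on relative matches (alignment must exceed chance), two-tailed on
the per-subject difference of optimal delays between ROIs (either direction
of propagation is possible a priori). Zeros are dropped. For n ≤ 16 the
p-value is exact by enumerating all 2^n sign patterns on the observed
(mid)ranks — delays live on a sample grid, so tied absolute differences are
common and the usual exact algorithm would refuse them; for larger tie-free
samples the exact distribution of `stats::wilcox.test` is used, and the
normal approximation with continuity correction beyond n = 25. The delay
contrast includes only subjects whose relative match exceeds 0 in both ROIs
(an optimal delay is meaningless when the alignment itself is at chance);
no multiple-testing correction is applied, matching the small number of
planned comparisons. The median state duration per subject and ROI is
reported descriptively, without a group test.

## Preprocessing

The deterministic chain, in fixed order: drop flagged channels → 0.1 Hz
high-pass → despike → common-average reference → 50 Hz notch (2 Hz width) →
ROI channel selection → downsample to 64 Hz → clip at ±3 SD → z-score per
channel. Choices worth noting:

* High-pass and notch are zero-phase (forward-backward Butterworth): the
  delay analyses cannot tolerate filter-induced lag. Filtering uses
  full-length odd-reflection padding because a 0.1 Hz filter's start-up
  transient lasts several seconds and would otherwise contaminate the data.
* Despiking flags samples with robust z (median/MAD per channel) above 8 and
  linearly interpolates across flagged runs; the threshold is configurable,
  and more than 50% flagged samples in a channel is treated as an unusable
  signal. MAD-based flagging cannot, by construction, flag a majority
  cluster, so the guard fires only for pathological inputs.
* Clipping uses the channel's own pre-clip mean and SD; z-scoring happens
  after clipping, per speech block (the segmentation is per block, so
  per-block standardization is the matching choice; whole-run z-scoring
  would let amplitude differences between blocks leak into the patterns).
* ICA-based re-referencing requires visual component selection and is out of
  scope; `reference = "none"` accepts externally re-referenced data.
* On band-limited signals the chain is transparent (per-channel r > 0.99
  against direct decimation). On piecewise-constant state patterns the 0.1 Hz
  high-pass necessarily sags long plateaus (a step function has substantial
  sub-0.1 Hz energy), which lowers raw waveform correlations while leaving
  boundary *locations* intact — the tests assert exactly that: segmentation
  recovery survives the chain.

## The synthetic generator

`synthetic_spec()` defines the emulated study conditions; `generate_cohort()`
draws independent subjects from one seed sequence with a per-subject seed
manifest. Per block: low-ROI boundaries are drawn as a random composition of
the block length (default 15–40 states of ≥ 8 samples, i.e. roughly 0.7–2 s
states); the high ROI copies a configurable fraction (default 0.7) of them
shifted by the planted inter-ROI lag (default −123 ms: high leads) and
replaces the rest with independent boundaries. Each state emits a unit-norm
mean pattern (i.i.d. Gaussian by default; optionally mutually orthogonal,
which gives every boundary equal strength and is the cleaner stress test for
recovery claims) plus white channel noise (default SD 0.3). States switch
instantaneously — this is the definition of a neural state, not a
simplification of one. Stimulus event tables place clause on/offsets at
`boundary_time − delay` (defaults: 273 ms low, 150 ms high, so the delay
difference equals the planted lag) with 1-sample jitter, 10% spurious marks,
and 10% dropped marks; consecutive marks are paired into (onset, offset)
events so the rebuilt feature timeline reproduces the surviving mark set
exactly. A raw mode emits 512 Hz data with drift, common 50 Hz line noise,
and sparse spikes to exercise the preprocessing chain.

What the generator does *not* emulate: realistic ECoG spectra, volume
conduction, transition ramps, or endogenous (stimulus-independent) state
dynamics. Passing tests therefore demonstrate that the estimators recover
the planted structure under the stated noise model — not that patient data
satisfy that model.

## Problem sizes, determinism, and numerical choices

The validation suite uses full-size blocks (1920 samples, `kmax` = 960)
where the claim concerns the segmentation at scale (state-count recovery:
20 blocks), and reduced sizes elsewhere (null calibration: 100 cohorts of 10
subjects at 200 permutations; delay recovery: 20 single-subject cohorts) to
keep each property's runtime in minutes. All stochastic steps run from
recorded seeds; `gsbs_segment` itself is fully deterministic. Fit
comparisons use a 1e−12 tolerance so that floating-point noise cannot turn
exact ties into spurious "improvements"; degenerate inputs (zero-variance
channels or timepoint patterns, empty timelines, all-zero effect vectors)
raise errors naming the offender rather than propagating NaNs.

## Known limitations

* The t-distance argmax on a single noisy block is genuinely unstable —
  that is the reason for the cross-block stabilization, and the package
  makes no claim of per-block optimality.
* Under the null the per-subject relative match is right-skewed
  (max-over-delays statistics are; mean-normalization therefore puts the
  null *median* slightly below zero, with fewer but larger positive
  values). The group signed-rank test weighs sign and magnitude, and its
  empirical type-I rate on planted-null cohorts sits at the nominal level
  (≈0.05 over hundreds of replicate cohorts in the validation runs); but
  the per-subject quantity itself should not be read as symmetric noise
  around zero.
* Electrode-to-Brodmann assignment, bad-channel screening, and ICA component
  selection are consumed as inputs (channel tables), not computed.
* The function surface plus `scripts/acceptance.R` is the supported
  interface; there is no shell CLI.
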