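---
title: "Temporally aligned segmentation and clustering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporally aligned segmentation and clustering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tasc)
```

## The problem

Continuous recordings of behavior — pose landmarks of a freely moving
animal, facial distances of a patient, joint trajectories of a reaching
primate — are built from short recurring *motifs*: sub-second to
second-scale units of movement that repeat with variable timing. Analyses
that pair behavior with neural or clinical data need each repetition
delimited precisely (its boundaries) and identified (its cluster), but the
repetitions of one motif differ in phase and speed, so fixed-window
segmentation and off-the-shelf clustering blur them together.

`tasc` refines an initial segmentation and clustering by *linear temporal
alignment*: each candidate segment is mapped onto its cluster's centroid by
one time shift and one uniform time-scale, the residual distance (plus a
penalty on the warp) scores candidate re-segmentations, and a dynamic
program keeps the best non-overlapping set. Re-embedding the aligned
segments and re-clustering closes the loop; iterating sharpens both the
boundaries and the clusters.

## The model

### Signal, segments, activity

The recording is a $D \times T$ matrix $S$ (features by frames), min-max
normalized per feature to $[0, 1]$. Segments are half-open frame intervals
$[t_B, t_E)$, so lengths and overlap tests are exact integer arithmetic.

Per-frame motion energy is the sum over features of the absolute first
difference, smoothed by a zero-phase low-pass filter (second-order
Butterworth, default cutoff 1 Hz) and thresholded at a quantile of its own
distribution (default 0.25). Frames above threshold form *activity
periods*; a segment is *valid* when at least 90% of its frames are active
(inclusive). Validity is enforced wherever segments are proposed: at
initialization, for every temporal-neighbor variant during refinement, and
for gap-reassignment candidates. The last two are a deliberate design
choice (see *Design choices*): without them the refinement admits a
degenerate solution in which quiet baseline windows, which resemble the
flattened centroid of a phase-mixed cluster, progressively displace true
motif content — internal metrics improve while agreement with ground truth
collapses.

### Variable-length weighted distance

Sequences being compared rarely have equal length. For $x$ ($D \times
\ell_x$) and $y$ ($D \times \ell_y$), the shorter is tail-padded with its
own per-feature median plus $\varepsilon = 10^{-6}$ up to $m =
\max(\ell_x, \ell_y)$, and frames are weighted by

$$H = \left[\,1 + \mathrm{hamming}(\min(\ell_x,\ell_y)),\; 1, \dots, 1\,\right],$$

i.e. a Hamming window ($0.54 - 0.46\cos(2\pi n/(N-1))$) raised on a
baseline of 1, with the padded tail staying at exactly 1 so shorter
sequences are not preferred. The cost is
$\sqrt{\sum_{d,t} H_t (a_{d,t} - b_{d,t})^2}$ — the root of the summed
weighted squared differences across all channels. The root-sum (rather
than mean) convention affects absolute costs but not rankings within a
fixed length; it is stated here because these numbers are stored with the
segments. Center-weighting encodes the observation that motif edges are
the unreliable part of a segment. The measure is not amplitude-invariant:
a half-executed movement is far from a full one. A weighted
correlation-based distance would be the substitution point for tasks where
that matters.

### Linear alignment

A query $x$ is mapped onto a template $y$ by two parameters, a shift
$\tau_w$ and a slope $s_w > 0$, acting in normalized time $t \in [0, 1)$:

$$\hat{x}(t) = x\big((\tau_w + t\, s_w)\,\ell_x\big),$$

with linear interpolation between flanking frames and clamping of
out-of-range positions to the sequence edges (the optimizer probes the
whole box, so out-of-range draws must be cheap, not fatal). $\tau_w$ is
dimensionless; the frame-domain shift is $\tau_w \ell_x$ and is reported
alongside. The penalized loss is

$$\mathrm{loss} = \mathrm{weightedL2}(\hat{x}, y) + \alpha\, r, \qquad
  r = \arctan|\tau_w| + 1.5\,\arctan|s_w - 1|,$$

zero only at the identity transform, with the time-scale term penalized
more heavily. $\alpha = 0$ disables the penalty entirely.

One subtlety deserves emphasis. Because the warp acts in normalized time,
$s_w = 1$ maps the *whole* query onto the template whatever their lengths:
the raw parameters do not measure real time-dilation when lengths differ,
so under the raw penalty a segment can absorb extra frames and squeeze
them back penalty-free. On gapped recordings this produces runaway
segment inflation (we measured costs falling monotonically with every
appended baseline frame). The default therefore evaluates the penalty on
the length-corrected pair $(\tau_w \rho,\ s_w \rho)$ with $\rho =
\ell_q/\ell_t$ (`penalty_scale = "effective"`), which is exactly the
speed-ratio semantics under which the synthetic variants are generated
(`length = round(len / s_w)`); the literal raw scale remains available.
The two coincide for equal lengths, and the exported penalty function
keeps the closed form above.

Minimization runs over a bounded box (default $\tau_w \in [-0.25, 0.25]$,
$s_w \in [0.5, 2]$, covering the generation-scale warps of the synthetic
protocol with margin) using deterministic coarse sampling of the box
followed by Nelder-Mead refinement of the best starts plus the identity —
the global-sampling-plus-local-polish pattern used for low-dimensional
bounded minimization. A dense grid search is both the fallback path and
the brute-force oracle the optimizer is tested against. Note an asymmetry
users should expect: if a variant was *generated* from a template by
parameters $(\tau, s)$, aligning that variant back onto the template
recovers the inverse map $(-\tau/s,\, 1/s)$, because alignment warps the
query, not the template.

### The refinement epoch

Each epoch executes, in order:

1. **Outlier removal.** Within each cluster, pairwise weighted distances
   give each member a mean distance to the others; members beyond the mean
   plus $\gamma$ standard deviations are dropped (a median-centered variant
   is available via `outlier_center`). The pre-removal statistics are kept —
   they later gate gap reassignment.
2. **Centroids.** Members are resampled to their rounded mean length and
   combined element-wise by median (default) or mean; by default the
   *existing* member closest to that average is used instead of the
   average itself, so centroids are always realizable sequences.
3. **Variants.** Every segment spawns candidates $(t_B + m,\; t_E + m + l)$
   for $m$ over the offset range $M$ and $l$ over the length range
   $L(\text{epoch})$, both inclusive. Candidates outside $[0, T)$, shorter
   than 2 frames, or failing the activity-validity rule are marked invalid
   (the incumbent $m = l = 0$ candidate is exempt from the activity test so
   a segment cannot vanish through the mask alone).
4. **Scoring.** Each valid variant is aligned to its own cluster's centroid
   with the epoch's $\alpha$; costs are converted to scores per cluster
   (divide by the cluster's maximum cost, subtract from 1), which keeps
   imbalanced clusters from skewing the selection scale.
5. **Selection.** Weighted-interval scheduling over all variants of all
   segments: the score-maximal pairwise non-overlapping subset, found by
   the standard sorted-by-end dynamic program with binary-search
   predecessor lookup. Since the incumbent variants are always available,
   the selected total never falls below the incumbent segmentation's score
   under the same centroids. Scores carry a microscopic deterministic
   tie-break, $-10^{-4}(|m| + |l|)$: re-segmentations whose appended
   content the warp simply excludes are *exactly* cost-tied with the
   incumbent, and without the tie-break optimizer noise (~$10^{-6}$)
   random-walks boundaries along that flat manifold. Real score
   differences are $10^{-2}$ and larger.
6. **Re-embedding and re-clustering.** Selected segments are warped by
   their stored parameters, resampled to the mean selected length,
   embedded (PCA refit each epoch), and re-clustered (fuzzy c-means with
   the number of live clusters). New cluster ids are mapped back onto the
   old ones by a maximal-agreement assignment so labels stay comparable
   across epochs.
7. **Gap reassignment.** Uncovered stretches at least as long as the mean
   segment slide a window (stride: a quarter of the mean length) whose
   distance to each centroid is compared against that cluster's
   pre-removal mean intra-cluster distance; passing windows compete by the
   same cost-to-score-plus-DP machinery within their gap.

The loop stops at the configured epoch count or earlier when fewer than 1%
of segments move either boundary by more than one frame.

## Initialization

The internal path cuts fixed windows across the recording, drops invalid
ones, embeds them (PCA, components configurable), soft-clusters them
(fuzzy c-means), and resolves overlaps by the same dynamic program using
the maximum membership as score. The default stride is a third of the
window: overlapping candidates sample each motif at several phases and
the membership-score selection keeps the best-phased ones, which raises
initial accuracy substantially (mean IoU ≈ 0.56 versus ≈ 0.32 for
end-to-end tiling on the semi-synthetic protocol). The worked
semi-synthetic configuration (`semisynthetic_config()`) instead tiles
windows end to end, mirroring the benchmark's original initialization —
a deliberately naive starting point from which the refinement's
improvement is plainly visible; with the overlapping default the
initialization already sits near the refinement's equilibrium and the
epochs mostly sharpen clustering rather than boundaries.

Fuzzy c-means is initialized deterministically: the first center is the
point nearest the data mean, subsequent centers are farthest-first
choices. This removes the only stochastic step in the default pipeline,
so clustering is reproducible and equivariant under input permutation
without seed juggling (the `seed` argument remains for stochastic
plug-ins). The fuzzifier defaults to 1.5 rather than the textbook 2.0:
on weakly separated embeddings the larger value exhibits the well-known
fuzzy-center collapse (all centers migrate to the grand mean and the
hard labels degenerate), which we observed mid-refinement; if a
re-clustering still collapses, the epoch keeps its previous labels and
warns. Up to 1000 iterations. The cluster count can be chosen by the
mean-silhouette sweep (`select_cluster_count`), ties toward fewer
clusters.

Any external segmentation (CSV of `start,end[,label,...]`) can replace
this path; unlabeled external segments are clustered first. Densely
strided external segmentations can be thinned by `spatiotemporal_dilution`,
which greedily removes segments that overlap a retained one by more than
half their length *and* sit within a latent radius (default: the median
nearest-neighbor embedding distance) of it.

## The semi-synthetic generator

`make_motif_library` + `assemble_signal` reproduce the validation protocol
used throughout: five multichannel motifs of 60–90 frames (five features,
smooth sums of 1–3 low-frequency sinusoid/bump components in place of the
original curated motifs, which are not redistributable), each instantiated
with uniformly random linear warps ($\tau_w \in \pm 0.1$, $s_w \in 1 \pm
0.2$; a variant's length is $\mathrm{round}(\ell / s_w)$, so slow
executions come out longer), laid in seeded random order on a constant
baseline equal to the per-feature mean across motifs, separated by
baseline gaps of uniformly random length (default 30–90 frames — a stated
choice, since only the presence of baseline between insertions is given;
gaps exercise both activity detection and gap reassignment), min-max
normalized, then perturbed by Gaussian noise ($\sigma = 0.01$). True
boundaries, labels, and every warp draw are recorded; with the noise off,
the recorded draws reconstruct each variant exactly.

What this emulates: warp-variability, phase ambiguity, rest periods, and
mild sensor noise at a realistic frame rate (120 fps). What it does not:
amplitude variability, drifting baselines, landmark dropouts, motif
co-articulation, or label noise — so passing tests here demonstrate the
machinery, not robustness to every property of real recordings.

## Worked configuration

`semisynthetic_config()` is the benchmark configuration: 90-frame windows,
10-component PCA, 5-cluster FCM with median existing centroids,
$M = (-10, 10)$, $L(n) = (-n, 10)$, $\alpha = 10^{R(n)}$ with $R$ evenly
spaced on $[0.5, -1]$ across epochs, $\gamma = 4$, 10 epochs. The
decreasing $\alpha$ schedule permits stronger warping as segmentation
stabilizes; $\gamma = 4$ is deliberately permissive, preserving all
members when the initial clustering is sound.

## Numerical choices

* Hamming convention: the symmetric window
  $0.54 - 0.46\cos(2\pi n/(N-1))$; single-frame windows degenerate to a
  flat raise of 1.
* Padding epsilon $10^{-6}$: only breaks exact ties; never visible at
  signal scale.
* Optimizer: coarse grid 11 × 15 (lean 5 × 7 inside the refinement loop,
  where tens of thousands of alignments run per epoch; the lean setting
  was verified to reproduce the strong setting's epoch trajectories),
  Nelder-Mead on the clamped box from the best starts plus the raw and
  effective identity transforms, tolerance $10^{-9}$ ($10^{-8}$ in-loop).
  Agreement with a 0.002-resolution exhaustive grid is part of the test
  suite.
* Selection tie-breaks: candidates sorted by end, then start, then input
  index; on equal totals the dynamic program keeps the candidate, so
  zero-score incumbents survive when nothing better claims their frames.
* Degenerate inputs: constant features normalize to zero; all-identical
  embeddings refuse to cluster; clusters emptied by outlier removal are
  retired with a warning and the cluster count is not re-inflated;
  single-member clusters skip the outlier test and are flagged.
* Convergence: < 1% of segments moving a boundary by > 1 frame stops the
  loop — boundary stability is the refinement target, so it is also the
  stopping criterion.

## What "fixed point" means here

A useful diagnostic — exercised in the test suite — initializes the loop
at the exact ground truth of a noiseless recording and runs one epoch.
Under the pure distance ($\alpha = 0$) the truth is an exact fixed point:
boundaries stay put, because every competing variant matches the centroid
no better than the incumbent and the tie-break settles exact ties. Under a
*positive* $\alpha$ this is intentionally not true: the penalty trades
boundary placement against warp magnitude, so instances whose true
execution is strongly warped get nudged toward less-warped-looking
boundaries. That is the designed behavior of the penalized objective, not
an artifact, which is why the stability check is defined at $\alpha = 0$.

## Problem sizes in the test suite

The packaged tests and the acceptance script run the full protocol shape
at reduced instance counts chosen to keep a laptop-scale single-core run
comfortable: alignment-recovery statistics over 200 noiseless pairs,
selection-optimality checks against exhaustive enumeration over hundreds
of random candidate sets, and end-to-end refinement on libraries of five
60–90-frame motifs with 6–12 variants per motif across multiple seeds.
These sizes are choices, not limits; `cmd_synth`/`cmd_run` reproduce the
full 20-variant protocol unchanged.

## Known limitations

* The method relies on motifs contributing clear structure to the chosen
  features; featureless centroids make alignment uninformative. Supplying
  curated motifs as initial centroids (semi-supervision) is the natural
  remedy and is supported through external initialization.
* Results are not transferable across sessions beyond exporting centroids.
* One shift and one slope per segment cannot express non-uniform timing
  inside a motif; piecewise-linear or DTW alignment would, at the cost of
  interpretability, and neither is implemented here.
* The distance is amplitude-sensitive by design (see above).
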