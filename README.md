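# tasc

Temporally aligned segmentation and clustering of multichannel behavioral
time series.

## The problem

Recordings of behavior — pose landmarks of a freely moving rodent, facial
distances of a patient, joint trajectories during a motor task — decompose
into short recurring **motifs**: sub-second movement units that repeat with
variable phase and speed. Downstream analyses (behavior–neural coupling,
clinical tic characterization) need each repetition delimited to frame
precision and assigned to the right cluster, but fixed windows cut motifs
at arbitrary phase and clustering on misaligned segments blurs them.

`tasc` iteratively refines an initial segmentation and clustering using
**penalized linear temporal alignment**. A query segment `x` is mapped onto
a template `y` by a shift `τ_w` and a uniform time-scale `s_w` acting in
normalized time `t ∈ [0, 1)`:

    x̂(t) = x((τ_w + t·s_w)·ℓ_x),
    loss  = weightedL2(x̂, y) + α·r,   r = arctan|τ_w| + 1.5·arctan|s_w − 1|

where `weightedL2` is a variable-length Euclidean distance (median-padded
tails, frames weighted by a Hamming window raised on a baseline of 1) and
`α` weights the penalty that keeps warps honest. Each epoch:

1. removes within-cluster outliers (γ standard deviations above the mean
   pairwise distance),
2. computes cluster centroids (element-wise median, by default the closest
   actual member),
3. scores every temporal neighbor `(t_B + m, t_E + m + l)` of every segment
   against its cluster centroid by minimizing the loss over a bounded
   `(τ_w, s_w)` box,
4. converts costs to per-cluster scores and selects the score-maximal
   non-overlapping subset by dynamic programming,
5. warps the selected segments by their fitted parameters, re-embeds (PCA)
   and re-clusters (fuzzy c-means),
6. rescans large unassigned gaps against the centroids.

Segments must lie at least 90% inside detected activity periods — at
initialization, for every candidate variant, and for gap candidates — which
anchors the refinement to actual movement.

## Worked example

Generate a ground-truthed semi-synthetic recording (five 60–90-frame
motifs, randomly warped instances on a quiet baseline, Gaussian noise) and
refine a naive fixed-window segmentation:

```r
library(tasc)

lib <- make_motif_library(n_motifs = 5, length_range = c(60, 90),
                          n_features = 5, seed = 2)
ds  <- assemble_signal(lib, n_variants_per_motif = 8, noise_sigma = 0.01,
                       seed = 3)
ds
#> <tasc_dataset> 5 features x 5838 frames, 40 true segments (5 classes), noise sd 0.01

cfg <- semisynthetic_config(epochs = 10, seed = 1)
res <- run_tasc(ds$signal, cfg, truth = ds$truth)
res
#> <tasc_result> 31 segments after epoch 10
#>   mean cost 1.397 | silhouette 0.656 | IoU vs truth 0.475 | boundary L1 925
res$trace[c(1, 4, 11), c("epoch", "n_segments", "silhouette", "iou_vs_truth")]
#>    epoch n_segments silhouette iou_vs_truth
#> 1      0         16  0.3683975    0.2473315
#> 4      3         27  0.6583382    0.4366773
#> 11    10         31  0.6556845    0.4750378
```

The trace records, per epoch, the segment count, mean alignment cost,
silhouette and Calinski–Harabasz indices of the refined clusters, and —
because ground truth was supplied — mean intersection-over-union against
the true segments and the summed L1 distance between corresponding
boundaries. Here the naive tiling starts from 16 windows covering 40 true
motif instances at mean IoU 0.25; ten refinement epochs grow the
segmentation to 31 segments, 28 of them matched to a true instance, and
roughly double the mean IoU (0.25 to 0.48) while the clusters tighten
(silhouette 0.37 to 0.66). Evaluate any segmentation against ground
truth:

```r
ev <- evaluate_segmentation(res$segments, ds$truth)
str(ev[c("mean_iou", "boundary_l1", "recall", "n_matched")])
#> List of 4
#>  $ mean_iou   : num 0.475
#>  $ boundary_l1: int 925
#>  $ recall     : num 0.575
#>  $ n_matched  : int 28
```

A thin command-line front-end (`inst/cli/tasc.R`) exposes the same
pipeline as `synth`, `run` and `evaluate` subcommands operating on CSV
files with YAML/JSON configurations.

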