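# lensroi

ROI determination, simulation and evaluation for **lensless calcium
imaging**.

Implantable lensless CMOS sensors record GCaMP fluorescence by direct
contact with brain tissue. Without focusing optics every neuron's light
spreads over many pixels, so the video contains diffuse blobs with no sharp
boundaries and the standard cell-segmentation tools for lens-based calcium
imaging (CNMF, Suite2p, …) do not apply. `lensroi` implements an ROI
determination algorithm built for this regime, plus everything needed to
characterize it against known ground truth.

## The algorithm

Frames are first baselined per pixel to percent ΔF/F,

    %ΔF_i/F_i,0 = 100 · (F_i,t − F_i,0) / F_i,0,

with F_i,0 the pixel mean over the pre-stimulation segment. The mask is
then built in two passes with seven tunable parameters
(σ₁, FP₁, A₁, σ₂, FP₂, A₂, time):

1. each of the first *time* frames is binarized with a **Gaussian adaptive
   threshold** (kernel SD σ₁; a pixel is foreground when it strictly
   exceeds the Gaussian-weighted mean of its neighborhood), then cleaned by
   **morphological opening** (square footprint FP₁) and **area opening**
   (components below A₁ px removed);
2. the cleaned binary frames are **averaged** into an occupancy image, and
   the same binarize (σ₂) / open (FP₂) / area-open (A₂) sequence applied to
   that average gives the final ROI mask.

Per-ROI traces (%ΔF/F of the ROI-mean fluorescence) are denoised by **STFT
spectral subtraction** using the mean ΔF/F of all non-ROI pixels as the
noise reference, and grouped into activity clusters by **PCA + k-means**
with the number of clusters selected by the **mean silhouette** score.

The package also ships a simulator of lensless datasets — 30 point-source
neurons at depths of 4–8 px (30–60 µm) with three post-stimulation firing
patterns — and evaluation tools: ground-truth detection accuracy, replicate
studies, missed-neuron depth analysis, and a PLS sensitivity model of the
seven parameters. See the methods vignette
(`vignettes/lensless-roi-methods.Rmd`) for the models and all numerical
conventions.

## Worked example

Simulate a reduced-length dataset (1/20 of the full frame count), detect
ROIs with the optimized parameters, score against ground truth and cluster
the denoised traces:

```r
library(lensroi)

cfg <- sim_config(n_pre_frames = 450L, n_post_frames = 1800L, seed = 42L)
ds  <- simulate_dataset(cfg)
dff <- compute_dff(ds$frames, cfg$n_pre_frames)
post <- dff[, , 451:2250]

rois <- determine_rois(post, algorithm_params())  # sigma 1.5, FP 3, A 0
rois
#> ROI mask 120 x 40: 31 ROI(s), mean area 32.84 px

detection_accuracy(rois, ds$neurons)
#> Detection accuracy (neuron center inside an ROI):
#>       pattern  n detected  fraction
#>      pattern2  9        9 1.0000000
#>  unresponsive  6        1 0.1666667
#>      pattern1 15       13 0.8666667
#>   active (pattern1+pattern2): 22/24 = 0.917

rset   <- label_rois(rois)
traces <- roi_traces(ds$frames, rset, 450L)
noise  <- noise_trace(dff, rois)
tss    <- apply(traces, 2, spectral_subtract, noise = noise)
cluster_roi_traces(t(tss[451:2250, ]), seed = 42L)
#> Activity clustering: k = 3 (mean silhouette 0.624), 7 PC(s)
#>   cluster sizes: 4, 10, 17
```

22 of 24 active neurons fall inside an ROI (both misses sit at the maximum
depth, z = 8 px — lensless detection degrades with distance from the
sensor),
most unresponsive neurons are correctly not captured, and the denoised
traces separate into three clusters: the two active firing patterns plus
one background/unresponsive group.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "lensroi", package = "lensroi")`, with subcommands
`simulate`, `detect`, `extract`, `denoise`, `cluster`, `evaluate`, `sweep`,
`replicates` and `run`.

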