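---
title: "ROI determination for lensless calcium imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI determination for lensless calcium imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lensroi)
```

## The problem

Implantable lensless CMOS sensors record calcium fluorescence by direct
contact with brain tissue. With no focusing optics, the light of each
GCaMP-expressing neuron spreads across many pixels and overlaps with its
neighbors, so the video shows diffuse, boundary-less "forms" rather than
cells. Segmentation tools built for lens-based microscopy (CNMF, Suite2p and
relatives) assume compact cellular footprints and do not transfer. `lensroi`
implements an ROI determination algorithm designed for this regime, together
with a ground-truth simulator and the evaluation machinery needed to
characterize it.

## The ROI determination algorithm

All detection operates on percent dF/F frames. Each pixel $i$ is baselined
against its mean over the pre-stimulation segment,

$$\%\Delta F_i/F_{i,0} = \frac{F_{i,t} - F_{i,0}}{F_{i,0}} \times 100\%,$$

and after segmentation each ROI trace is the analogous quantity computed
from the ROI-mean fluorescence $\bar F_t$ and the ROI-mean baseline $F_0$.

The mask is built in two passes:

1. **Per-frame pass.** Every analyzed frame is binarized with a Gaussian
   adaptive threshold: a pixel is foreground when it strictly exceeds the
   Gaussian-weighted mean (kernel SD $\sigma_1$, window `block_size`) of its
   neighborhood. The binary frame is cleaned by morphological opening
   (square footprint $FP_1$) and area opening (minimum component area
   $A_1$).
2. **Averaging pass.** The cleaned binary frames are averaged into a
   per-pixel occupancy image — the fraction of frames in which each pixel
   was a local maximum. The same binarize ($\sigma_2$) / open ($FP_2$) /
   area-open ($A_2$) sequence applied to this average yields the final
   mask.

Binarizing frame by frame (rather than binarizing the mean image) weights
every frame's local maxima equally, so transient low-amplitude sources are
not drowned by bright epochs. The seven tunables are
$\sigma_1, FP_1, A_1, \sigma_2, FP_2, A_2$ and `time_frames` (how many
frames enter the first pass). The threshold window side (`block_size`,
default 15) is deliberately excluded from the tunable set: it does not
change which ROIs are selected, only marginally how smooth the threshold
surface is. Defaults ($\sigma = 1.5$, $FP = 3$, $A = 0$) are the settings
that produce uniformly distributed, consistently sized ROIs; over-large
$\sigma_1$ merges neighborhoods into sprawling regions, while small
$\sigma_2$ with a larger $FP_2$ deletes almost everything.

### Numerical and boundary conventions

* Gaussian threshold: kernel truncated to the `block_size` window,
  normalized per axis, boundaries reflected (edge pixel repeated). The
  comparison is strict (`>`) with zero offset, shielded by a tiny tie
  tolerance (`1e-9` relative) so that mathematically constant regions
  binarize to exactly zero despite floating-point summation order.
* Opening: erosion with zero padding (features touching the border erode),
  dilation with the reflected footprint — the adjoint pair, which keeps
  opening idempotent and anti-extensive for every footprint. Odd footprints
  are centered; even footprints (the default sweep grid includes $FP = 2$)
  anchor at the floor-center pixel.
* Area opening and ROI labeling use 8-connectivity; components of exactly
  the minimum area are retained ("strictly lower" is removed).
* All separable neighborhood sums are computed as banded-matrix BLAS
  products, batched across frames; this is what makes hundred-replicate
  studies feasible in pure R.

## The simulator

`sim_config()` encodes the synthetic study design: a $120 \times 40$ px
sensor at 10 fps, 9,000 pre-stimulation frames (15 min) and 36,000
post-stimulation frames (60 min), and 30 point-source neurons at integer
positions $x \in [5, 35]$, $y \in [5, 115]$ (the noisy 5-px sensor border
is excluded) and depth $z \in [4, 8]$ px — 30 to 60 µm at the 7.5 µm pixel
pitch; closer tissue is assumed damaged by implantation.

**Activity.** During the baseline every neuron fires as a per-frame
Bernoulli(0.10). Post-stimulation each neuron follows one of three patterns
assigned uniformly at random. Firing regimes are: *high* — 10 Hz events
with 25% burst chance; *medium* — 10 Hz with 1/15 burst chance; *low* —
5 Hz with 1/20 burst chance; bursts carry 2–5 spikes uniformly. Pattern 1
is high for the first sixth of the post window, medium for the next two
sixths, low thereafter; pattern 2 swaps the high block into the second
sixth (medium first), then declines the same way; unresponsive neurons keep
baseline statistics. Since stated rates are per second at a ~10 fps frame
rate, events per frame are drawn Poisson(rate/fps), which preserves the
per-second expectations and the high > medium > low ordering. Schedule
blocks are defined as fractions of the post window, so a shortened
simulation compresses the pattern proportionally.

**Optics.** A spike contributes an instantaneous-rise, exponentially
decaying transient ($\tau = 1$ s, GCaMP6-like, kernel truncated at $5\tau$).
The instantaneous brightness is spread on the sensor as an isotropic point
source over a planar detector: irradiance $\propto z/(d^2+z^2)^{3/2}$ at
lateral offset $d$, truncated at radius $4z$. The peak pixel of a spike at
depth $z$ is `spike_amplitude`$/z^2$: deeper neurons are simultaneously
dimmer and blurrier, which is the phenomenon that makes lensless ROI
detection depth-limited.

**Noise.** Three components, each configurable to zero: (i) i.i.d. Gaussian
pixel noise (`noise_sd`); (ii) a static linear illumination gradient along
the long axis, emulating uneven LED excitation; (iii) a slowly varying
stray-light fluctuation shared by all pixels (AR(1), SD
`background_noise_sd`, time constant 5 s). The shared term reflects how
these devices actually fail — non-stationary stray light reaches every
pixel — and it is what gives the non-ROI "noise reference" its meaning: a
purely i.i.d. noise model would make spectral subtraction a no-op. Because
it is a per-frame global offset, it cancels exactly in the local-mean
threshold and therefore does not interact with detection.

**Amplitude calibration.** The brightness of a single spike in detector
units is not a physically constrained quantity; it was fixed once
(`spike_amplitude = 120`, `noise_sd = 1` on a baseline of 100 counts) so
that the deepest simulated neurons sit near the detection limit of the
optimized algorithm — detection failures then concentrate at $z = 7$–8 px,
typically when a deep neuron lies a few pixels from a brighter neighbor
whose halo raises the local threshold ("shadowing"). This is the operating
regime the replicate studies characterize: most replicates capture all
active neurons, a substantial minority miss one or two deep ones.

## Spectral subtraction

ROI traces are denoised against the mean dF/F of all non-ROI pixels.
Both trace and reference are transformed with a short-time Fourier
transform (periodic Hann window, 256-frame segments ≈ 25.6 s at 10 fps,
50% overlap — a constant-overlap-add configuration, so the transform
round-trips to numerical precision). The reference magnitude spectrogram is
subtracted from the trace's, negative magnitudes are floored at zero (the
standard spectral-subtraction rule), the trace's phase is reused, and the
inverse transform returns a trace of the original length. The raw
background spectrogram is subtracted without per-ROI rescaling.

## Activity clustering

Denoised post-stimulation traces are clustered to separate active from
non-active ROIs and to group activity patterns: PCA retains the smallest
component set explaining 95% of variance, k-means (10 restarts) runs for
$k = 2..10$, and the $k$ with the highest mean silhouette width wins (ties
to the smallest $k$).

Feature preparation required a genuine design decision. Traces are averaged
into 6-s bins and scaled by $\sqrt{s_i^2 + (2\,\tilde s)^2}$, where $s_i$
is the trace SD and $\tilde s$ the median SD across ROIs. Two failure modes
motivate this instead of a plain per-trace z-score: without normalization,
the $\sim 4\times$ depth-driven amplitude range dominates the Euclidean
geometry and k-means partitions by brightness rather than activity pattern;
with a full z-score, the many neuron-free ROIs are inflated into
unit-variance noise vectors that are mutually near-orthogonal, and the
silhouette criterion happily carves that diffuse shell into extra clusters.
The noise-floor regularization normalizes genuinely active traces while
leaving near-silent ones close to the origin, where they form the single
background cluster they belong to. The low-level operations
(`reduce_traces()`, `cluster_traces()`) are scaling-agnostic; the policy
lives only in `cluster_roi_traces()`.

The *active* cluster is the one whose member traces have the highest
time-averaged mean over the analysis window; ties go to the smallest label.

## Evaluation

A simulated neuron counts as detected when its center pixel lies inside an
ROI — no tolerance radius, which makes the criterion strict: a mask that
surrounds a neuron without covering its center pixel scores a miss.
`replicate_study()` repeats simulate → baseline → detect → score over
seeds and reports the fraction of replicates capturing 100% and ≥ 90% of
active (pattern 1 or 2) neurons with Clopper–Pearson intervals, plus the
full 10%-bin histogram. `undetected_depth_analysis()` pools misses across
replicates; under the point-source model the mean depth of missed active
neurons exceeds that of detected ones.

### Parameter sensitivity

`parameter_sweep()` runs the pipeline over a parameter grid (default
levels: $\sigma \in \{0.5, 1.5, 2.5\}$, $FP \in \{1, 2, 3\}$,
$A \in \{0, 9\}$ per pass, plus `time_frames` levels) and
`pls_parameter_model()` fits a partial least squares regression of mean ROI
area on the seven raw-unit parameters (2 latent components by default),
reporting response-scale coefficients, in-sample $R^2$, and the relative
prediction deviation SD(y)/RMSE from leave-one-out refits. PLS is used
rather than OLS because the sweep designs are small and the parameters act
through strongly collinear intermediate quantities.

Two empirical subtleties deserve a record. First, *mean* ROI area is a
ratio of survivors: a large opening footprint ($FP = 5$) deletes small ROIs
outright, and the surviving large ones can raise the mean even though
opening by a larger footprint is pointwise smaller — the monotone quantity
is foreground mass, which the test suite checks as a theorem-level
property. Second, sweep settings with no opening at all ($FP = 1$) can
produce a single sprawling component three orders of magnitude larger than
typical ROIs; on such a right-skewed response an additive linear model is
mis-specified, so the sensitivity analysis in the acceptance checks fits
the log response (a monotone transform, leaving the sign structure — both
sigmas and $A_2$ positive, both footprints negative, $A_1$ and time near
zero — as the object of interest), pooled over three simulated datasets.

## Problem sizes used by the tests and the acceptance script

Replicate studies and clustering checks run the full $120 \times 40$ px
design at 1/20 of the frame count (450 pre- + 1,800 post-stimulation
frames, patterns compressed proportionally), 100 replicates for detection
statistics and 10 seeds for cluster-count selection; parameter sweeps use
shorter stacks (300 + 900 frames, 36-point sampled grids per dataset).
These sizes were chosen as the smallest at which the detection and
clustering statistics are stable across seeds; all of them are plain
function arguments, and the full-scale design is a configuration change.

## What passing tests do and do not show

The simulator emulates point-source geometry, depth attenuation, calcium
kinetics, firing statistics, stray light and shot-like noise. It does not
emulate motion artifacts, hemodynamic signals, absorption-filter leakage,
angular sensor sensitivity, or spatially structured electronic noise, and
its neurons are ideal points rather than extended somata. Results on
synthetic data therefore validate the algorithmic contracts (detection
under the stated SNR regime, depth-dependent failure, pattern
separability), not in-vivo performance; real recordings additionally face
the parameters' interaction with tissue-specific brightness scales that
must be set by inspection.

## Known limitations

* The detection criterion is center-pixel containment; a 1-px mask
  misalignment counts as a miss even when the ROI clearly corresponds to
  the neuron.
* Silhouette-based $k$ selection takes the global maximum; data with a
  hierarchy of groupings can have informative local maxima at larger $k$
  that are deliberately ignored.
* Spectral subtraction assumes the background reference is representative
  of the noise inside ROIs; spatially structured noise gains are not
  modeled.
* `pls_parameter_model()` reports in-sample $R^2$ alongside leave-one-out
  RPD; with small sweep designs the former is optimistic by construction.
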