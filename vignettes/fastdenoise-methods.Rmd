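---
title: "Self-supervised denoising of high-speed fluorescence imaging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised denoising of high-speed fluorescence imaging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastdenoise)
```

## The problem

High-speed fluorescence imaging of neural activity — calcium indicators at
tens of hertz, voltage indicators at a kilohertz — is photon-starved: short
exposures collect few photons, so frames are dominated by shot noise (Poisson,
signal-dependent) plus camera read noise (Gaussian, additive). Clean reference
recordings do not exist for in-vivo data, which rules out supervised
denoising. `fastdenoise` implements a *self-supervised* scheme: the denoiser
is trained on the noisy recording itself, exploiting the fact that noise is
independent across nearby pixels and frames while the underlying fluorescence
signal is not.

## Training-pair construction (frame-multiplexed spatiotemporal sampling)

Let the recording be an $H \times W \times T$ stack. Two sampling operations
build each training example:

1. **Temporal windows.** A window of width $C$ frames slides along the stack
   with shift step $S \le C$. Pair $i$ consists of the input window $X_i$
   starting at frame $iS$ and the target window $Y_i = X_{i}$ shifted by one
   step, starting at frame $iS + S$. The windows overlap when $S < C$, so
   input and target share slow signal content but differ in noise
   realizations. $S$ is the single knob trading temporal separation (more
   denoising of slow signals) against fidelity to fast transients; the
   default is $S = C/2$ with $C = 16$.

2. **Spatial 2×2 subsampling.** Each frame is partitioned into 2×2 blocks.
   For every block one of the six two-one binary *mask cells* is drawn
   (there are exactly $\binom{4}{2} = 6$ such 2×2 matrices); the cell selects
   two pixels for branch $G_1$ and its complement selects the other two for
   branch $G_2$. Each branch averages its two selected pixels (a stride-2
   sparse convolution with weights 0.5/0.5), producing half-resolution views
   $G_1(\cdot)$, $G_2(\cdot)$ whose pixels at the same coordinate come from
   *adjacent* source pixels: their signal content agrees, their noise is
   independent. One mask field is drawn per window pair — a pure function of
   (pair index, seed) — and shared by $X_i$ and $Y_i$, which keeps the
   spatial adjacency between the two views consistent within a pair while
   varying across pairs. A `single_pixel` subsampling mode (take one selected
   pixel instead of the two-pixel mean) is available for comparison with
   single-pixel neighbor-subsampling schemes.

Odd trailing rows/columns are cropped before subsampling during training
(padding would fabricate pixels); inference operates on full frames.

## The network

The denoiser $f(\cdot)$ is a deliberately small 2-D encoder-decoder that
treats the $C$ frames of a window as input channels:

* grouped 3×3 stem projection $C \to 64$;
* two encoder blocks: grouped 3×3 convolution (2 channels per group),
  batch normalization, ReLU, 3×3 max-pool stride 2;
* two decoder blocks: nearest-neighbour ×2 upsampling, grouped 3×3
  convolution, batch normalization, ReLU — with a single skip connection
  concatenating the second encoder block's pre-pool features into the first
  decoder block (the top-level skip is deliberately absent: top-level features
  are mostly noise in a denoising task);
* 1×1 output projection $64 \to C$.

Grouping with 2 channels per group keeps groups of adjacent frames
independent through the trunk (mitigating temporal aliasing across distant
frames) and keeps the model tiny: 7,632 trainable parameters at the defaults
(`count_parameters(build_model(network_config()))`), under the 0.013 M
design budget. The window width must be even because of the 2-channel groups.
Since the architecture is fully convolutional, the same weights process
full-resolution windows and half-resolution subsampled windows alike — a
property the objective depends on.

Design points that were genuinely open, and the choices made:

* **Stem and output projections.** The boundary layers are not pinned down by
  the architectural summary we follow. An *ungrouped* 3×3 stem would cost
  $3\cdot3\cdot16\cdot64 + 64 = 9{,}280$ parameters by itself and push the
  total past the 0.013 M budget, so the stem is a grouped 3×3 convolution in
  the same style as the encoder blocks; the output is an ungrouped 1×1
  projection, which is what finally mixes information across frame groups.
* **Max-pool.** 3×3 window, stride 2, padding 1 — stride 2 is forced by the
  downsampling role; padding preserves even dimensions.
* **Skip tap point.** Encoder-2 features are taken *pre-pool* and
  concatenated after the first upsample (standard U-Net convention).
* **Initialization.** He-uniform everywhere except the output projection,
  whose weights are scaled by $5\times10^{-3}$ and whose bias the fitting
  routine sets to the normalized corpus mean — the initial network is the
  mean-intensity map. With batch size 1 and a learning rate of $10^{-4}$ the
  optimizer makes small per-step moves, and a scale-matched start lets short
  schedules (tens of epochs) reach useful denoisers; with a plain He start
  the output scale is ~7× the signal scale and short runs stall. (On the
  package's standard calcium fixture this choice is the difference between a
  strongly negative PSNR and a >10 dB gain at 30 epochs.)
* **No residual output.** The network predicts intensities directly.
* **Batch normalization** uses per-window statistics during training (batch
  size is 1 throughout, so "batch" statistics are per-sample), biased
  variance, momentum 0.1 running buffers, and running statistics at
  inference, which makes evaluation deterministic. Both training-mode
  forward passes of a step (on $G_1(X_i)$ and on $X_i$) update the running
  buffers, in that order.

## The objective

Two terms, summed with no hidden weighting:

* **Scale self-constraining:**
  $L_{SC} = \lVert f(G_1(X_i)) - G_1(f(X_i)) \rVert_2^2$ —
  the prediction on the subsampled input must agree with the subsampled
  prediction on the full input, tying the network's behaviour across the two
  scales it is used at. Gradients are *not* propagated through $f(X_i)$
  (stop-gradient); the term only steers the $f(G_1(X_i))$ path.
* **Spatiotemporal self-supervising:**
  $L_{ST} = \lVert f(G_1(X_i)) - G_2(Y_i) \rVert_2^2
           + \lVert P(f(G_1(X_i))) - P(G_2(Y_i)) \rVert_1$,
  where $P$ averages intensity over 10 randomly placed 20×20 patches
  (averaged over all $C$ frames), constraining slow intensity trends that the
  pixel term alone under-weights.

Reductions are means (per term), so losses are comparable across window
sizes; any constant factor is absorbed by the learning rate. Patches are
redrawn each optimization step from the step's sub-seed, keeping the patch
statistic unbiased over training; a fixed-patch mode (fixed `patch_spec`)
serves the unit tests. For images smaller than 20 pixels the patch side is
clipped to `min(20, H, W)`. Whether $P$ should average per frame or over the
window is not pinned down by its description; averaging over all frames
matches its stated purpose (consistency of intensity *trends over time*).

## Training

Defaults: 100 epochs, batch size 1, ADAM with AMSGrad, learning rate
$10^{-4}$, weight decay $10^{-4}$, master seed 123. Window pairs are visited
in index order within an epoch; augmentation applies one of the eight
dihedral symmetries jointly to both windows, both subsampled views and the
mask field, drawn from a per-step sub-seed. The optimizer state persists
across epochs and there is no learning-rate schedule. Every random stream
(initialization, per-pair mask fields, per-step augmentation and patches)
derives from the master seed through a counter scheme, so the whole weight
trajectory is a pure function of (data, configuration, seed) — run it twice
and the weights agree bit for bit.

Intensities are affinely normalized to $[0,1]$ by the training stack's
(min, max); the transform is stored in the fit and inverted at prediction.
A recorded, invertible normalization is the safest default for data whose
absolute scale is camera-specific.

For volumetric multi-channel series (x-y-z-t per channel), each channel
trains its own model; the Z plane-wise x-y-t stacks of a channel jointly form
the corpus of one model, with plane order shuffled per epoch under the master
seed (interleaving planes within an epoch is the rejected alternative; with
optimizer state shared either way, order-shuffling is the variant that does
not privilege deep planes every epoch).

## Inference

Offline: windows of width $C$ at stride $S$ (plus a tail window ending at the
last frame) are normalized, forwarded in evaluation mode, denormalized, and
overlapping per-frame outputs are averaged with equal weights — each frame's
blend weights sum to 1. Central-frame selection is the rejected alternative;
averaging uses all available estimates of a frame. Spatial sizes not
divisible by 4 (two pooling stages) are reflect-padded and cropped back.

Streaming: three cooperative stages — acquire, denoise, emit — connected by
bounded FIFO queues reproduce the real-time pipeline's queueing contract:
frames are processed in arrival order, a full queue stalls the upstream stage
(back-pressure; never silent frame dropping), shutdown drains every queue so
`frames_out == frames_in`, and per-frame latency plus steady-state throughput
are recorded. The default streaming stride is $S = C$ (non-overlapping
blocks, lowest latency), which is pixel-identical to offline inference at
$S = C$; overlapped streaming ($S < C$) is available at higher latency. The
stages are scheduled cooperatively in one R process; the contract tested is
ordering, conservation and back-pressure, not wall-clock parallelism.

## The simulation harness

The generator emulates the features of functional recordings that matter to
a denoiser, not the optics of any particular microscope:

* **Structure:** soma-like 2-D Gaussian blobs (random centres, radii 2.5–5
  px, peak amplitudes 0.1–0.3) over a background of 0.05, with per-cell masks
  at each blob's half-maximum. Amplitudes are chosen so that the standard
  noise model below puts the noisy input near 13–14 dB PSNR — the
  photon-starved regime of interest.
* **Activity:** per-cell Poisson event trains convolved with a unit-peak
  kernel — a triangular pulse of stated full width (2/4/6/8 ms at 1000 Hz)
  for voltage; a bi-exponential rise/decay kernel (rise 50 ms, decay 400 ms
  at 30 Hz) for calcium. The clean video modulates the structure
  multiplicatively on each cell's mask:
  `clean = structure * (1 + amplitude * trace)`.
* **Noise:** `noisy = Poisson(a * clean) / a + N(0, sigma^2)` — unbiased,
  with variance `clean / a + sigma^2`. The standard fixture uses photon gain
  a = 2 and read sigma = 0.1.

What the generator does *not* emulate: optical PSF and scattering, motion,
neuropil contamination, indicator nonlinearity, structured (row/column)
camera noise. Passing the package's checks therefore demonstrates the
method's behaviour under idealized photon-limited conditions, not performance
on any specific instrument; motion in particular must be corrected upstream.

The standard calcium fixture (`synthetic_calcium_fixture()`) is
64 × 64 × 200 frames, 8 cells, 30 Hz, seed 7 — small enough that a full
training run takes minutes on one CPU core, noisy enough (~13.7 dB input
PSNR) that denoising gains are unambiguous.

## Evaluation

* `psnr(ref, test, data_range)` = $10\log_{10}(\text{range}^2/\text{MSE})$,
  with an `Inf` sentinel at zero error.
* `ssim()` — windowed SSIM with a 7×7 Gaussian window ($\sigma = 1.5$),
  $k_1 = 0.01$, $k_2 = 0.03$, mean over valid window positions and frames.
  The constants are fixed and documented because reported SSIM values depend
  on them.
* `extract_dff()` — per-ROI mean fluorescence $F(t)$, baseline $F_0$ as the
  10th percentile of $F$ over time (robust to activity; the baseline
  definition is pluggable and recorded in the output), and
  $\Delta F/F = (F - F_0)/\max(F_0, \epsilon)$. Per-pixel traces are single
  pixel ROIs.
* `trace_correlation()` — per-ROI Pearson r, with `NA` flagged for constant
  traces.
* `boxcar_smooth()` — the classical moving-average control: it gains PSNR on
  slow signals but *destroys* millisecond transients, which is exactly the
  failure mode the spatiotemporal sampling scheme avoids.

## Problem sizes used by the test suite

The packaged checks train on the 64 × 64 × 200 calcium fixture for 30 epochs
(~700 optimization steps, C = 16, S = 8) and on a 64 × 64 × 2000 voltage
scene at the hardest spike width (2 ms at 1000 Hz) with the kinetics-matched
window C = 2, S = 1 for 10 epochs (~20,000 steps). The window choice for the
voltage check is the method's own dial, not a tuning trick: with the calcium
default S = 8 the target window no longer contains a 2 ms transient at the
input window's position, and the fitted denoiser measurably suppresses
spikes (trace correlation against ground truth falls *below* the noisy
input); at C = 2, S = 1 adjacent-frame windows share every transient,
temporal smearing is bounded by the 2-frame window, and the correlation
ordering denoised > noisy > 9-frame boxcar emerges within a few epochs and
keeps improving with training length. These sizes keep a full suite run in
the tens of minutes on one CPU core; production use at the defaults
(100 epochs, longer stacks) only increases the margins.

## Known limitations

* Training assumes noise that is independent across adjacent pixels and
  across windows $S$ frames apart; correlated noise (fixed-pattern,
  row-banding) violates the premise and will be partially learned as signal.
* Signals faster than the shift step blur: choose $S$ (and $C$) against the
  kinetics of interest — small $S$ for voltage, larger for calcium.
* The streaming engine models the queueing contract; it does not itself use
  OS threads, so wall-clock throughput is bounded by single-core inference
  speed.
* Batch-norm running statistics come from training windows; applying a fit to
  data with a very different intensity distribution without re-fitting will
  shift the output scale.
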