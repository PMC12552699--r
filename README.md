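# fastdenoise

Self-supervised, real-time-oriented denoising for high-speed fluorescence
neural imaging in R: calcium imaging at tens of hertz, voltage imaging at a
kilohertz, and volumetric multi-channel time-lapse series. No clean reference
data are needed — the denoiser is trained on the noisy recording itself.

## Who this is for

Labs doing functional fluorescence imaging in the photon-starved regime,
where shot noise (Poisson) and camera read noise (Gaussian) bury neuronal
morphology and distort activity traces. Supervised denoisers need clean
targets that in-vivo data cannot provide; classical temporal smoothing
destroys exactly the millisecond transients voltage imaging exists to record.

## The method

Training pairs come from **frame-multiplexed spatiotemporal sampling** of the
noisy stack itself. A temporal window of width *C* frames slides with shift
step *S* ≤ *C*: pair *i* is the input window *X<sub>i</sub>* (start *iS*) and
target window *Y<sub>i</sub>* (start *iS + S*). Each window is split
spatially: every 2×2 pixel block draws one of the six two-one binary mask
cells; the cell selects two adjacent pixels for branch *G<sub>1</sub>*, its
complement the other two for *G<sub>2</sub>*, each branch averaging its pair
(stride-2 sparse convolution). The two half-resolution views share signal but
have independent noise.

A deliberately small 2-D grouped-convolution encoder-decoder *f* (two encoder
blocks, two decoder blocks, 64 feature channels, 2 channels per group, a
single deepest-level skip connection; 7,632 trainable parameters — under
0.013 M) maps *C*-frame windows to *C*-frame windows and is fitted with

&nbsp;&nbsp;*L<sub>SC</sub>* = ‖*f*(*G<sub>1</sub>*(*X<sub>i</sub>*)) − *G<sub>1</sub>*(*f*(*X<sub>i</sub>*))‖²₂ &nbsp; (scale self-constraining; no gradient through *f*(*X<sub>i</sub>*))

&nbsp;&nbsp;*L<sub>ST</sub>* = ‖*f*(*G<sub>1</sub>*(*X<sub>i</sub>*)) − *G<sub>2</sub>*(*Y<sub>i</sub>*)‖²₂ + ‖*P*(*f*(*G<sub>1</sub>*(*X<sub>i</sub>*))) − *P*(*G<sub>2</sub>*(*Y<sub>i</sub>*))‖₁

&nbsp;&nbsp;*L<sub>total</sub>* = *L<sub>SC</sub>* + *L<sub>ST</sub>*,

where *P* averages intensity over ten random 20×20 patches (an intensity-
trend constraint). Training: ADAM + AMSGrad, learning rate 10⁻⁴, weight decay
10⁻⁴, batch size 1, 100 epochs by default, dihedral augmentation, master seed
123; fully reproducible. Inference runs sliding windows with overlap
averaging, or a streaming FIFO pipeline (acquire → denoise → emit) with
bounded queues and back-pressure for real-time use.

The shift step *S* is the temporal-fidelity dial: large *S* (default *C*/2)
suits slow calcium indicators; kilohertz voltage imaging with millisecond
spikes needs *S* of 1–2 frames so that input and target windows still share
each transient.

## Worked example

Simulate the package's standard calcium fixture (64×64×200 frames at 30 Hz,
8 cells, mixed Poisson-Gaussian noise at photon gain 2, read sigma 0.1),
train for 30 epochs, and measure the gain:

```r
library(fastdenoise)

fx <- synthetic_calcium_fixture(seed = 7)
rng <- max(fx$scene$clean_video) - min(fx$scene$clean_video)

psnr(fx$scene$clean_video, fx$noisy, rng)   # 13.69 dB  (noisy input)
ssim(fx$scene$clean_video, fx$noisy, rng)   # 0.045

fit <- fast_denoiser(fx$noisy, window_width = 16, shift_step = 8,
                     epochs = 30, seed = 123)
print(fit)
#> Self-supervised fluorescence denoiser
#>   window width C = 16, shift step S = 8, seed = 123
#>   7632 trainable parameters (0.0076 M), 30 epochs
#>   final loss: 0.00323344 (scale-consistency 7.61256e-05 + spatiotemporal 0.00315731)

den <- predict(fit, fx$noisy)
psnr(fx$scene$clean_video, unclass(den), rng)   # 26.1 dB  (+12.4 dB)
ssim(fx$scene$clean_video, unclass(den), rng)   # 0.70
```

The fitted object is a regular R model: `print()`, `summary()`, `coef()`
(named weight tensors), `predict()` (denoise a stack), `plot()` (loss
history), `residuals()`. Checkpoints: `save_checkpoint()` /
`load_checkpoint()`.

A command-line interface wraps the same functions
(`inst/scripts/fast`): `fast simulate`, `fast train`, `fast denoise`,
`fast stream`, `fast evaluate`; every artifact-writing run records its full
configuration as JSON beside its output.

## Limitations

Noise must be (approximately) independent across adjacent pixels and across
*S*-frame temporal shifts: correlated fixed-pattern noise will be partly
learned as signal. Motion correction belongs upstream. See the methods
vignette (`vignettes/fastdenoise-methods.Rmd`) for the full model
description, design rationale and simulation caveats.
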