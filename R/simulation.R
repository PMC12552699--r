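#' Mixed Poisson-Gaussian sensor noise model
#'
#' Photon shot noise (Poisson, signal-dependent) plus additive Gaussian read
#' noise. `photon_gain` is the expected photon count per intensity unit; the
#' Poisson draw is divided by the gain so intensity units are preserved and the
#' expectation of the noisy signal equals the clean signal, with variance
#' `x / photon_gain + read_sigma^2` at clean intensity x.
#'
#' @param photon_gain expected photons per intensity unit (a > 0).
#' @param read_sigma Gaussian read-noise standard deviation in intensity units.
#' @param seed integer seed.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(photon_gain = 2, read_sigma = 0.1, seed = 1L) {
  if (photon_gain <= 0) stop("photon_gain must be > 0")
  if (read_sigma < 0) stop("read_sigma must be >= 0")
  structure(list(photon_gain = photon_gain, read_sigma = read_sigma,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Add mixed Poisson-Gaussian noise to a clean signal
#'
#' @param clean non-negative numeric array.
#' @param noise a [noise_model()].
#' @param photon_counts return raw photon counts instead of intensity units?
#' @return Noisy array of the same shape.
#' @examples
#' nz <- add_mixed_noise(array(4, c(8, 8, 2)), noise_model(1, 0.5, seed = 1))
#' @export
add_mixed_noise <- function(clean, noise = noise_model(), photon_counts = FALSE) {
  stopifnot(inherits(noise, "noise_model"))
  if (min(clean) < 0) stop("clean signal must be non-negative")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(sub_seed(noise$seed, 909L))
  a <- noise$photon_gain
  counts <- rpois(length(clean), a * as.numeric(clean))
  noisy <- if (photon_counts) counts
           else counts / a + rnorm(length(clean), 0, noise$read_sigma)
  out <- array(noisy, dim(clean))
  out
}

#' Generate a static neuronal structure image
#'
#' Soma-like 2-D Gaussian blobs with random centres, radii and amplitudes over
#' a low uniform background; per-cell masks are the pixels where a cell's own
#' blob exceeds half its peak.
#'
#' @param H,W image size.
#' @param n_cells number of cells (`>= 0`).
#' @param seed integer seed.
#' @param background baseline intensity; default 0.05.
#' @param amplitude_range blob peak amplitudes, drawn uniformly; default
#'   `c(0.1, 0.3)` (dim somata over a low background, the photon-starved
#'   regime of high-speed functional imaging).
#' @param radius_range blob Gaussian sigma in pixels; default `c(2.5, 5)`.
#' @return A list: `structure` (H x W matrix), `masks` (list of n_cells
#'   2-column pixel index matrices), `overlap` (TRUE if any two masks share a
#'   pixel).
#' @export
generate_structure <- function(H, W, n_cells, seed = 7L, background = 0.05,
                               amplitude_range = c(0.1, 0.3),
                               radius_range = c(2.5, 5)) {
  H <- as.integer(H); W <- as.integer(W); n_cells <- as.integer(n_cells)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(sub_seed(seed, 11L))
  img <- matrix(background, H, W)
  masks <- list()
  if (n_cells > 0L) {
    margin <- ceiling(max(radius_range))
    cy <- runif(n_cells, margin + 1, H - margin)
    cx <- runif(n_cells, margin + 1, W - margin)
    amp <- runif(n_cells, amplitude_range[1], amplitude_range[2])
    sig <- runif(n_cells, radius_range[1], radius_range[2])
    rr <- row(img); cc <- col(img)
    for (k in seq_len(n_cells)) {
      blob <- amp[k] * exp(-((rr - cy[k])^2 + (cc - cx[k])^2) / (2 * sig[k]^2))
      img <- img + blob
      masks[[k]] <- which(blob >= amp[k] / 2, arr.ind = TRUE)
    }
  }
  overlap <- FALSE
  if (n_cells > 1L) {
    lin <- lapply(masks, function(m) m[, 1] + (m[, 2] - 1L) * H)
    all_px <- unlist(lin)
    overlap <- any(duplicated(all_px))
  }
  list(structure = img, masks = masks, overlap = overlap)
}

# Unit-peak activity kernels.
pulse_kernel <- function(width_frames, shape = c("triangular", "gaussian",
                                                 "rectangular")) {
  shape <- match.arg(shape)
  w <- as.integer(width_frames)
  if (w < 1L) stop("pulse must span at least one frame")
  t <- seq_len(w) - 1
  apex <- (w - 1) / 2
  k <- switch(shape,
    triangular = 1 - abs(t - apex) / (w / 2),
    gaussian = exp(-(t - apex)^2 / (2 * (w / 4)^2)),
    rectangular = rep(1, w))
  k / max(k)
}

calcium_kernel <- function(tau_rise, tau_decay, fps) {
  t <- seq(0, 5 * tau_decay, by = 1 / fps)
  k <- (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)
  k / max(k)
}

# Seeded Poisson spike train convolved with a unit-peak kernel.
spike_trace <- function(T_, rate, fps, kernel, seed) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  spikes <- rbinom(T_, 1L, min(1, rate / fps))
  tr <- as.numeric(stats::convolve(spikes, rev(kernel), type = "open"))
  list(trace = tr[seq_len(T_)], spikes = spikes)
}

make_scene <- function(str, traces, amplitude, fps) {
  H <- nrow(str$structure); W <- ncol(str$structure)
  T_ <- nrow(traces)
  clean <- array(rep(str$structure, T_), c(H, W, T_))
  for (k in seq_along(str$masks)) {
    m <- str$masks[[k]]
    if (nrow(m) == 0L) next
    lin <- m[, 1] + (m[, 2] - 1L) * H
    base <- str$structure[lin]
    mod <- outer(base, amplitude * traces[, k])   # npix x T increment
    idx <- rep(lin, T_) + rep((seq_len(T_) - 1L) * H * W, each = length(lin))
    clean[idx] <- clean[idx] + as.numeric(mod)
  }
  structure(list(structure = str$structure, masks = str$masks,
                 traces = traces, clean_video = clean, frame_rate = fps,
                 amplitude = amplitude, overlap = str$overlap),
            class = "synthetic_scene")
}

#' Simulate a voltage-imaging scene with controlled spike widths
#'
#' Neurons carry Poisson spike trains convolved with a unit-amplitude pulse of
#' the stated full width (triangular by default); the clean video modulates the
#' static structure multiplicatively on each neuron's mask:
#' `clean = structure * (1 + amplitude * trace)`.
#'
#' @param H,W frame size; default 64.
#' @param n_neurons number of neurons; default 10.
#' @param fps acquisition rate in Hz; default 1000.
#' @param spike_width_ms full pulse width in milliseconds (2, 4, 6 or 8 in the
#'   standard protocol); must span at least one frame at `fps`.
#' @param rate mean spike rate in Hz; default 5.
#' @param n_frames number of frames T; default 2000.
#' @param seed integer seed.
#' @param amplitude peak fractional fluorescence change per spike; default 0.8.
#' @param pulse_shape `"triangular"` (default), `"gaussian"` or
#'   `"rectangular"`.
#' @return A `synthetic_scene`: `structure`, `masks`, `traces` (T x n_neurons),
#'   `clean_video` (H x W x T), `frame_rate`.
#' @export
generate_voltage_video <- function(H = 64L, W = 64L, n_neurons = 10L,
                                   fps = 1000, spike_width_ms = 4,
                                   rate = 5, n_frames = 2000L, seed = 7L,
                                   amplitude = 0.8,
                                   pulse_shape = "triangular") {
  wf <- spike_width_ms * fps / 1000
  if (wf < 1) stop("spike_width_ms * fps / 1000 must span at least one frame")
  kernel <- pulse_kernel(round(wf), pulse_shape)
  if (rate / fps * length(kernel) > 0.5)
    warning("spike rate so high that pulses will saturate the trace")
  str <- generate_structure(H, W, n_neurons, seed)
  traces <- vapply(seq_len(n_neurons), function(k)
    spike_trace(n_frames, rate, fps, kernel, sub_seed(seed, 21L, k))$trace,
    numeric(n_frames))
  traces <- matrix(traces, nrow = n_frames)
  make_scene(str, traces, amplitude, fps)
}

#' Simulate a calcium-imaging scene
#'
#' Like [generate_voltage_video()] but with calcium-indicator kinetics: spike
#' trains are convolved with a unit-peak bi-exponential kernel
#' `(1 - exp(-t/tau_rise)) * exp(-t/tau_decay)`.
#'
#' @param H,W frame size; default 64.
#' @param n_cells number of cells; default 8.
#' @param fps acquisition rate in Hz; default 30.
#' @param tau_decay decay time constant in seconds; default 0.4.
#' @param tau_rise rise time constant in seconds; default 0.05.
#' @param rate mean event rate in Hz; default 0.3.
#' @param n_frames number of frames T; default 200.
#' @param seed integer seed.
#' @param amplitude peak fractional fluorescence change per event; default 1.5.
#' @return A `synthetic_scene` (see [generate_voltage_video()]).
#' @export
generate_calcium_video <- function(H = 64L, W = 64L, n_cells = 8L, fps = 30,
                                   tau_decay = 0.4, tau_rise = 0.05,
                                   rate = 0.3, n_frames = 200L, seed = 7L,
                                   amplitude = 1.5) {
  if (tau_decay <= 0) stop("tau_decay must be > 0")
  kernel <- calcium_kernel(tau_rise, tau_decay, fps)
  str <- generate_structure(H, W, n_cells, seed)
  traces <- vapply(seq_len(n_cells), function(k)
    spike_trace(n_frames, rate, fps, kernel, sub_seed(seed, 21L, k))$trace,
    numeric(n_frames))
  traces <- matrix(traces, nrow = n_frames)
  make_scene(str, traces, amplitude, fps)
}

#' The standard synthetic calcium fixture
#'
#' The package's reference simulation for quick CPU experiments and its
#' denoising-gain checks: a 64 x 64 x 200 calcium scene (8 cells, 30 Hz,
#' seed 7) degraded by mixed Poisson-Gaussian noise at photon gain 2 and read
#' sigma 0.1, which puts the noisy input in the low-PSNR regime typical of
#' photon-starved high-speed recordings.
#'
#' @param seed scene seed; default 7.
#' @return A list: `scene` (the `synthetic_scene`), `noisy` (H x W x T array),
#'   `noise` (the [noise_model()] used).
#' @export
synthetic_calcium_fixture <- function(seed = 7L) {
  scene <- generate_calcium_video(seed = seed)
  nm <- noise_model(photon_gain = 2, read_sigma = 0.1, seed = seed + 1000L)
  list(scene = scene, noisy = add_mixed_noise(scene$clean_video, nm),
       noise = nm)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$clean_video)
  cat(sprintf("<synthetic_scene> %d x %d x %d frames at %g Hz, %d cells\n",
              d[1], d[2], d[3], x$frame_rate, length(x$masks)))
  invisible(x)
}
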