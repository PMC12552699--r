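#' Sliding-window coverage plan for whole-stack inference
#'
#' Window starts at stride S, plus a tail window ending at the last frame so
#' every frame is covered; overlapping window outputs are averaged with equal
#' weight (each frame's weights sum to 1).
#'
#' @param n_frames total frame count T.
#' @param window_width window width C (`T >= C`).
#' @param shift_step stride S between window starts.
#' @return A list of class `blend_plan`: `starts` (0-based), `coverage`
#'   (per-frame window count) and `weights` (per-frame averaging weight,
#'   `1/coverage`).
#' @export
blend_plan <- function(n_frames, window_width, shift_step) {
  T_ <- as.integer(n_frames); C <- as.integer(window_width)
  S <- as.integer(shift_step)
  if (T_ < C) stop("stack shorter than one window (T = ", T_, " < C = ", C, ")")
  if (S < 1L) stop("shift_step must be >= 1")
  starts <- seq.int(0L, T_ - C, by = S)
  if (tail(starts, 1L) != T_ - C) starts <- c(starts, T_ - C)
  coverage <- integer(T_)
  for (s in starts) coverage[(s + 1L):(s + C)] <- coverage[(s + 1L):(s + C)] + 1L
  structure(list(starts = starts, coverage = coverage, weights = 1 / coverage),
            class = "blend_plan")
}

# Reflect-pad spatial dims up to the next multiple of 4 (pad <= 3 rows/cols,
# mirrored without repeating the edge), remembering the original size.
reflect_pad4 <- function(a) {
  d <- dim(a)
  ph <- (4L - d[1] %% 4L) %% 4L
  pw <- (4L - d[2] %% 4L) %% 4L
  if (ph > 0L) a <- a[c(seq_len(d[1]), d[1] - seq_len(ph)), , , drop = FALSE]
  if (pw > 0L) a <- a[, c(seq_len(d[2]), d[2] - seq_len(pw)), , drop = FALSE]
  list(a = a, H = d[1], W = d[2])
}

model_forward_eval <- function(model, x) {
  if (is.function(model)) return(model(x))
  if (inherits(model, "fast_denoiser")) model <- model$net
  net_forward_impl(model, x, training = FALSE, update_running = FALSE)$y
}

model_norm <- function(model) {
  if (inherits(model, "fast_denoiser")) model$norm else c(0, 1)
}

model_channels <- function(model, default) {
  if (inherits(model, "fast_denoiser"))
    model$net$config$in_out_channels
  else if (inherits(model, "fast_network"))
    model$config$in_out_channels
  else default
}

#' Offline sliding-window denoising of a whole stack
#'
#' Normalizes the stack with the model's stored intensity scale, runs the
#' network on windows of width C at stride S (plus a tail window), averages
#' overlapping per-frame outputs with equal weights, and inverts the
#' normalization. Spatial sizes not divisible by 4 are reflect-padded
#' internally and cropped back.
#'
#' @param model a `fast_denoiser` fit, a bare `fast_network`, or (for testing
#'   custom denoisers) a function mapping an H x W x C array to an equal-shape
#'   array.
#' @param stack a [video_stack()] or 3-D array.
#' @param window_width window width C (defaults to the model's channel count).
#' @param shift_step stride S; default `window_width %/% 2`.
#' @return A denoised [video_stack()] with the input's shape and metadata.
#' @export
denoise_stack <- function(model, stack, window_width = NULL, shift_step = NULL) {
  a <- as_stack_array(stack)
  d <- dim(a)
  C <- as.integer(window_width %||% model_channels(model, 16L))
  S <- as.integer(shift_step %||% max(1L, C %/% 2L))
  plan <- blend_plan(d[3], C, S)
  norm <- model_norm(model)
  scale <- norm[2] - norm[1]
  if (scale <= 0) scale <- 1
  an <- (a - norm[1]) / scale
  pad <- reflect_pad4(an)
  dp <- dim(pad$a)
  acc <- array(0, dp)
  for (s in plan$starts) {
    idx <- (s + 1L):(s + C)
    y <- model_forward_eval(model, pad$a[, , idx, drop = FALSE])
    acc[, , idx] <- acc[, , idx] + sweep(y, 3L, plan$weights[idx], "*")
  }
  out <- acc[seq_len(pad$H), seq_len(pad$W), , drop = FALSE] * scale + norm[1]
  video_stack(pmax(out, 0),
              frame_interval = attr(stack, "frame_interval"),
              pixel_size = attr(stack, "pixel_size"))
}

# Simple bounded FIFO queue on a preallocated list.
fifo_new <- function(capacity) {
  env <- new.env(parent = emptyenv())
  env$buf <- vector("list", 0L)
  env$capacity <- capacity
  env
}
fifo_full <- function(q) length(q$buf) >= q$capacity
fifo_size <- function(q) length(q$buf)
fifo_push <- function(q, x) { q$buf[[length(q$buf) + 1L]] <- x; invisible(q) }
fifo_pop_n <- function(q, n) {
  out <- q$buf[seq_len(n)]
  q$buf <- q$buf[-seq_len(n)]
  out
}

#' Streaming FIFO denoising
#'
#' Reproduces the acquisition -> denoise -> display pipeline contract with
#' three cooperative stages connected by bounded first-in first-out queues:
#' an acquirer pulls frames from the source into the noisy queue, the denoiser
#' consumes blocks of C frames in arrival order, and an emitter releases
#' denoised frames in order. A full queue stalls the upstream stage
#' (back-pressure) rather than dropping frames; on shutdown all queues drain,
#' so `frames_out == frames_in` and output order equals input order. If the
#' source ends mid-window the final partial block is padded by repeating the
#' last frame (padding frames are never emitted; the event is flagged).
#'
#' With the default `shift_step = window_width` (non-overlapping blocks, the
#' lowest-latency mode) the emitted pixels are identical to
#' [denoise_stack()] at S = C. Overlap-averaged streaming (S < C) is available
#' at higher latency: a frame is emitted once all windows covering it have run.
#'
#' @param source a [video_stack()] / 3-D array replayed frame by frame, or a
#'   function `function()` returning the next H x W frame (`NULL` when
#'   exhausted).
#' @param model a `fast_denoiser` fit (or forward function, as in
#'   [denoise_stack()]).
#' @param window_width block size C; defaults to the model's channel count.
#' @param shift_step stride S between processed windows; default C.
#' @param capacity noisy-queue capacity in frames (`>= window_width`).
#' @param out_capacity denoised-queue capacity in frames.
#' @param emit_per_tick frames the display stage consumes per scheduling tick
#'   (use a small value to emulate a slow consumer); default `Inf`.
#' @return A list: `frames` (denoised [video_stack()]), `stats` (a
#'   `stream_stats` list: frames_in, frames_out, producer_stalls,
#'   denoiser_stalls, queue high-water marks, per-frame latency in ms,
#'   throughput over the steady-state middle 80 percent, tail_padded flag).
#' @export
stream_denoise <- function(source, model, window_width = NULL,
                           shift_step = NULL, capacity = NULL,
                           out_capacity = NULL, emit_per_tick = Inf) {
  C <- as.integer(window_width %||% model_channels(model, 16L))
  S <- as.integer(shift_step %||% C)
  if (S < 1L || S > C) stop("shift_step must satisfy 1 <= S <= C")
  capacity <- as.integer(capacity %||% (2L * C))
  if (capacity < C) stop("capacity must be >= window_width")
  out_capacity <- as.integer(out_capacity %||% (4L * C))
  if (is.finite(emit_per_tick) && emit_per_tick < 1)
    stop("emit_per_tick must be >= 1")

  if (!is.function(source)) {
    a <- as_stack_array(source)
    nsrc <- dim(a)[3]
    srci <- 0L
    pull <- function() {
      if (srci >= nsrc) return(NULL)
      srci <<- srci + 1L
      a[, , srci]
    }
  } else pull <- source

  norm <- model_norm(model)
  scale <- if (norm[2] - norm[1] > 0) norm[2] - norm[1] else 1

  inq <- fifo_new(capacity)    # acquired (noisy) frames not yet consumed
  outq <- fifo_new(out_capacity)
  emitted <- list()
  t_acq <- numeric(0)          # wall-clock acquire time per input frame
  t_emit <- numeric(0)
  frames_in <- 0L
  frames_out <- 0L
  producer_stalls <- 0L
  denoiser_stalls <- 0L
  hw_in <- 0L; hw_out <- 0L
  exhausted <- FALSE
  tail_padded <- FALSE
  next_start <- 0L             # 0-based start of the next window to process
  consumed <- 0L               # frames dropped from the head of inq so far
  # overlap bookkeeping: accumulated outputs and remaining coverage per frame
  pend <- list()               # per pending frame: list(acc, remaining)
  pend_base <- 0L              # frame index (0-based) of pend[[1]]
  plan_cov <- NULL

  finalize_ready <- function() {
    while (length(pend) > 0L && pend[[1L]]$remaining == 0L) {
      if (fifo_full(outq)) return(TRUE)   # display back-pressure
      fifo_push(outq, pend[[1L]]$acc)
      pend[[1L]] <<- NULL
      pend_base <<- pend_base + 1L
      hw_out <<- max(hw_out, fifo_size(outq))
    }
    FALSE
  }

  repeat {
    progressed <- FALSE
    # --- emit stage (drain first so queues free up) ---
    n_emit <- min(fifo_size(outq),
                  if (is.finite(emit_per_tick)) as.integer(emit_per_tick)
                  else fifo_size(outq))
    if (n_emit > 0L) {
      for (f in fifo_pop_n(outq, n_emit)) {
        frames_out <- frames_out + 1L
        emitted[[frames_out]] <- f
        t_emit[frames_out] <- as.numeric(Sys.time()) * 1000
      }
      progressed <- TRUE
    }
    finalize_ready()   # move any completed frames into the freed queue slots
    # --- denoise stage ---
    avail_end <- frames_in          # frames acquired so far (0-based exclusive)
    want_end <- next_start + C
    can_run <- (avail_end >= want_end) ||
      (exhausted && next_start < frames_in && frames_in > 0L)
    if (can_run) {
      blocked <- finalize_ready()
      # require room in pend/out path before running to keep memory bounded
      if (!blocked) {
        idx0 <- next_start; idx1 <- next_start + C - 1L
        frames <- vector("list", C)
        for (k in 0:(C - 1L)) {
          fi <- idx0 + k
          if (fi < frames_in) {
            frames[[k + 1L]] <- inq$buf[[fi - consumed + 1L]]
          } else {
            frames[[k + 1L]] <- inq$buf[[frames_in - consumed]]  # repeat last
            tail_padded <- TRUE
          }
        }
        d2 <- dim(frames[[1L]])
        block <- array(unlist(frames), c(d2[1], d2[2], C))
        bn <- (block - norm[1]) / scale
        pad <- reflect_pad4(bn)
        y <- model_forward_eval(model, pad$a)
        y <- y[seq_len(pad$H), seq_len(pad$W), , drop = FALSE] * scale + norm[1]
        y <- pmax(y, 0)
        # fold into pending coverage
        for (k in 0:(C - 1L)) {
          fi <- idx0 + k
          if (fi >= frames_in) break        # padding frames are discarded
          pi <- fi - pend_base + 1L
          while (length(pend) < pi) {
            nf <- pend_base + length(pend)  # 0-based frame index of new entry
            pend[[length(pend) + 1L]] <-
              list(acc = 0, remaining = cov_total(nf, C, S))
          }
          w <- 1 / cov_total(fi, C, S)
          pend[[pi]]$acc <- pend[[pi]]$acc + y[, , k + 1L] * w
          pend[[pi]]$remaining <- pend[[pi]]$remaining - 1L
        }
        next_start <- next_start + S
        # frames before the next window start are no longer needed upstream
        drop_to <- min(next_start, frames_in)
        if (drop_to > consumed) {
          fifo_pop_n(inq, drop_to - consumed)
          consumed <- drop_to
        }
        finalize_ready()
        progressed <- TRUE
      } else denoiser_stalls <- denoiser_stalls + 1L
    }
    # --- acquire stage: the producer pulls as fast as the queue admits ---
    if (!exhausted) {
      while (!exhausted && !fifo_full(inq)) {
        fr <- pull()
        if (is.null(fr)) {
          exhausted <- TRUE
        } else {
          frames_in <- frames_in + 1L
          fifo_push(inq, fr)
          t_acq[frames_in] <- as.numeric(Sys.time()) * 1000
          hw_in <- max(hw_in, fifo_size(inq))
          progressed <- TRUE
        }
      }
      if (!exhausted && fifo_full(inq))
        producer_stalls <- producer_stalls + 1L
    }
    done <- exhausted && frames_out == frames_in &&
      (frames_in == 0L || next_start >= frames_in)
    if (done) break
    if (!progressed && exhausted && next_start >= frames_in &&
        fifo_size(outq) == 0L && length(pend) == 0L)
      break  # safety: nothing left to do
  }

  lat <- t_emit[seq_len(frames_out)] - t_acq[seq_len(frames_out)]
  mid <- if (frames_out >= 10L) {
    lo <- floor(frames_out * 0.1) + 1L; hi <- ceiling(frames_out * 0.9)
    (t_emit[hi] - t_acq[lo])
  } else if (frames_out > 0L) t_emit[frames_out] - t_acq[1L] else NA_real_
  thr <- if (!is.na(mid) && mid > 0) 1000 * frames_out * 0.8 / mid else NA_real_
  stats <- structure(list(
    frames_in = frames_in, frames_out = frames_out,
    producer_stalls = producer_stalls, denoiser_stalls = denoiser_stalls,
    queue_high_water = c(noisy = hw_in, denoised = hw_out),
    latency_ms = lat, throughput_fps = thr, tail_padded = tail_padded
  ), class = "stream_stats")
  d2 <- if (frames_out > 0L) dim(emitted[[1L]]) else c(0L, 0L)
  frames <- if (frames_out > 0L)
    video_stack(array(unlist(emitted), c(d2[1], d2[2], frames_out)))
  else NULL
  list(frames = frames, stats = stats)
}

# Number of stream windows (starts at multiples of S) covering frame fi
# (0-based). Every such window runs before fi is finalized, so this both
# weights the overlap average and counts down to emission.
cov_total <- function(fi, C, S) {
  starts <- seq.int(0L, fi, by = S)
  sum(starts > fi - C)
}

#' @export
print.stream_stats <- function(x, ...) {
  cat(sprintf("stream: %d frames in, %d out; stalls: producer %d, denoiser %d\n",
              x$frames_in, x$frames_out, x$producer_stalls, x$denoiser_stalls))
  cat(sprintf("  queue high-water: noisy %d, denoised %d; throughput %.1f fps\n",
              x$queue_high_water[1], x$queue_high_water[2], x$throughput_fps))
  if (x$tail_padded) cat("  note: final partial window padded with last frame\n")
  invisible(x)
}
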