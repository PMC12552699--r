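#' Sampler configuration for spatiotemporal training pairs
#'
#' Training pairs are built by sliding a temporal window of width `window_width`
#' (C frames) along the stack with shift step `shift_step` (S frames): the i-th
#' pair is the window starting at frame i*S (input X_i) and the window starting
#' at frame i*S + S (target Y_i). Each pair is then split spatially into two
#' half-resolution views by seeded 2x2 mask-cell subsampling (see
#' [build_mask_pool()]).
#'
#' @param window_width temporal window width C in frames; must be even (the
#'   grouped convolutions process channels in pairs). Default 16.
#' @param shift_step temporal shift step S in frames, `1 <= S <= C`. S trades
#'   temporal separation of input and target (hence denoising strength on slow
#'   signals) against fidelity to fast transients. Default 8 (= C/2).
#' @param seed master integer seed for mask-field draws. Default 123.
#' @param subsample_mode `"mean2"` (average the two selected pixels of each 2x2
#'   block; default) or `"single_pixel"` (take only the first selected pixel).
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(window_width = 16L, shift_step = 8L, seed = 123L,
                           subsample_mode = c("mean2", "single_pixel")) {
  window_width <- as.integer(window_width)
  shift_step <- as.integer(shift_step)
  subsample_mode <- match.arg(subsample_mode)
  if (window_width < 2L || window_width %% 2L != 0L)
    stop("window_width (C) must be a positive even integer")
  if (shift_step < 1L || shift_step > window_width)
    stop("shift_step (S) must satisfy 1 <= S <= C (got S = ", shift_step,
         ", C = ", window_width, ")")
  structure(list(window_width = window_width, shift_step = shift_step,
                 seed = as.integer(seed), subsample_mode = subsample_mode),
            class = "sampler_config")
}

#' Plan the temporal sliding-window training pairs
#'
#' Enumerates all (X_i, Y_i) window pairs for a stack of `n_frames` frames:
#' pair i (0-based) has `x_start = i*S` and `y_start = i*S + S`, both 0-based,
#' half-open windows of C frames, subject to `y_start + C <= n_frames`.
#'
#' @param n_frames number of frames T in the stack.
#' @param config a [sampler_config()].
#' @return A data.frame with columns `index`, `x_start`, `y_start` (all
#'   0-based), one row per pair, in increasing order.
#' @examples
#' plan_windows(10, sampler_config(window_width = 4, shift_step = 2))
#' @export
plan_windows <- function(n_frames, config) {
  stopifnot(inherits(config, "sampler_config"))
  C <- config$window_width; S <- config$shift_step
  n_frames <- as.integer(n_frames)
  if (n_frames < C + S)
    stop("stack too short for one training pair: need at least C + S = ",
         C + S, " frames, got ", n_frames)
  n <- (n_frames - C - S) %/% S + 1L
  i <- seq_len(n) - 1L
  data.frame(index = i, x_start = i * S, y_start = i * S + S)
}

# The six distinct 2x2 binary matrices with exactly two ones, in a fixed
# documented order. Complement pairs: 1<->2 (rows), 3<->4 (columns),
# 5<->6 (diagonals). Positions are (row, col) offsets within a block, 0-based.
mask_cell_offsets <- function() {
  list(
    rbind(c(0L, 0L), c(0L, 1L)),  # 1: top row
    rbind(c(1L, 0L), c(1L, 1L)),  # 2: bottom row
    rbind(c(0L, 0L), c(1L, 0L)),  # 3: left column
    rbind(c(0L, 1L), c(1L, 1L)),  # 4: right column
    rbind(c(0L, 0L), c(1L, 1L)),  # 5: main diagonal
    rbind(c(0L, 1L), c(1L, 0L))   # 6: anti-diagonal
  )
}

mask_complement <- c(2L, 1L, 4L, 3L, 6L, 5L)

cell_matrix <- function(idx) {
  m <- matrix(0L, 2L, 2L)
  off <- mask_cell_offsets()[[idx]]
  m[off + 1L] <- 1L
  m
}

#' The pool of complementary 2x2 mask-cell pairs
#'
#' Each mask cell is a 2x2 binary matrix with exactly two entries set to 1;
#' there are choose(4, 2) = 6 such matrices. The pool pairs every cell with its
#' complement, so within each 2x2 pixel block the two branches select disjoint
#' pixel pairs that together cover the block. Branch 1 of pair j uses cell j,
#' branch 2 its complement.
#'
#' @return A list of 6 elements, each `list(g1 = <2x2 0/1 matrix>, g2 = <2x2
#'   0/1 matrix>)` with `g1 + g2` the all-ones matrix.
#' @examples
#' pool <- build_mask_pool()
#' pool[[1]]$g1 + pool[[1]]$g2
#' @export
build_mask_pool <- function() {
  lapply(seq_len(6L), function(j)
    list(g1 = cell_matrix(j), g2 = cell_matrix(mask_complement[j])))
}

#' Draw the per-block mask field for one window pair
#'
#' For every non-overlapping 2x2 block of an H x W frame, draws one of the 6
#' complementary mask-cell pairs. The draw is a pure function of
#' `(H, W, pair_index, seed)`: the same pair always gets the same field (this
#' keeps spatial adjacency consistent between X_i and Y_i of a pair and across
#' epochs), while different pairs get independent fields.
#'
#' @param H,W even spatial dimensions of the window.
#' @param pair_index 0-based index of the window pair the field belongs to.
#' @param seed master sampling seed.
#' @return An object of class `mask_field`: list with `pool_index` (an
#'   (H/2) x (W/2) integer matrix of values in 1..6), `H`, `W`, `pair_index`,
#'   `seed`.
#' @export
draw_mask_field <- function(H, W, pair_index, seed) {
  H <- as.integer(H); W <- as.integer(W)
  if (H %% 2L != 0L || W %% 2L != 0L)
    stop("spatial dimensions must be even (crop odd trailing row/column first)")
  nb <- (H %/% 2L) * (W %/% 2L)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(sub_seed(seed, 101L, pair_index))
  pool_index <- matrix(sample.int(6L, nb, replace = TRUE), H %/% 2L, W %/% 2L)
  structure(list(pool_index = pool_index, H = H, W = W,
                 pair_index = as.integer(pair_index), seed = as.integer(seed)),
            class = "mask_field")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(value) {
  if (is.null(value)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", value, envir = globalenv())
  invisible(NULL)
}

# Linear (column-major, 1-based) indices into an H x W frame of the two pixels
# selected by the given branch in every block, ordered block-column-major so
# the result maps directly onto an (H/2) x (W/2) output.
field_indices <- function(field, branch) {
  stopifnot(inherits(field, "mask_field"), branch %in% c(1L, 2L))
  offs <- mask_cell_offsets()
  cell_idx <- field$pool_index
  if (branch == 2L) cell_idx <- matrix(mask_complement[cell_idx], nrow(cell_idx))
  Hh <- nrow(cell_idx); Wh <- ncol(cell_idx)
  u <- rep(seq_len(Hh), times = Wh)        # block row
  v <- rep(seq_len(Wh), each = Hh)         # block col
  base_r <- 2L * u - 1L; base_c <- 2L * v - 1L
  ci <- as.vector(cell_idx)
  dr1 <- vapply(offs, function(o) o[1, 1], integer(1))[ci]
  dc1 <- vapply(offs, function(o) o[1, 2], integer(1))[ci]
  dr2 <- vapply(offs, function(o) o[2, 1], integer(1))[ci]
  dc2 <- vapply(offs, function(o) o[2, 2], integer(1))[ci]
  H <- field$H
  list(i1 = (base_r + dr1) + (base_c + dc1 - 1L) * H,
       i2 = (base_r + dr2) + (base_c + dc2 - 1L) * H)
}

#' Spatial 2x2 subsampling of a window
#'
#' Applies one branch of the mask field to every frame of an H x W x C window:
#' the output pixel at block (u, v) is the average of the two window pixels
#' selected by that block's branch cell (a stride-2 sparse convolution with a
#' two-one 2x2 kernel, weights 0.5/0.5). With `mode = "single_pixel"` only the
#' first selected pixel is taken (no averaging).
#'
#' @param window numeric H x W x C array (a 2-D matrix is treated as C = 1).
#' @param field a [draw_mask_field()] result matching the window's spatial dims.
#' @param branch 1 or 2, selecting the G1 or G2 cell of each block.
#' @param mode `"mean2"` or `"single_pixel"`.
#' @return An (H/2) x (W/2) x C array.
#' @export
subsample <- function(window, field, branch, mode = c("mean2", "single_pixel")) {
  mode <- match.arg(mode)
  if (is.matrix(window)) window <- array(window, c(dim(window), 1L))
  d <- dim(window)
  if (d[1] != field$H || d[2] != field$W)
    stop("window spatial dimensions (", d[1], " x ", d[2],
         ") do not match mask field (", field$H, " x ", field$W, ")")
  idx <- field_indices(field, as.integer(branch))
  wm <- matrix(window, d[1] * d[2], d[3])
  out <- if (mode == "mean2")
    (wm[idx$i1, , drop = FALSE] + wm[idx$i2, , drop = FALSE]) / 2
  else
    wm[idx$i1, , drop = FALSE]
  array(out, c(d[1] %/% 2L, d[2] %/% 2L, d[3]))
}

#' Materialize one spatiotemporally subsampled training pair
#'
#' Slices the input window X_i and target window Y_i from the stack, draws the
#' pair's mask field (a pure function of the pair index and the config seed),
#' and subsamples X_i with branch 1 and Y_i with branch 2. Because both windows
#' share one field, G1(X_i) and G2(Y_i) occupy corresponding block positions and
#' their source pixels are spatially adjacent within each block.
#'
#' Odd trailing rows/columns are cropped before subsampling (training only;
#' inference operates on full frames).
#'
#' @param stack a [video_stack()] or 3-D array.
#' @param pair one row of [plan_windows()] (or a list with `index`, `x_start`,
#'   `y_start`, 0-based).
#' @param config a [sampler_config()].
#' @return A list of class `subsampled_pair`: `x_window`, `y_window` (H x W x C),
#'   `g1_x`, `g2_y` ((H/2) x (W/2) x C), `mask_field`, `index`.
#' @export
make_training_pair <- function(stack, pair, config) {
  stopifnot(inherits(config, "sampler_config"))
  a <- as_stack_array(stack)
  d <- dim(a)
  C <- config$window_width
  x0 <- as.integer(pair$x_start); y0 <- as.integer(pair$y_start)
  if (y0 != x0 + config$shift_step)
    stop("invalid window pair: y_start must equal x_start + shift_step")
  if (y0 + C > d[3])
    stop("window pair extends past the end of the stack")
  H <- d[1] - d[1] %% 2L
  W <- d[2] - d[2] %% 2L
  xw <- a[seq_len(H), seq_len(W), (x0 + 1L):(x0 + C), drop = FALSE]
  yw <- a[seq_len(H), seq_len(W), (y0 + 1L):(y0 + C), drop = FALSE]
  field <- draw_mask_field(H, W, pair$index, config$seed)
  structure(list(
    x_window = xw, y_window = yw,
    g1_x = subsample(xw, field, 1L, config$subsample_mode),
    g2_y = subsample(yw, field, 2L, config$subsample_mode),
    mask_field = field, index = as.integer(pair$index),
    subsample_mode = config$subsample_mode
  ), class = "subsampled_pair")
}
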