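#' Single-channel fluorescence time-lapse stack
#'
#' A `video_stack` wraps a 3-D intensity array (height x width x frames) with
#' optional physical sampling metadata. All downstream functions (training,
#' inference, evaluation) accept either a `video_stack` or a bare 3-D array.
#'
#' @param pixels numeric 3-D array, height x width x frames. All values must be
#'   finite and non-negative.
#' @param frame_interval milliseconds per frame, or `NULL` if unknown.
#' @param pixel_size micrometres per pixel, or `NULL` if unknown.
#' @return An object of class `video_stack`: the pixel array with attributes
#'   `frame_interval` and `pixel_size`.
#' @examples
#' vs <- video_stack(array(runif(16 * 16 * 5), c(16, 16, 5)), frame_interval = 33.3)
#' dim(vs)
#' @export
video_stack <- function(pixels, frame_interval = NULL, pixel_size = NULL) {
  if (inherits(pixels, "video_stack")) {
    if (!is.null(frame_interval)) attr(pixels, "frame_interval") <- frame_interval
    if (!is.null(pixel_size)) attr(pixels, "pixel_size") <- pixel_size
    return(pixels)
  }
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("pixels must be a 3-D array (height x width x frames)")
  d <- dim(pixels)
  if (d[1] < 2L || d[2] < 2L || d[3] < 1L)
    stop("stack must be at least 2 x 2 x 1")
  if (!all(is.finite(pixels)))
    stop("all intensities must be finite")
  if (min(pixels) < 0)
    stop("all intensities must be non-negative")
  structure(pixels,
            frame_interval = frame_interval,
            pixel_size = pixel_size,
            class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<video_stack> %d x %d pixels, %d frames\n", d[1], d[2], d[3]))
  fi <- attr(x, "frame_interval")
  if (!is.null(fi)) cat(sprintf("  frame interval: %g ms (%.1f Hz)\n", fi, 1000 / fi))
  ps <- attr(x, "pixel_size")
  if (!is.null(ps)) cat(sprintf("  pixel size: %g um\n", ps))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

as_stack_array <- function(stack) {
  if (inherits(stack, "video_stack")) {
    a <- unclass(stack)
    attr(a, "frame_interval") <- NULL
    attr(a, "pixel_size") <- NULL
    return(a)
  }
  if (is.array(stack) && length(dim(stack)) == 3L) return(stack)
  stop("expected a video_stack or a 3-D array")
}
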