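#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in decibels; `Inf` when the arrays are
#' identical.
#'
#' @param reference,test equal-shape numeric arrays.
#' @param data_range peak-to-peak intensity range of the reference signal;
#'   defaults to `max(reference) - min(reference)`.
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0, 4, 4), matrix(0.1, 4, 4), data_range = 1)  # 20 dB
#' @export
psnr <- function(reference, test, data_range = NULL) {
  if (length(reference) != length(test))
    stop("shape mismatch between reference and test")
  data_range <- data_range %||% (max(reference) - min(reference))
  if (data_range <= 0) stop("data_range must be > 0")
  mse <- mean((as.numeric(reference) - as.numeric(test))^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

gaussian_kernel1d <- function(size = 7L, sigma = 1.5) {
  t <- seq_len(size) - (size + 1) / 2
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable valid-region weighted filtering of a matrix with a 1-D kernel.
sep_filter_valid <- function(m, k) {
  n <- length(k)
  H <- nrow(m); W <- ncol(m)
  Ho <- H - n + 1L; Wo <- W - n + 1L
  out <- matrix(0, Ho, W)
  for (i in seq_len(n)) out <- out + k[i] * m[i:(i + Ho - 1L), , drop = FALSE]
  out2 <- matrix(0, Ho, Wo)
  for (j in seq_len(n)) out2 <- out2 + k[j] * out[, j:(j + Wo - 1L), drop = FALSE]
  out2
}

ssim_frame <- function(x, y, data_range, k1 = 0.01, k2 = 0.03,
                       win_size = 7L, sigma = 1.5) {
  g <- gaussian_kernel1d(win_size, sigma)
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  mu1 <- sep_filter_valid(x, g)
  mu2 <- sep_filter_valid(y, g)
  s11 <- sep_filter_valid(x * x, g) - mu1 * mu1
  s22 <- sep_filter_valid(y * y, g) - mu2 * mu2
  s12 <- sep_filter_valid(x * y, g) - mu1 * mu2
  num <- (2 * mu1 * mu2 + c1) * (2 * s12 + c2)
  den <- (mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)
  mean(num / den)
}

#' Structural similarity index
#'
#' Windowed SSIM with a 7 x 7 Gaussian weighting window (sigma 1.5) and the
#' standard stabilizers k1 = 0.01, k2 = 0.03, averaged over all valid window
#' positions; for 3-D input, additionally averaged over frames. Local
#' statistics use the Gaussian-weighted mean/variance/covariance of the two
#' images.
#'
#' @param reference,test equal-shape 2-D or 3-D numeric arrays, at least
#'   7 x 7 spatially.
#' @param data_range intensity range; defaults to the reference's range.
#' @return SSIM in `[-1, 1]` (1 for identical images).
#' @export
ssim <- function(reference, test, data_range = NULL) {
  if (!identical(dim(reference), dim(test)))
    stop("shape mismatch between reference and test")
  data_range <- data_range %||% (max(reference) - min(reference))
  if (data_range <= 0) stop("data_range must be > 0")
  if (is.matrix(reference)) {
    reference <- array(reference, c(dim(reference), 1L))
    test <- array(test, c(dim(test), 1L))
  }
  d <- dim(reference)
  if (d[1] < 7L || d[2] < 7L) stop("images smaller than the 7 x 7 window")
  vals <- vapply(seq_len(d[3]), function(t)
    ssim_frame(reference[, , t], test[, , t], data_range), numeric(1))
  mean(vals)
}

#' Extract fractional-fluorescence (delta F over F) traces from ROIs
#'
#' For each region of interest, `F(t)` is the mean intensity over the ROI per
#' frame and `dF/F = (F - F0) / max(F0, eps)` where the baseline `F0` is by
#' default the 10th percentile of `F` over time (robust to activity).
#'
#' @param stack a [video_stack()] or 3-D array.
#' @param rois a list of ROIs, each either a 2-column (row, col) index matrix
#'   or a logical H x W mask.
#' @param baseline_method `"percentile"` (default), `"mean"`, or `"min"`.
#' @param percentile baseline percentile when `baseline_method = "percentile"`;
#'   default 0.10.
#' @param eps positive floor for F0; default 1e-6.
#' @return A list of class `trace_set`: `dff` (T x n_roi matrix), `f` (raw
#'   mean-intensity traces), `f0` (baselines), `baseline_method`.
#' @export
extract_dff <- function(stack, rois, baseline_method = c("percentile", "mean",
                                                         "min"),
                        percentile = 0.10, eps = 1e-6) {
  baseline_method <- match.arg(baseline_method)
  a <- as_stack_array(stack)
  d <- dim(a)
  am <- matrix(a, d[1] * d[2], d[3])
  if (!is.list(rois)) rois <- list(rois)
  f <- vapply(rois, function(r) {
    lin <- if (is.logical(r)) which(r)
           else if (is.matrix(r) && ncol(r) == 2L) r[, 1] + (r[, 2] - 1L) * d[1]
           else as.integer(r)
    if (length(lin) == 0L) stop("empty ROI")
    if (min(lin) < 1L || max(lin) > d[1] * d[2]) stop("ROI out of bounds")
    colMeans(am[lin, , drop = FALSE])
  }, numeric(d[3]))
  f <- matrix(f, nrow = d[3])
  f0 <- switch(baseline_method,
               percentile = apply(f, 2L, quantile, probs = percentile,
                                  names = FALSE),
               mean = colMeans(f),
               min = apply(f, 2L, min))
  f0 <- pmax(f0, eps)
  dff <- sweep(sweep(f, 2L, f0, "-"), 2L, f0, "/")
  structure(list(dff = dff, f = f, f0 = f0,
                 baseline_method = baseline_method),
            class = "trace_set")
}

#' Pearson correlation between matched trace sets
#'
#' @param traces_a,traces_b T x n matrices (or `trace_set`s) with matching
#'   dimensions; column j of each is compared.
#' @return Numeric vector of per-trace Pearson r; `NA` where either trace is
#'   constant (undefined correlation).
#' @export
trace_correlation <- function(traces_a, traces_b) {
  ta <- if (inherits(traces_a, "trace_set")) traces_a$dff else as.matrix(traces_a)
  tb <- if (inherits(traces_b, "trace_set")) traces_b$dff else as.matrix(traces_b)
  if (nrow(ta) != nrow(tb) || ncol(ta) != ncol(tb))
    stop("trace length/count mismatch")
  vapply(seq_len(ncol(ta)), function(j) {
    if (sd(ta[, j]) == 0 || sd(tb[, j]) == 0) return(NA_real_)
    cor(ta[, j], tb[, j])
  }, numeric(1))
}

#' Temporal boxcar smoothing (naive denoising control)
#'
#' Centered moving average of each pixel over `width` frames (edges use the
#' available frames). Used as the classical control that suppresses noise but
#' also destroys fast transients.
#'
#' @param stack a [video_stack()] or 3-D array.
#' @param width odd window width in frames; default 9.
#' @return A smoothed array of the same shape.
#' @export
boxcar_smooth <- function(stack, width = 9L) {
  a <- as_stack_array(stack)
  d <- dim(a)
  width <- as.integer(width)
  half <- width %/% 2L
  am <- matrix(a, d[1] * d[2], d[3])
  cs <- cbind(0, t(apply(am, 1L, cumsum)))
  out <- matrix(0, d[1] * d[2], d[3])
  for (t in seq_len(d[3])) {
    lo <- max(1L, t - half); hi <- min(d[3], t + half)
    out[, t] <- (cs[, hi + 1L] - cs[, lo]) / (hi - lo + 1L)
  }
  array(out, d)
}
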