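#' Patch specification for the intensity-trend penalty
#'
#' The patch-mean operator P averages intensity over `n_regions` randomly
#' placed square patches (20 x 20 pixels by default). Patch locations are a
#' pure function of the seed and the image size, so applying the same spec to
#' prediction and target yields co-located patches. For images smaller than the
#' nominal patch the size is clipped to `min(patch_size, H, W)`.
#'
#' @param patch_size patch side length in pixels; default 20.
#' @param n_regions number of patches; default 10.
#' @param seed integer seed for patch placement.
#' @return A list of class `patch_spec`.
#' @export
patch_spec <- function(patch_size = 20L, n_regions = 10L, seed = 123L) {
  patch_size <- as.integer(patch_size)
  n_regions <- as.integer(n_regions)
  if (patch_size < 1L) stop("patch_size must be >= 1")
  if (n_regions < 1L) stop("n_regions must be >= 1")
  structure(list(patch_size = patch_size, n_regions = n_regions,
                 seed = as.integer(seed)),
            class = "patch_spec")
}

# Top-left corners (1-based) of the patches for an H x W image.
patch_corners <- function(H, W, spec) {
  ps <- min(spec$patch_size, H, W)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(sub_seed(spec$seed, 707L))
  r0 <- sample.int(H - ps + 1L, spec$n_regions, replace = TRUE)
  c0 <- sample.int(W - ps + 1L, spec$n_regions, replace = TRUE)
  list(r0 = r0, c0 = c0, ps = ps)
}

#' Mean intensity over randomly placed patches
#'
#' Returns the arithmetic mean over each of the spec's patches; for a 3-D input
#' each patch mean is additionally averaged over all frames (the operator
#' tracks intensity trends of the whole window).
#'
#' @param image 2-D matrix or 3-D array.
#' @param spec a [patch_spec()].
#' @return Numeric vector of length `spec$n_regions`.
#' @export
patch_means <- function(image, spec) {
  stopifnot(inherits(spec, "patch_spec"))
  if (length(image) == 0) stop("empty image")
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  pc <- patch_corners(d[1], d[2], spec)
  vapply(seq_len(spec$n_regions), function(j) {
    mean(image[pc$r0[j]:(pc$r0[j] + pc$ps - 1L),
               pc$c0[j]:(pc$c0[j] + pc$ps - 1L), , drop = FALSE])
  }, numeric(1))
}

#' Scale self-constraining loss
#'
#' Mean squared difference between the prediction on the subsampled input,
#' f(G1(X_i)), and the subsampled prediction on the full input, G1(f(X_i)).
#' The second argument is treated as a constant: no gradient flows through it
#' during fitting.
#'
#' @param pred_half f(G1(X_i)), an (H/2) x (W/2) x C array.
#' @param full_pred_subsampled G1(f(X_i)), same shape, gradient-free.
#' @return Non-negative scalar; 0 iff the arguments are equal.
#' @export
loss_sc <- function(pred_half, full_pred_subsampled) {
  if (!identical(dim(pred_half), dim(full_pred_subsampled)) &&
      length(pred_half) != length(full_pred_subsampled))
    stop("shape mismatch between f(G1(X)) and G1(f(X))")
  mean((pred_half - full_pred_subsampled)^2)
}

#' Spatiotemporal self-supervising loss
#'
#' Mean squared pixel difference between f(G1(X_i)) and the subsampled target
#' G2(Y_i), plus the L1 distance between their patch means (mean over the
#' spec's regions), which constrains slow intensity trends.
#'
#' @param pred_half f(G1(X_i)).
#' @param target_half G2(Y_i), same shape.
#' @param spec a [patch_spec()] applied identically to both arguments; `NULL`
#'   drops the patch term (plain MSE).
#' @return Non-negative scalar; 0 when prediction equals target.
#' @export
loss_st <- function(pred_half, target_half, spec = patch_spec()) {
  if (length(pred_half) != length(target_half))
    stop("shape mismatch between prediction and target")
  pixel <- mean((pred_half - target_half)^2)
  if (is.null(spec)) return(pixel)
  pm <- patch_means(pred_half, spec)
  tm <- patch_means(target_half, spec)
  pixel + mean(abs(pm - tm))
}

# Gradient of loss_st + loss_sc w.r.t. pred_half. All reductions are means, so
# the pixel terms contribute 2*(diff)/n and each patch contributes
# sign(diff_j)/(n_regions * patch_elements) over its support (overlapping
# patches accumulate).
loss_grad_pred <- function(pred_half, target_half, sc_target, spec) {
  n <- length(pred_half)
  g <- 2 * (pred_half - target_half) / n + 2 * (pred_half - sc_target) / n
  if (!is.null(spec)) {
    d <- dim(pred_half)
    pc <- patch_corners(d[1], d[2], spec)
    pm <- patch_means(pred_half, spec)
    tm <- patch_means(target_half, spec)
    sgn <- sign(pm - tm)
    per_el <- 1 / (spec$n_regions * pc$ps * pc$ps * d[3])
    for (j in seq_len(spec$n_regions)) {
      if (sgn[j] == 0) next
      ri <- pc$r0[j]:(pc$r0[j] + pc$ps - 1L)
      ci <- pc$c0[j]:(pc$c0[j] + pc$ps - 1L)
      g[ri, ci, ] <- g[ri, ci, ] + sgn[j] * per_el
    }
  }
  g
}

#' Evaluate the total self-supervised objective on one training pair
#'
#' Runs the network on G1(X_i) (the gradient path) and on the full window X_i
#' (stop-gradient path, used only to form the scale-consistency target
#' G1(f(X_i))), then assembles the two loss terms.
#'
#' @param sample a [make_training_pair()] result.
#' @param model a `fast_network` or `fast_denoiser`.
#' @param spec a [patch_spec()], or `NULL` to drop the patch-mean term.
#' @param training evaluate the network with per-window batch statistics
#'   (matching the fitting procedure)? Default `TRUE`.
#' @return A list of class `loss_report` with elements `l_sc`, `l_st`,
#'   `l_total` (`l_total = l_sc + l_st`).
#' @export
total_loss <- function(sample, model, spec = patch_spec(), training = TRUE) {
  r <- total_loss_impl(sample, model, spec, training, want_grad = FALSE)
  structure(r[c("l_sc", "l_st", "l_total")], class = "loss_report")
}

total_loss_impl <- function(sample, model, spec, training, want_grad,
                            update_running = FALSE) {
  if (inherits(model, "fast_denoiser")) model <- model$net
  stopifnot(inherits(model, "fast_network"), inherits(sample, "subsampled_pair"))
  fw_half <- net_forward_impl(model, sample$g1_x, training = training,
                              update_running = update_running)
  fw_full <- net_forward_impl(fw_half$net, sample$x_window, training = training,
                              update_running = update_running)
  sc_target <- subsample(fw_full$y, sample$mask_field, 1L,
                         sample$subsample_mode %||% "mean2")
  ph <- fw_half$y
  l_sc <- loss_sc(ph, sc_target)
  l_st <- loss_st(ph, sample$g2_y, spec)
  out <- list(l_sc = l_sc, l_st = l_st, l_total = l_sc + l_st,
              net = fw_full$net)
  if (want_grad) {
    gy <- loss_grad_pred(ph, sample$g2_y, sc_target, spec)
    out$grads <- net_backward(model, fw_half$cache, gy)
  }
  out
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("loss: total %.6g (scale-consistency %.6g + spatiotemporal %.6g)\n",
              x$l_total, x$l_sc, x$l_st))
  invisible(x)
}
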