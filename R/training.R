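# ---- dihedral augmentation --------------------------------------------------

# op in 0..7: op %% 4 counter-clockwise 90-degree rotations, preceded by a
# horizontal flip (column reversal) when op >= 4.
dihedral_3d <- function(a, op) {
  op <- as.integer(op)
  if (op >= 4L) a <- a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  k <- op %% 4L
  for (r in seq_len(k)) {
    a <- aperm(a, c(2L, 1L, 3L))                       # transpose
    a <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]  # then reverse rows = rot90 ccw
  }
  a
}

dihedral_matrix <- function(m, op) {
  a <- dihedral_3d(array(m, c(dim(m), 1L)), op)
  array(a, dim(a)[1:2])
}

# How each of the 6 mask cells maps under each dihedral op (computed once).
cell_transform_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    pool <- lapply(seq_len(6L), cell_matrix)
    t_ <- matrix(0L, 8L, 6L)
    for (op in 0:7) {
      for (j in seq_len(6L)) {
        m <- dihedral_matrix(pool[[j]], op)
        t_[op + 1L, j] <- which(vapply(pool, function(p) all(p == m), logical(1)))
      }
    }
    tab <<- t_
    tab
  }
})

#' Jointly augment a training pair by a dihedral symmetry
#'
#' Applies one of the 8 dihedral transforms (flips and 90-degree rotations),
#' drawn from `step_seed`, identically to the input window, target window, the
#' mask field, and the two subsampled views, so input/target geometry stays
#' aligned. Because spatial dimensions are even, 2x2 blocks map onto blocks and
#' the mask cells transform consistently: the augmented subsampled views equal
#' the subsampling of the augmented windows under the augmented field.
#'
#' @param pair a [make_training_pair()] result.
#' @param step_seed integer seed; the transform is `op = step_seed`-determined.
#'   Alternatively pass `op` directly to force a specific transform.
#' @param op optional explicit transform index in 0..7 (0 = identity),
#'   overriding the seeded draw.
#' @return A `subsampled_pair` with all components transformed.
#' @export
augment <- function(pair, step_seed = NULL, op = NULL) {
  stopifnot(inherits(pair, "subsampled_pair"))
  if (is.null(op)) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(sub_seed(step_seed %||% 0L, 505L))
    op <- sample.int(8L, 1L) - 1L
  }
  op <- as.integer(op)
  if (op == 0L) return(pair)
  field <- pair$mask_field
  tab <- cell_transform_table()
  new_pool <- dihedral_matrix(field$pool_index, op)
  new_pool <- matrix(tab[op + 1L, new_pool], nrow(new_pool))
  field$pool_index <- new_pool
  field$H <- 2L * nrow(new_pool)
  field$W <- 2L * ncol(new_pool)
  pair$x_window <- dihedral_3d(pair$x_window, op)
  pair$y_window <- dihedral_3d(pair$y_window, op)
  pair$g1_x <- dihedral_3d(pair$g1_x, op)
  pair$g2_y <- dihedral_3d(pair$g2_y, op)
  pair$mask_field <- field
  pair
}

# ---- optimizer --------------------------------------------------------------

adam_init <- function(params) {
  list(step = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       vhat = lapply(params, function(p) p * 0))
}

# ADAM with AMSGrad; weight decay added to the gradient (L2 regularization).
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    state$vhat[[nm]] <- pmax(state$vhat[[nm]], state$v[[nm]])
    mhat <- state$m[[nm]] / bc1
    vhat <- state$vhat[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' Defaults follow the method's standard recipe: 100 epochs, batch size 1,
#' ADAM with AMSGrad, learning rate 1e-4, weight decay 1e-4, master seed 123,
#' dihedral augmentation (random flips and 90-degree rotations).
#'
#' @param epochs number of passes over all window pairs.
#' @param learning_rate ADAM learning rate.
#' @param weight_decay L2 weight decay coefficient.
#' @param master_seed master integer seed for init, masks, augmentation and
#'   patch draws.
#' @param augment apply random dihedral augmentation?
#' @param patch_size,n_regions patch-mean penalty geometry (see [patch_spec()]).
#' @param patience stop early after this many epochs without improvement of
#'   the epoch-mean total loss; `Inf` (default) trains the full schedule.
#' @param verbose print per-epoch losses?
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, learning_rate = 1e-4,
                         weight_decay = 1e-4, master_seed = 123L,
                         augment = TRUE, patch_size = 20L, n_regions = 10L,
                         patience = Inf, verbose = FALSE) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  structure(list(epochs = epochs, batch = 1L, learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 master_seed = as.integer(master_seed),
                 augment = isTRUE(augment), patch_size = as.integer(patch_size),
                 n_regions = as.integer(n_regions), patience = patience,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# Shared training core over a corpus of (stack_array, plan) units.
# Each unit is one x-y-t stack; pairs are visited in index order within a
# stack, stack order shuffled per epoch when shuffle_units = TRUE.
train_core <- function(units, sampler, net, cfg, norm, shuffle_units = FALSE) {
  params <- net_param_list(net)
  state <- adam_init(params)
  history <- data.frame(epoch = integer(), l_sc = numeric(), l_st = numeric(),
                        l_total = numeric())
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    unit_order <- seq_along(units)
    if (shuffle_units && length(units) > 1L) {
      old <- .Random.seed_get()
      set.seed(sub_seed(cfg$master_seed, 303L, epoch))
      unit_order <- sample(unit_order)
      .Random.seed_set(old)
    }
    acc <- c(l_sc = 0, l_st = 0, l_total = 0); nacc <- 0L
    for (ui in unit_order) {
      unit <- units[[ui]]
      for (r in seq_len(nrow(unit$plan))) {
        step <- step + 1L
        pair_row <- unit$plan[r, ]
        samp_cfg <- sampler
        samp_cfg$seed <- sub_seed(sampler$seed, 11L, ui)
        pair <- make_training_pair(unit$stack, pair_row, samp_cfg)
        pair$x_window <- (pair$x_window - norm[1]) / (norm[2] - norm[1])
        pair$y_window <- (pair$y_window - norm[1]) / (norm[2] - norm[1])
        pair$g1_x <- (pair$g1_x - norm[1]) / (norm[2] - norm[1])
        pair$g2_y <- (pair$g2_y - norm[1]) / (norm[2] - norm[1])
        if (cfg$augment)
          pair <- augment(pair, step_seed = sub_seed(cfg$master_seed, 202L, step))
        spec <- patch_spec(cfg$patch_size, cfg$n_regions,
                           seed = sub_seed(cfg$master_seed, 404L, step))
        res <- total_loss_impl(pair, net, spec, training = TRUE,
                               want_grad = TRUE, update_running = TRUE)
        if (!is.finite(res$l_total))
          stop("non-finite loss at step ", step,
               " (l_sc = ", res$l_sc, ", l_st = ", res$l_st, "); aborting")
        net <- res$net   # carries updated batch-norm running statistics
        upd <- adam_step(params, res$grads, state, cfg$learning_rate,
                         cfg$weight_decay)
        params <- upd$params
        state <- upd$state
        net <- net_set_params(net, params)
        acc <- acc + c(res$l_sc, res$l_st, res$l_total)
        nacc <- nacc + 1L
      }
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         l_sc = acc[["l_sc"]] / nacc,
                                         l_st = acc[["l_st"]] / nacc,
                                         l_total = acc[["l_total"]] / nacc))
    if (cfg$verbose)
      message(sprintf("epoch %3d  l_sc %.5g  l_st %.5g  l_total %.5g",
                      epoch, history$l_sc[epoch], history$l_st[epoch],
                      history$l_total[epoch]))
    pat <- cfg$patience %||% Inf
    if (is.finite(pat) && nrow(history) > pat &&
        min(tail(history$l_total, pat)) >=
          min(head(history$l_total, nrow(history) - pat)))
      break
  }
  list(net = net, history = history)
}

#' Fit a self-supervised denoiser to a fluorescence time-lapse stack
#'
#' Trains the lightweight grouped-convolution encoder-decoder on training pairs
#' drawn from the noisy stack itself (no clean reference is ever used): the
#' stack is split into temporally shifted window pairs, each spatially
#' subsampled into two half-resolution views, and the network is optimized so
#' its output on one view predicts the other while staying scale-consistent
#' with its own full-resolution output. The stack is affinely normalized to
#' [0, 1] by its (min, max); the normalization is stored with the fit and
#' inverted at prediction time.
#'
#' @param stack a [video_stack()], a 3-D array, or a list of them (all stacks
#'   then train a single shared model).
#' @param window_width temporal window width C (even); default 16.
#' @param shift_step temporal shift step S, `1 <= S <= C`; default 8.
#' @param epochs number of training epochs; default 100.
#' @param learning_rate,weight_decay ADAM/AMSGrad settings; default 1e-4 each.
#' @param seed master seed controlling initialization, mask fields,
#'   augmentation and patch placement; default 123.
#' @param subsample_mode `"mean2"` or `"single_pixel"` (see [sampler_config()]).
#' @param augment apply random dihedral augmentation; default `TRUE`.
#' @param patch_size,n_regions intensity-trend penalty geometry; defaults 20, 10.
#' @param patience optional early stopping: epochs without improvement before
#'   halting; `Inf` (default) runs the full schedule.
#' @param verbose print per-epoch losses.
#' @return An object of class `fast_denoiser` with components `net` (the fitted
#'   network), `norm` (intensity normalization `c(min, max)`), `history`
#'   (per-epoch mean losses), `sampler`, `train_cfg`, and `call`. Use
#'   [predict.fast_denoiser()] to denoise stacks.
#' @seealso [denoise_stack()], [stream_denoise()], [total_loss()]
#' @export
fast_denoiser <- function(stack, window_width = 16L, shift_step = 8L,
                          epochs = 100L, learning_rate = 1e-4,
                          weight_decay = 1e-4, seed = 123L,
                          subsample_mode = "mean2", augment = TRUE,
                          patch_size = 20L, n_regions = 10L, patience = Inf,
                          verbose = FALSE) {
  cl <- match.call()
  stacks <- if (is.list(stack) && !is.array(stack)) stack else list(stack)
  stacks <- lapply(stacks, as_stack_array)
  sampler <- sampler_config(window_width, shift_step, seed = seed,
                            subsample_mode = subsample_mode)
  cfg <- train_config(epochs = epochs, learning_rate = learning_rate,
                      weight_decay = weight_decay, master_seed = seed,
                      augment = augment, patch_size = patch_size,
                      n_regions = n_regions, patience = patience,
                      verbose = verbose)
  for (s in stacks)
    if (dim(s)[3] < window_width + shift_step)
      stop("stack too short for one training pair: need at least C + S = ",
           window_width + shift_step, " frames, got ", dim(s)[3])
  rng <- range(unlist(lapply(stacks, range)))
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1  # constant stack: degenerate scale
  units <- lapply(stacks, function(s)
    list(stack = s, plan = plan_windows(dim(s)[3], sampler)))
  net <- build_model(network_config(in_out_channels = sampler$window_width),
                     init_seed = sub_seed(seed, 1L))
  # start from the mean-intensity map (see build_model's output init)
  corpus_mean <- mean(vapply(stacks, mean, numeric(1)) *
                        vapply(stacks, length, numeric(1))) /
    mean(vapply(stacks, length, numeric(1)))
  net$out$b <- rep((corpus_mean - rng[1]) / (rng[2] - rng[1]),
                   sampler$window_width)
  fit <- train_core(units, sampler, net, cfg, rng,
                    shuffle_units = length(units) > 1L)
  structure(list(net = fit$net, norm = rng, history = fit$history,
                 sampler = sampler, train_cfg = cfg, call = cl),
            class = "fast_denoiser")
}

#' Fit per-channel denoisers to a volumetric multi-channel series
#'
#' For volumetric time-lapse imaging (x-y-z-t per channel), each channel is
#' trained independently: the Z plane-wise x-y-t stacks of a channel jointly
#' form the training corpus of one shared model, with plane order shuffled per
#' epoch under the master seed.
#'
#' @param series a list with one element per channel, each an H x W x Z x T
#'   array (or a single such array for one channel).
#' @param ... arguments passed to [fast_denoiser()].
#' @return A list of `fast_denoiser` fits, one per channel.
#' @export
fast_denoiser_volumetric <- function(series, ...) {
  if (is.array(series) && length(dim(series)) == 4L) series <- list(series)
  stopifnot(is.list(series))
  lapply(series, function(chan) {
    if (!is.array(chan) || length(dim(chan)) != 4L)
      stop("each channel must be an H x W x Z x T array")
    d <- dim(chan)
    planes <- lapply(seq_len(d[3]), function(z) chan[, , z, , drop = TRUE])
    planes <- lapply(planes, function(p) array(p, c(d[1], d[2], d[4])))
    if (length(unique(vapply(planes, function(p) paste(dim(p), collapse = "x"),
                             character(1)))) != 1L)
      stop("inconsistent plane shapes")
    fast_denoiser(planes, ...)
  })
}

# ---- S3 methods -------------------------------------------------------------

#' @export
print.fast_denoiser <- function(x, ...) {
  cat("Self-supervised fluorescence denoiser\n")
  cat(sprintf("  window width C = %d, shift step S = %d, seed = %d\n",
              x$sampler$window_width, x$sampler$shift_step, x$sampler$seed))
  cat(sprintf("  %d trainable parameters (%.4f M), %d epochs\n",
              count_parameters(x$net), count_parameters(x$net) / 1e6,
              nrow(x$history)))
  cat(sprintf("  final loss: %.6g (scale-consistency %.6g + spatiotemporal %.6g)\n",
              tail(x$history$l_total, 1), tail(x$history$l_sc, 1),
              tail(x$history$l_st, 1)))
  invisible(x)
}

#' @export
summary.fast_denoiser <- function(object, ...) {
  h <- object$history
  cat("Self-supervised fluorescence denoiser\n\n")
  cat("Sampling: window width C =", object$sampler$window_width,
      ", shift step S =", object$sampler$shift_step,
      ", subsampling =", object$sampler$subsample_mode, "\n")
  cat("Network:", count_parameters(object$net), "trainable parameters (",
      sprintf("%.4f", count_parameters(object$net) / 1e6), "M )\n")
  cat("Intensity normalization: [", format(object$norm[1]), ",",
      format(object$norm[2]), "] -> [0, 1]\n")
  cat("Optimizer: ADAM + AMSGrad, lr", object$train_cfg$learning_rate,
      ", weight decay", object$train_cfg$weight_decay, "\n\n")
  cat("Loss history (first / mid / final epoch):\n")
  print(h[unique(c(1L, ceiling(nrow(h) / 2), nrow(h))), ], row.names = FALSE)
  invisible(object)
}

#' @export
coef.fast_denoiser <- function(object, ...) {
  net_param_list(object$net)
}

#' Denoise a stack with a fitted model
#'
#' @param object a `fast_denoiser` fit.
#' @param stack a [video_stack()] or 3-D array to denoise (defaults to
#'   requiring an explicit stack; the training stack is not stored).
#' @param shift_step inference stride S (defaults to the training shift step).
#' @param ... unused.
#' @return A denoised [video_stack()] of identical shape.
#' @export
predict.fast_denoiser <- function(object, stack, shift_step = NULL, ...) {
  denoise_stack(object, stack,
                shift_step = shift_step %||% object$sampler$shift_step)
}

#' @export
fitted.fast_denoiser <- function(object, stack, ...) {
  predict(object, stack, ...)
}

#' @export
residuals.fast_denoiser <- function(object, stack, ...) {
  a <- as_stack_array(stack)
  a - as_stack_array(predict(object, stack, ...))
}

#' @export
plot.fast_denoiser <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$l_total, h$l_sc, h$l_st), type = "l",
                    lty = 1, col = c("black", "steelblue", "firebrick"),
                    xlab = "epoch", ylab = "mean loss", ...)
  graphics::legend("topright", c("total", "scale-consistency", "spatiotemporal"),
                   lty = 1, col = c("black", "steelblue", "firebrick"),
                   bty = "n")
  invisible(x)
}
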