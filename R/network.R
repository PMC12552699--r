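#' Denoising network configuration
#'
#' The denoiser is an ultra-lightweight 2-D encoder-decoder that maps a C-frame
#' window (frames as input channels) to a C-frame denoised window:
#' a grouped 3x3 stem projection C -> 64, two encoder blocks (grouped 3x3 conv,
#' batch norm, ReLU, 3x3 max-pool stride 2), two decoder blocks
#' (nearest-neighbour x2 upsample, grouped 3x3 conv, batch norm, ReLU) with a
#' single skip connection from the second encoder block's pre-pool features to
#' the first decoder block, and a 1x1 output projection 64 -> C. All grouped
#' convolutions process `group_width` channels per group, which keeps the whole
#' model under 0.013 million trainable parameters at the defaults.
#'
#' @param in_out_channels window width C (even); default 16.
#' @param feature_channels channels per feature map; default 64.
#' @param group_width input channels per convolution group; default 2.
#' @param skip keep the deepest-level skip connection; default `TRUE`.
#' @return A list of class `network_config`.
#' @export
network_config <- function(in_out_channels = 16L, feature_channels = 64L,
                           group_width = 2L, skip = TRUE) {
  C <- as.integer(in_out_channels)
  Fc <- as.integer(feature_channels)
  gw <- as.integer(group_width)
  if (C < 2L || C %% 2L != 0L) stop("in_out_channels (C) must be even and >= 2")
  if (Fc %% gw != 0L) stop("feature_channels must be divisible by group_width")
  if (C %% gw != 0L) stop("in_out_channels must be divisible by group_width")
  structure(list(in_out_channels = C, feature_channels = Fc,
                 group_width = gw, depth = 2L, skip = isTRUE(skip)),
            class = "network_config")
}

# He-uniform init for a grouped conv layer: w dim (k, k, cin_g, Cout), b = 0.
init_conv <- function(k, cin, cout, groups) {
  cin_g <- cin %/% groups
  fan_in <- k * k * cin_g
  bound <- sqrt(6 / fan_in)
  list(w = array(runif(k * k * cin_g * cout, -bound, bound),
                 c(k, k, cin_g, cout)),
       b = numeric(cout),
       k = k, cin = cin, cout = cout, groups = groups)
}

OUT_INIT_GAIN <- 0.005

init_bn <- function(ch) {
  list(gamma = rep(1, ch), beta = numeric(ch),
       running_mean = numeric(ch), running_var = rep(1, ch))
}

#' Build the denoising network
#'
#' Instantiates all layers of the architecture described in [network_config()]
#' with deterministic He-uniform initialization under `init_seed`.
#'
#' @param config a [network_config()].
#' @param init_seed integer seed for weight initialization.
#' @return An object of class `fast_network` holding the layer parameters,
#'   batch-norm running statistics and the config.
#' @export
build_model <- function(config = network_config(), init_seed = 123L) {
  stopifnot(inherits(config, "network_config"))
  C <- config$in_out_channels
  Fc <- config$feature_channels
  gw <- config$group_width
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(as.integer(init_seed))
  dec1_in <- if (config$skip) 2L * Fc else Fc
  net <- list(
    config = config,
    init_seed = as.integer(init_seed),
    stem = init_conv(3L, C, Fc, C %/% gw),
    enc1 = init_conv(3L, Fc, Fc, Fc %/% gw), bn1 = init_bn(Fc),
    enc2 = init_conv(3L, Fc, Fc, Fc %/% gw), bn2 = init_bn(Fc),
    dec1 = init_conv(3L, dec1_in, Fc, dec1_in %/% gw), bn3 = init_bn(Fc),
    dec2 = init_conv(3L, Fc, Fc, Fc %/% gw), bn4 = init_bn(Fc),
    out = init_conv(1L, Fc, C, 1L)
  )
  # The output projection starts near the zero map: together with an output
  # bias set to the data mean by the fitting routine, the initial network
  # predicts the mean intensity, which stabilizes early optimization of the
  # self-supervised objective at batch size 1 and short training schedules.
  net$out$w <- net$out$w * OUT_INIT_GAIN
  class(net) <- "fast_network"
  net
}

#' Count trainable parameters
#'
#' Total number of trainable scalars: convolution weights and biases plus the
#' batch-norm affine terms (running statistics are buffers, not parameters).
#'
#' @param model a `fast_network` (or a `fast_denoiser` fit).
#' @return Integer parameter count.
#' @examples
#' count_parameters(build_model(network_config()))
#' @export
count_parameters <- function(model) {
  if (inherits(model, "fast_denoiser")) model <- model$net
  stopifnot(inherits(model, "fast_network"))
  n <- 0L
  for (nm in c("stem", "enc1", "enc2", "dec1", "dec2", "out"))
    n <- n + length(model[[nm]]$w) + length(model[[nm]]$b)
  for (nm in c("bn1", "bn2", "bn3", "bn4"))
    n <- n + length(model[[nm]]$gamma) + length(model[[nm]]$beta)
  n
}

# ---- layer primitives (R side; convolutions and pooling are in C++) --------

conv_apply <- function(layer, x) {
  d <- dim(x)
  y <- conv2d_fwd(x, layer$w, layer$b,
                  d[1], d[2], layer$cin, layer$cout, layer$k, layer$groups)
  dim(y) <- c(d[1], d[2], layer$cout)
  y
}

conv_backward <- function(layer, x, gy) {
  d <- dim(x)
  g <- conv2d_bwd(x, layer$w, gy,
                  d[1], d[2], layer$cin, layer$cout, layer$k, layer$groups)
  gx <- g$gx; dim(gx) <- d
  gw <- g$gw; dim(gw) <- dim(layer$w)
  list(gx = gx, gw = gw, gb = g$gb)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_forward <- function(bn, x, training) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- x; dim(xm) <- c(n, d[3])
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu   # biased (population) variance
    va <- pmax(va, 0)
  } else {
    mu <- bn$running_mean
    va <- bn$running_var
  }
  invstd <- 1 / sqrt(va + BN_EPS)
  xhat <- affine_cols(xm, invstd, -mu * invstd, n, d[3])
  dim(xhat) <- c(n, d[3])
  y <- affine_cols(xhat, bn$gamma, bn$beta, n, d[3])
  dim(y) <- d
  list(y = y, xhat = xhat, invstd = invstd, mu = mu, var = va)
}

bn_update_running <- function(bn, mu, va) {
  bn$running_mean <- (1 - BN_MOMENTUM) * bn$running_mean + BN_MOMENTUM * mu
  bn$running_var <- (1 - BN_MOMENTUM) * bn$running_var + BN_MOMENTUM * va
  bn
}

# Backward through training-mode batch norm (per-channel stats over H*W).
bn_backward <- function(bn, cache, gy) {
  d <- dim(gy)
  n <- d[1] * d[2]
  r <- bn_bwd_core(gy, cache$xhat, bn$gamma, cache$invstd, n, d[3])
  gx <- r$gx; dim(gx) <- d
  list(gx = gx, ggamma = r$ggamma, gbeta = r$gbeta)
}

relu_forward <- function(x) {
  y <- relu_fwd(x)
  dim(y) <- dim(x)
  list(y = y)
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

upsample2_backward <- function(gy) {
  d <- dim(gy)
  i1 <- seq(1L, d[1], by = 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], by = 2L); j2 <- j1 + 1L
  gy[i1, j1, , drop = FALSE] + gy[i2, j1, , drop = FALSE] +
    gy[i1, j2, , drop = FALSE] + gy[i2, j2, , drop = FALSE]
}

pool_apply <- function(x) {
  d <- dim(x)
  p <- maxpool3_fwd(x, d[1], d[2], d[3])
  y <- p$y; dim(y) <- c(p$Ho, p$Wo, d[3])
  list(y = y, argmax = p$argmax, Ho = p$Ho, Wo = p$Wo, H = d[1], W = d[2])
}

pool_backward <- function(cache, gy) {
  d3 <- dim(gy)[3]
  g <- maxpool3_bwd(cache$argmax, gy, cache$H, cache$W, d3,
                    cache$Ho, cache$Wo)
  dim(g) <- c(cache$H, cache$W, d3)
  g
}

# ---- full forward / backward ------------------------------------------------

# Forward pass. training = TRUE uses per-window batch-norm statistics (batch
# size is 1 throughout) and returns every intermediate needed for backward;
# training = FALSE uses running statistics and returns only the output.
# update_running: refresh running stats from this window's statistics.
net_forward_impl <- function(net, x, training, update_running = training) {
  d <- dim(x)
  if (d[3] != net$config$in_out_channels)
    stop("window has ", d[3], " frames but the model expects ",
         net$config$in_out_channels)
  if (training && (d[1] %% 4L != 0L || d[2] %% 4L != 0L))
    stop("spatial dimensions must be divisible by 4 (two pooling stages); ",
         "pad-or-crop required")
  cache <- list(x = x)
  s <- conv_apply(net$stem, x)
  e1a <- conv_apply(net$enc1, s)
  b1 <- bn_forward(net$bn1, e1a, training)
  r1 <- relu_forward(b1$y)
  p1 <- pool_apply(r1$y)
  e2a <- conv_apply(net$enc2, p1$y)
  b2 <- bn_forward(net$bn2, e2a, training)
  r2 <- relu_forward(b2$y)
  p2 <- pool_apply(r2$y)
  u1 <- upsample2(p2$y)
  cat_in <- if (net$config$skip) {
    dd <- dim(u1)
    arr <- array(0, c(dd[1], dd[2], dd[3] + dim(r2$y)[3]))
    arr[, , seq_len(dd[3])] <- u1
    arr[, , dd[3] + seq_len(dim(r2$y)[3])] <- r2$y
    arr
  } else u1
  d1a <- conv_apply(net$dec1, cat_in)
  b3 <- bn_forward(net$bn3, d1a, training)
  r3 <- relu_forward(b3$y)
  u2 <- upsample2(r3$y)
  d2a <- conv_apply(net$dec2, u2)
  b4 <- bn_forward(net$bn4, d2a, training)
  r4 <- relu_forward(b4$y)
  y <- conv_apply(net$out, r4$y)
  if (update_running) {
    net$bn1 <- bn_update_running(net$bn1, b1$mu, b1$var)
    net$bn2 <- bn_update_running(net$bn2, b2$mu, b2$var)
    net$bn3 <- bn_update_running(net$bn3, b3$mu, b3$var)
    net$bn4 <- bn_update_running(net$bn4, b4$mu, b4$var)
  }
  list(y = y, net = net,
       cache = if (training) list(x = x, s = s, e1a = e1a, b1 = b1, r1 = r1,
                                  p1 = p1, e2a = e2a, b2 = b2, r2 = r2,
                                  p2 = p2, u1 = u1, cat_in = cat_in, d1a = d1a,
                                  b3 = b3, r3 = r3, u2 = u2, d2a = d2a,
                                  b4 = b4, r4 = r4) else NULL)
}

# Backward pass: gradient of a scalar loss w.r.t. all trainable parameters,
# given dL/dy. Returns a named flat list matching net_param_list().
net_backward <- function(net, cache, gy) {
  g <- list()
  bo <- conv_backward(net$out, cache$r4$y, gy)
  g$out.w <- bo$gw; g$out.b <- bo$gb
  gr4 <- relu_bwd(cache$r4$y, bo$gx); dim(gr4) <- dim(bo$gx)
  bb4 <- bn_backward(net$bn4, cache$b4, gr4)
  g$bn4.gamma <- bb4$ggamma; g$bn4.beta <- bb4$gbeta
  bd2 <- conv_backward(net$dec2, cache$u2, bb4$gx)
  g$dec2.w <- bd2$gw; g$dec2.b <- bd2$gb
  gu2 <- upsample2_backward(bd2$gx)
  gr3 <- relu_bwd(cache$r3$y, gu2); dim(gr3) <- dim(gu2)
  bb3 <- bn_backward(net$bn3, cache$b3, gr3)
  g$bn3.gamma <- bb3$ggamma; g$bn3.beta <- bb3$gbeta
  bd1 <- conv_backward(net$dec1, cache$cat_in, bb3$gx)
  g$dec1.w <- bd1$gw; g$dec1.b <- bd1$gb
  Fc <- net$config$feature_channels
  if (net$config$skip) {
    gu1 <- bd1$gx[, , seq_len(Fc), drop = FALSE]
    gskip <- bd1$gx[, , Fc + seq_len(Fc), drop = FALSE]
  } else {
    gu1 <- bd1$gx
    gskip <- 0
  }
  gp2 <- upsample2_backward(gu1)
  gr2 <- pool_backward(cache$p2, gp2)
  if (net$config$skip) gr2 <- gr2 + gskip
  gr2a <- relu_bwd(cache$r2$y, gr2); dim(gr2a) <- dim(gr2); gr2 <- gr2a
  bb2 <- bn_backward(net$bn2, cache$b2, gr2)
  g$bn2.gamma <- bb2$ggamma; g$bn2.beta <- bb2$gbeta
  be2 <- conv_backward(net$enc2, cache$p1$y, bb2$gx)
  g$enc2.w <- be2$gw; g$enc2.b <- be2$gb
  gp1 <- pool_backward(cache$p1, be2$gx)
  gr1 <- relu_bwd(cache$r1$y, gp1); dim(gr1) <- dim(gp1)
  bb1 <- bn_backward(net$bn1, cache$b1, gr1)
  g$bn1.gamma <- bb1$ggamma; g$bn1.beta <- bb1$gbeta
  be1 <- conv_backward(net$enc1, cache$s, bb1$gx)
  g$enc1.w <- be1$gw; g$enc1.b <- be1$gb
  bs <- conv_backward(net$stem, cache$x, be1$gx)
  g$stem.w <- bs$gw; g$stem.b <- bs$gb
  g
}

net_param_list <- function(net) {
  p <- list()
  for (nm in c("stem", "enc1", "enc2", "dec1", "dec2", "out")) {
    p[[paste0(nm, ".w")]] <- net[[nm]]$w
    p[[paste0(nm, ".b")]] <- net[[nm]]$b
  }
  for (nm in c("bn1", "bn2", "bn3", "bn4")) {
    p[[paste0(nm, ".gamma")]] <- net[[nm]]$gamma
    p[[paste0(nm, ".beta")]] <- net[[nm]]$beta
  }
  p
}

net_set_params <- function(net, p) {
  for (nm in c("stem", "enc1", "enc2", "dec1", "dec2", "out")) {
    net[[nm]]$w <- p[[paste0(nm, ".w")]]
    net[[nm]]$b <- p[[paste0(nm, ".b")]]
  }
  for (nm in c("bn1", "bn2", "bn3", "bn4")) {
    net[[nm]]$gamma <- p[[paste0(nm, ".gamma")]]
    net[[nm]]$beta <- p[[paste0(nm, ".beta")]]
  }
  net
}

#' Run the denoising network on one window
#'
#' Forward pass mapping an H x W x C window to a denoised window of identical
#' shape. In evaluation mode (`training = FALSE`, the default) batch-norm uses
#' its running statistics and the pass is deterministic. The network accepts
#' any spatial size divisible by 4, including half-resolution subsampled
#' windows, without reconfiguration.
#'
#' @param model a `fast_network` or `fast_denoiser`.
#' @param window numeric H x W x C array, H and W divisible by 4.
#' @param training use per-window batch statistics (as during fitting)?
#' @return An H x W x C array.
#' @export
net_forward <- function(model, window, training = FALSE) {
  if (inherits(model, "fast_denoiser")) model <- model$net
  stopifnot(inherits(model, "fast_network"))
  d <- dim(window)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop("spatial dimensions must be divisible by 4 (two pooling stages); ",
         "pad-or-crop required")
  net_forward_impl(model, window, training = training,
                   update_running = FALSE)$y
}

#' @export
print.fast_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<fast_network> C = %d frames/window, %d feature channels, ",
                     "%d-channel groups, skip = %s\n"),
              cfg$in_out_channels, cfg$feature_channels, cfg$group_width,
              cfg$skip))
  cat(sprintf("  trainable parameters: %d (%.4f M)\n",
              count_parameters(x), count_parameters(x) / 1e6))
  invisible(x)
}
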