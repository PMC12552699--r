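# Shared fixtures and independent oracles used across the suite.

# Brute-force window-pair enumeration: all (x, x + S) with x a multiple of S
# and x + S + C <= T. Independent of plan_windows()'s closed form.
brute_force_windows <- function(T_, C, S) {
  out <- list()
  x <- 0L
  while (x + S + C <= T_) {
    out[[length(out) + 1L]] <- c(x, x + S)
    x <- x + S
  }
  if (length(out) == 0L) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}

# Naive per-pixel subsampling by explicit loops over blocks (oracle for the
# vectorized subsample()).
naive_subsample <- function(window, field, branch) {
  pool <- build_mask_pool()
  H <- dim(window)[1]; W <- dim(window)[2]; C <- dim(window)[3]
  out <- array(0, c(H / 2, W / 2, C))
  for (u in seq_len(H / 2)) for (v in seq_len(W / 2)) {
    cell <- if (branch == 1) pool[[field$pool_index[u, v]]]$g1
            else pool[[field$pool_index[u, v]]]$g2
    sel <- which(cell == 1, arr.ind = TRUE)
    for (t in seq_len(C)) {
      out[u, v, t] <- mean(window[cbind(2 * u - 2 + sel[, 1],
                                        2 * v - 2 + sel[, 2], t)])
    }
  }
  out
}

# Naive double-loop Gaussian-weighted SSIM (oracle for ssim()).
naive_ssim <- function(x, y, data_range, win = 7L, sigma = 1.5,
                       k1 = 0.01, k2 = 0.03) {
  t <- seq_len(win) - (win + 1) / 2
  g1d <- exp(-t^2 / (2 * sigma^2)); g1d <- g1d / sum(g1d)
  wts <- outer(g1d, g1d)
  c1 <- (k1 * data_range)^2; c2 <- (k2 * data_range)^2
  H <- nrow(x); W <- ncol(x)
  vals <- c()
  for (i in seq_len(H - win + 1)) for (j in seq_len(W - win + 1)) {
    px <- x[i:(i + win - 1), j:(j + win - 1)]
    py <- y[i:(i + win - 1), j:(j + win - 1)]
    m1 <- sum(wts * px); m2 <- sum(wts * py)
    v1 <- sum(wts * px^2) - m1^2; v2 <- sum(wts * py^2) - m2^2
    cv <- sum(wts * px * py) - m1 * m2
    vals <- c(vals, ((2 * m1 * m2 + c1) * (2 * cv + c2)) /
                      ((m1^2 + m2^2 + c1) * (v1 + v2 + c2)))
  }
  mean(vals)
}

# A small random stack for quick structural tests.
tiny_stack <- function(H = 8L, W = 8L, T_ = 12L, seed = 1L) {
  set.seed(seed)
  array(runif(H * W * T_), c(H, W, T_))
}

# A small network configuration for gradient and training mechanics tests.
tiny_net <- function(C = 4L, Fc = 8L, seed = 2L) {
  build_model(network_config(in_out_channels = C, feature_channels = Fc),
              init_seed = seed)
}

# Frozen scale-consistency target variant of the objective: finite-difference
# reference for the stop-gradient contract.
loss_with_frozen_sc <- function(net, pair, spec, sc_fixed) {
  ph <- fastdenoise:::net_forward_impl(net, pair$g1_x, training = TRUE,
                                       update_running = FALSE)$y
  loss_sc(ph, sc_fixed) + loss_st(ph, pair$g2_y, spec)
}
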