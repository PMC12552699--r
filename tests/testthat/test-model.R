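test_that("default network stays under the 13k parameter budget", {
  net <- build_model(network_config(), init_seed = 1)
  n <- count_parameters(net)
  expect_lte(n, 13000L)
  # closed-form check of the layer-wise count:
  # stem grouped 3x3 C=16 -> 64 (8 groups):       3*3*2*8*8  + 64 = 1216
  # enc1/enc2/dec2 grouped 3x3 64 -> 64 (32 grp): 3*3*2*2*32 + 64 = 1216 each
  # dec1 grouped 3x3 128 -> 64 (64 groups):       3*3*2*1*64 + 64 = 1216
  # out 1x1 64 -> 16:                             64*16      + 16 = 1040
  # four batch norms:                             4 * (64+64)     =  512
  expect_identical(n, 5L * 1216L + 1040L + 512L)
})

test_that("parameter count shrinks monotonically with ablations", {
  full <- count_parameters(build_model(network_config(), 1))
  # with fixed 2-channel groups a grouped conv's weight count is independent
  # of its input width, so dropping the skip cannot increase the count
  noskip <- count_parameters(build_model(network_config(skip = FALSE), 1))
  half <- count_parameters(build_model(network_config(feature_channels = 32), 1))
  expect_lte(noskip, full)
  expect_lt(half, full)
})

test_that("grouped convolution layer parameter counts follow the closed form", {
  l <- fastdenoise:::init_conv(3L, 64L, 64L, 32L)
  expect_equal(length(l$w) + length(l$b), 3 * 3 * 2 * 2 * 32 + 64)  # 1216
  l2 <- fastdenoise:::init_conv(1L, 64L, 16L, 1L)
  expect_equal(length(l2$w), 1024L)
})

test_that("forward preserves shape at full and half resolution and is deterministic", {
  net <- build_model(network_config(), init_seed = 7)
  x <- array(runif(32 * 48 * 16), c(32, 48, 16))
  y1 <- net_forward(net, x)
  expect_equal(dim(y1), dim(x))
  expect_true(all(is.finite(y1)))
  y2 <- net_forward(net, x)
  expect_identical(y1, y2)  # evaluation mode is deterministic
  # half-resolution windows pass through the same weights unchanged
  xh <- array(runif(16 * 24 * 16), c(16, 24, 16))
  expect_equal(dim(net_forward(net, xh)), dim(xh))
  expect_error(net_forward(net, array(0, c(30, 32, 16))), "divisible by 4")
  expect_error(net_forward(net, array(0, c(32, 32, 8))), "expects")
})

test_that("two builds from one init seed are identical, different seeds differ", {
  a <- build_model(network_config(), init_seed = 11)
  b <- build_model(network_config(), init_seed = 11)
  expect_identical(fastdenoise:::net_param_list(a),
                   fastdenoise:::net_param_list(b))
  c_ <- build_model(network_config(), init_seed = 12)
  expect_false(identical(a$stem$w, c_$stem$w))
})

test_that("a single-pixel perturbation only reaches a bounded neighbourhood", {
  # receptive field bound: 3x3 convs around two 2x pool/upsample stages keep
  # the influence of one input pixel well inside a ~50-pixel radius
  net <- build_model(network_config(), init_seed = 3)
  x <- array(0.5, c(64, 64, 16))
  y0 <- net_forward(net, x)
  x2 <- x
  x2[32, 32, 8] <- 5
  y1 <- net_forward(net, x2)
  changed <- apply(abs(y1 - y0) > 1e-12, c(1, 2), any)
  idx <- which(changed, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  expect_lte(max(abs(idx[, 1] - 32)), 50)
  expect_lte(max(abs(idx[, 2] - 32)), 50)
  # corners stay untouched
  expect_false(changed[1, 1] || changed[64, 64])
})

test_that("backward gradients match finite differences with the scale target frozen", {
  set.seed(42)
  net <- tiny_net()
  stack <- tiny_stack(8, 8, 12, seed = 5)
  cfg <- sampler_config(4, 2, seed = 3)
  pair <- make_training_pair(stack, plan_windows(12, cfg)[1, ], cfg)
  spec <- patch_spec(20, 5, seed = 9)
  res <- fastdenoise:::total_loss_impl(pair, net, spec, training = TRUE,
                                       want_grad = TRUE)
  full <- fastdenoise:::net_forward_impl(net, pair$x_window, training = TRUE,
                                         update_running = FALSE)$y
  sc_fixed <- subsample(full, pair$mask_field, 1)
  p <- fastdenoise:::net_param_list(net)
  eps <- 1e-6
  for (nm in names(p)) {
    i <- sample(length(p[[nm]]), 1)
    p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
    num <- (loss_with_frozen_sc(fastdenoise:::net_set_params(net, p1), pair,
                                spec, sc_fixed) -
            loss_with_frozen_sc(fastdenoise:::net_set_params(net, p2), pair,
                                spec, sc_fixed)) / (2 * eps)
    ana <- res$grads[[nm]][i]
    expect_equal(ana, num, tolerance = 5e-3,
                 label = paste("gradient of", nm))
  }
})
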