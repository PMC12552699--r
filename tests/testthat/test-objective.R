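test_that("patch means are deterministic, co-located, and correct on toys", {
  spec <- patch_spec(20, 10, seed = 5)
  # constant image: every region mean equals the constant
  expect_equal(patch_means(matrix(2.5, 40, 40), spec), rep(2.5, 10))
  # 20x20 image admits one patch position: every entry is the global mean
  img <- matrix(runif(400), 20, 20)
  expect_equal(patch_means(img, spec), rep(mean(img), 10))
  # checkerboard: every even-sided patch holds exactly half ones
  cb <- outer(1:40, 1:40, function(i, j) (i + j) %% 2)
  pm <- patch_means(cb, patch_spec(20, 10, seed = 8))
  expect_equal(pm, rep(0.5, 10))
  # determinism: pure function of (image, spec)
  expect_identical(patch_means(img, spec), patch_means(img, spec))
  # 3-D input averages each patch over frames
  vol <- array(c(img, img + 1), c(20, 20, 2))
  expect_equal(patch_means(vol, spec), rep(mean(img) + 0.5, 10))
  expect_error(patch_means(matrix(numeric(0), 0, 0), spec), "empty")
})

test_that("loss terms are non-negative, zero at optimum, and match closed forms", {
  set.seed(1)
  x <- array(runif(8 * 8 * 2), c(8, 8, 2))
  # L_SC vanishes for the identity map: G1(X) - G1(X)
  f <- draw_mask_field(8, 8, 0, 3)
  g1 <- subsample(x, f, 1)
  expect_equal(loss_sc(g1, g1), 0)
  # printed scalar example: single-element arrays 1 vs 3 -> (1-3)^2 = 4
  expect_equal(loss_sc(array(1, c(1, 1, 1)), array(3, c(1, 1, 1))), 4)
  # homogeneity: scaling both inputs by lambda scales L_SC by lambda^2
  a <- array(runif(16), c(4, 4, 1)); b <- array(runif(16), c(4, 4, 1))
  expect_equal(loss_sc(3 * a, 3 * b), 9 * loss_sc(a, b))

  spec <- patch_spec(20, 10, seed = 2)
  t0 <- array(runif(24 * 24 * 2), c(24, 24, 2))
  expect_equal(loss_st(t0, t0, spec), 0)
  # constant offset delta: pixel term delta^2 plus patch term |delta|
  delta <- 0.3
  c0 <- array(1, c(24, 24, 2))
  expect_equal(loss_st(c0 + delta, c0, spec), delta^2 + delta)
  # dropping the patch term recovers plain MSE
  expect_equal(loss_st(c0 + delta, c0, spec = NULL), delta^2)
  expect_error(loss_st(c0, c0[1:12, 1:12, ]), "mismatch")
})

test_that("total loss adds its terms and is positive for an untrained model", {
  net <- tiny_net()
  stack <- tiny_stack(8, 8, 12, seed = 31)
  cfg <- sampler_config(4, 2, seed = 13)
  pair <- make_training_pair(stack, plan_windows(12, cfg)[1, ], cfg)
  spec <- patch_spec(20, 4, seed = 21)
  rep_ <- total_loss(pair, net, spec)
  expect_equal(rep_$l_total, rep_$l_sc + rep_$l_st)
  expect_gt(rep_$l_total, 0)
  expect_gte(rep_$l_sc, 0)
  expect_gte(rep_$l_st, 0)
})

test_that("no gradient flows through the stop-gradient path", {
  # Ablation: gradients from the full objective must equal gradients of the
  # objective with G1(f(X)) frozen at its current value -- i.e. the f(X)
  # branch contributes no parameter gradient.
  set.seed(7)
  net <- tiny_net(seed = 4)
  stack <- tiny_stack(8, 8, 12, seed = 8)
  cfg <- sampler_config(4, 2, seed = 5)
  pair <- make_training_pair(stack, plan_windows(12, cfg)[1, ], cfg)
  spec <- patch_spec(20, 5, seed = 6)
  res <- fastdenoise:::total_loss_impl(pair, net, spec, training = TRUE,
                                       want_grad = TRUE)
  full <- fastdenoise:::net_forward_impl(net, pair$x_window, training = TRUE,
                                         update_running = FALSE)$y
  sc_fixed <- subsample(full, pair$mask_field, 1)
  p <- fastdenoise:::net_param_list(net)
  eps <- 1e-6
  # spot-check parameters on the main trunk (stem feeds both branches, so a
  # leak through f(X) would show up here)
  for (nm in c("stem.w", "enc1.w", "out.w", "bn2.gamma")) {
    for (rep in 1:3) {
      i <- sample(length(p[[nm]]), 1)
      p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (loss_with_frozen_sc(fastdenoise:::net_set_params(net, p1), pair,
                                  spec, sc_fixed) -
              loss_with_frozen_sc(fastdenoise:::net_set_params(net, p2), pair,
                                  spec, sc_fixed)) / (2 * eps)
      expect_equal(res$grads[[nm]][i], num, tolerance = 5e-3)
    }
  }
})

test_that("patch gradient matches finite differences of the L1 term", {
  set.seed(9)
  spec <- patch_spec(6, 4, seed = 11)
  ph <- array(runif(12 * 12 * 2), c(12, 12, 2))
  th <- array(runif(12 * 12 * 2), c(12, 12, 2))
  sc <- array(runif(12 * 12 * 2), c(12, 12, 2))
  g <- fastdenoise:::loss_grad_pred(ph, th, sc, spec)
  lossfun <- function(z) loss_sc(z, sc) + loss_st(z, th, spec)
  eps <- 1e-7
  for (rep in 1:10) {
    i <- sample(length(ph), 1)
    ph1 <- ph; ph1[i] <- ph1[i] + eps
    ph2 <- ph; ph2[i] <- ph2[i] - eps
    expect_equal(g[i], (lossfun(ph1) - lossfun(ph2)) / (2 * eps),
                 tolerance = 1e-4)
  }
})
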