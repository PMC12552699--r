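test_that("dihedral augmentation keeps windows, views and field consistent", {
  cfg <- sampler_config(4, 2, seed = 19)
  stack <- tiny_stack(8, 8, 6, seed = 23)
  pair <- make_training_pair(stack, plan_windows(6, cfg)[1, ], cfg)

  # identity transform leaves the pair untouched
  expect_identical(augment(pair, op = 0), pair)

  for (op in 1:7) {
    ap <- augment(pair, op = op)
    # intensity content is permuted, never altered
    expect_equal(mean(ap$x_window), mean(pair$x_window))
    expect_equal(sort(as.numeric(ap$y_window)), sort(as.numeric(pair$y_window)))
    # transformed subsampled views equal subsampling of transformed windows
    expect_equal(ap$g1_x, subsample(ap$x_window, ap$mask_field, 1))
    expect_equal(ap$g2_y, subsample(ap$y_window, ap$mask_field, 2))
  }

  # group property: two quarter-turns equal a half-turn
  expect_equal(augment(augment(pair, op = 1), op = 1)$x_window,
               augment(pair, op = 2)$x_window)

  # seeded draws are reproducible
  expect_identical(augment(pair, step_seed = 77), augment(pair, step_seed = 77))
})

test_that("training is reproducible and reduces the loss on the tiny fixture", {
  set.seed(100)
  noisy <- tiny_stack(16, 16, 40, seed = 41) +
    array(rnorm(16 * 16 * 40, 0, 0.2), c(16, 16, 40))
  noisy <- pmax(noisy, 0)
  fit1 <- fast_denoiser(noisy, window_width = 8, shift_step = 4, epochs = 3,
                        patch_size = 8, n_regions = 4, seed = 123)
  fit2 <- fast_denoiser(noisy, window_width = 8, shift_step = 4, epochs = 3,
                        patch_size = 8, n_regions = 4, seed = 123)
  expect_identical(coef(fit1), coef(fit2))
  expect_identical(fit1$history, fit2$history)
  expect_lt(tail(fit1$history$l_total, 1), fit1$history$l_total[1])

  # a different seed takes a different trajectory
  fit3 <- fast_denoiser(noisy, window_width = 8, shift_step = 4, epochs = 1,
                        patch_size = 8, n_regions = 4, seed = 321)
  expect_false(identical(coef(fit1)$out.w, coef(fit3)$out.w))
})

test_that("early stopping halts once the loss stops improving", {
  noisy <- tiny_stack(16, 16, 30, seed = 171)
  fit <- fast_denoiser(noisy, window_width = 8, shift_step = 4, epochs = 40,
                       patch_size = 8, n_regions = 4, patience = 2)
  expect_lt(nrow(fit$history), 40L)
})

test_that("training errors are informative", {
  expect_error(fast_denoiser(tiny_stack(8, 8, 10), window_width = 8,
                             shift_step = 4), "too short")
})

test_that("the fitted object exposes the standard modelling interface", {
  noisy <- tiny_stack(16, 16, 30, seed = 51)
  fit <- fast_denoiser(noisy, window_width = 8, shift_step = 4, epochs = 2,
                       patch_size = 8, n_regions = 4)
  expect_s3_class(fit, "fast_denoiser")
  expect_named(fit$history, c("epoch", "l_sc", "l_st", "l_total"))
  expect_output(print(fit), "denoiser")
  expect_output(summary(fit), "ADAM")
  co <- coef(fit)
  expect_true(all(c("stem.w", "out.b", "bn4.gamma") %in% names(co)))
  den <- predict(fit, noisy)
  expect_s3_class(den, "video_stack")
  expect_equal(dim(den), dim(noisy))
  res <- residuals(fit, noisy)
  expect_equal(noisy - unclass(den)[seq_len(16), seq_len(16), ],
               unclass(res), tolerance = 1e-12)
})

test_that("volumetric series train one model per channel over all planes", {
  set.seed(61)
  mk_chan <- function(seed) {
    set.seed(seed)
    array(runif(16 * 16 * 2 * 30), c(16, 16, 2, 30))
  }
  series <- list(mk_chan(1), mk_chan(2))
  fits <- fast_denoiser_volumetric(series, window_width = 8, shift_step = 4,
                                   epochs = 2, patch_size = 8, n_regions = 4)
  expect_length(fits, 2)
  expect_false(identical(coef(fits[[1]])$out.w, coef(fits[[2]])$out.w))
  expect_true(all(vapply(fits, function(f) nrow(f$history) == 2L, logical(1))))
  expect_lt(tail(fits[[1]]$history$l_total, 1), fits[[1]]$history$l_total[1])

  # Z = 1 reduces exactly to training on the single plane
  one <- mk_chan(3)[, , 1, , drop = FALSE]
  fitv <- fast_denoiser_volumetric(list(one), window_width = 8, shift_step = 4,
                                   epochs = 1, patch_size = 8, n_regions = 4)
  fitp <- fast_denoiser(array(one, c(16, 16, 30)), window_width = 8,
                        shift_step = 4, epochs = 1, patch_size = 8,
                        n_regions = 4)
  expect_equal(coef(fitv[[1]]), coef(fitp))
  expect_error(fast_denoiser_volumetric(list(array(0, c(4, 4, 2)))),
               "H x W x Z x T")
})
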