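test_that("structure generator produces the requested cells and masks", {
  s0 <- generate_structure(64, 64, 0, seed = 1)
  expect_equal(s0$structure, matrix(0.05, 64, 64))
  expect_length(s0$masks, 0)

  s <- generate_structure(128, 128, 10, seed = 7)
  expect_length(s$masks, 10)
  expect_true(all(vapply(s$masks, nrow, integer(1)) > 0))
  expect_true(all(s$structure >= 0.05))

  # doubling blob amplitude doubles foreground-minus-background contrast
  lo <- generate_structure(64, 64, 5, seed = 3, amplitude_range = c(0.2, 0.2))
  hi <- generate_structure(64, 64, 5, seed = 3, amplitude_range = c(0.4, 0.4))
  expect_equal(max(hi$structure) - 0.05, 2 * (max(lo$structure) - 0.05),
               tolerance = 1e-12)
  # reproducibility
  expect_identical(generate_structure(64, 64, 5, seed = 3),
                   generate_structure(64, 64, 5, seed = 3))
})

test_that("voltage scenes honor spike width, rate and frame pacing", {
  # width 2 ms at 1000 Hz spans 2 frames
  expect_length(fastdenoise:::pulse_kernel(2), 2L)
  expect_length(fastdenoise:::pulse_kernel(8), 8L)
  expect_equal(max(fastdenoise:::pulse_kernel(6)), 1)

  # rate 0: constant video
  sc0 <- generate_voltage_video(16, 16, 3, fps = 1000, spike_width_ms = 4,
                                rate = 0, n_frames = 50, seed = 1)
  expect_true(all(sc0$clean_video == sc0$clean_video[, , rep(1, 50)]))

  # sub-frame pulses are rejected
  expect_error(generate_voltage_video(16, 16, 2, fps = 100,
                                      spike_width_ms = 2, n_frames = 20),
               "at least one frame")

  # autocorrelation width grows with spike width
  widths <- c(2, 4, 6, 8)
  acw <- vapply(widths, function(w) {
    sc <- generate_voltage_video(16, 16, 6, fps = 1000, spike_width_ms = w,
                                 rate = 10, n_frames = 3000, seed = 5)
    mean(vapply(seq_len(6), function(k) {
      ac <- acf(sc$traces[, k], lag.max = 20, plot = FALSE)$acf[, 1, 1]
      sum(ac > 0.1)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acw) > 0))
})

test_that("calcium kinetics rise fast and decay with tau_decay", {
  fps <- 100; tau_d <- 0.3; tau_r <- 0.02
  k <- fastdenoise:::calcium_kernel(tau_r, tau_d, fps)
  expect_equal(max(k), 1)
  expect_gt(which.max(k), 1)                          # finite rise time
  # closed-form oracle: peak-normalized (1 - exp(-t/tr)) * exp(-t/td)
  t <- seq(0, 5 * tau_d, by = 1 / fps)
  raw <- (1 - exp(-t / tau_r)) * exp(-t / tau_d)
  expect_equal(k, raw / max(raw), tolerance = 1e-12)
  # decays below 5% of peak within 3.5 tau of the peak, monotonically
  ipk <- which.max(k)
  tail_k <- k[ipk:length(k)]
  expect_lt(k[min(length(k), ipk + round(3.5 * tau_d * fps))], 0.05)
  expect_true(all(diff(tail_k) <= 0))
  # rate 0 -> constant video
  sc0 <- generate_calcium_video(16, 16, 2, rate = 0, n_frames = 30, seed = 2)
  expect_true(all(sc0$clean_video == sc0$clean_video[, , rep(1, 30)]))
  # full scene reproducibility
  a <- generate_calcium_video(24, 24, 3, n_frames = 40, seed = 9)
  b <- generate_calcium_video(24, 24, 3, n_frames = 40, seed = 9)
  expect_identical(a, b)
})

test_that("mixed noise is unbiased with variance x/a + sigma^2", {
  n <- 1e5
  clean <- array(4, c(n, 1, 1))
  nz <- add_mixed_noise(clean, noise_model(1, 0.5, seed = 2))
  expect_equal(mean(nz), 4, tolerance = 0.05)        # CLT: se ~ 0.0065
  expect_equal(var(as.numeric(nz)), 4 + 0.25, tolerance = 0.15)
  # large photon gain, no read noise: noisy ~ clean
  hi <- add_mixed_noise(array(2, c(50, 50, 2)), noise_model(1e6, 0, seed = 3))
  expect_lt(max(abs(hi - 2)), 0.02)
  # seeded reproducibility; clean geometry shared
  a <- add_mixed_noise(array(1, c(8, 8, 2)), noise_model(2, 0.1, seed = 5))
  b <- add_mixed_noise(array(1, c(8, 8, 2)), noise_model(2, 0.1, seed = 5))
  expect_identical(a, b)
  expect_error(add_mixed_noise(array(-1, c(2, 2, 1)), noise_model()),
               "non-negative")
})

test_that("variance law holds across intensity levels", {
  nm <- noise_model(2, 0.1, seed = 11)
  for (x in c(0.5, 2, 8)) {
    nz <- add_mixed_noise(array(x, c(200, 200, 1)), nm)
    expect_equal(var(as.numeric(nz)), x / 2 + 0.01, tolerance = 0.05 * (x / 2 + 0.01) + 0.01)
  }
})

test_that("the standard calcium fixture sits in the low-SNR regime", {
  fx <- synthetic_calcium_fixture(7)
  expect_equal(dim(fx$noisy), c(64L, 64L, 200L))
  expect_length(fx$scene$masks, 8)
  rng <- max(fx$scene$clean_video) - min(fx$scene$clean_video)
  p <- psnr(fx$scene$clean_video, fx$noisy, rng)
  expect_gt(p, 10); expect_lt(p, 17)
})
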