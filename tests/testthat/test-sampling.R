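test_that("plan_windows matches brute-force enumeration and its printed examples", {
  cfg <- sampler_config(window_width = 4, shift_step = 2)
  pw <- plan_windows(10, cfg)
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$x_start, c(0L, 2L, 4L))
  expect_equal(pw$y_start, c(2L, 4L, 6L))

  # boundary: T = C + S gives exactly one pair at (0, S)
  for (C in c(2L, 6L, 16L)) for (S in c(1L, C %/% 2L, C)) {
    one <- plan_windows(C + S, sampler_config(C, S))
    expect_equal(nrow(one), 1L)
    expect_equal(c(one$x_start, one$y_start), c(0L, S))
  }

  # long-stack case against the independent oracle
  pw <- plan_windows(5000, sampler_config(16, 8))
  bf <- brute_force_windows(5000L, 16L, 8L)
  expect_equal(nrow(pw), 623L)
  expect_equal(cbind(pw$x_start, pw$y_start), unname(bf))

  # randomized sweep
  set.seed(99)
  for (rep in 1:50) {
    C <- 2L * sample.int(8L, 1)
    S <- sample.int(C, 1)
    T_ <- sample(seq.int(C + S, 200L), 1)
    pw <- plan_windows(T_, sampler_config(C, S))
    bf <- brute_force_windows(T_, C, S)
    expect_equal(cbind(pw$x_start, pw$y_start), unname(bf))
    expect_true(all(pw$y_start + C <= T_))
  }
})

test_that("too-short stacks and invalid configs are rejected", {
  expect_error(plan_windows(5, sampler_config(4, 2)), "too short")
  expect_error(sampler_config(4, 5), "S <= C")
  expect_error(sampler_config(4, 0), "S <= C")
  expect_error(sampler_config(5, 2), "even")
})

test_that("mask pool holds the 6 complementary two-one cells", {
  pool <- build_mask_pool()
  expect_length(pool, 6L)
  for (p in pool) {
    expect_equal(sum(p$g1), 2L)
    expect_equal(sum(p$g2), 2L)
    expect_equal(p$g1 + p$g2, matrix(1L, 2, 2))  # disjoint support, full cover
  }
  # all 6 distinct two-one matrices occur as G1 cells
  keys <- vapply(pool, function(p) paste(p$g1, collapse = ""), character(1))
  expect_equal(length(unique(keys)), 6L)
})

test_that("mask fields are deterministic, block-resolved, and pair-specific", {
  f1 <- draw_mask_field(64, 64, pair_index = 0, seed = 123)
  f2 <- draw_mask_field(64, 64, pair_index = 0, seed = 123)
  expect_identical(f1, f2)
  expect_equal(dim(f1$pool_index), c(32L, 32L))
  f3 <- draw_mask_field(64, 64, pair_index = 1, seed = 123)
  expect_false(identical(f1$pool_index, f3$pool_index))
  expect_equal(dim(draw_mask_field(4, 4, 0, 1)$pool_index), c(2L, 2L))
  expect_error(draw_mask_field(5, 4, 0, 1), "even")
})

test_that("subsample averages the selected adjacent pixels", {
  # constant window stays constant under any field/branch
  f <- draw_mask_field(6, 6, 0, 42)
  const <- array(3.7, c(6, 6, 2))
  expect_equal(subsample(const, f, 1), array(3.7, c(3, 3, 2)))
  expect_equal(subsample(const, f, 2), array(3.7, c(3, 3, 2)))

  # single block, top-row cell: (1 + 2) / 2 with values laid out by row
  blk <- array(c(1, 3, 2, 4), c(2, 2, 1))  # [[1,2],[3,4]] in matrix notation
  f1 <- draw_mask_field(2, 2, 0, 1)
  f1$pool_index[1, 1] <- 1L  # top row cell
  expect_equal(as.numeric(subsample(blk, f1, 1)), 1.5)
  expect_equal(as.numeric(subsample(blk, f1, 2)), 3.5)  # complement: bottom row

  # output shape (H/2, W/2, C)
  w <- array(runif(4 * 4 * 3), c(4, 4, 3))
  f2 <- draw_mask_field(4, 4, 0, 5)
  expect_equal(dim(subsample(w, f2, 1)), c(2L, 2L, 3L))

  # vectorized path equals the naive loop oracle
  set.seed(11)
  for (rep in 1:5) {
    w <- array(runif(8 * 6 * 4), c(8, 6, 4))
    f <- draw_mask_field(8, 6, rep, seed = rep)
    expect_equal(subsample(w, f, 1), naive_subsample(w, f, 1))
    expect_equal(subsample(w, f, 2), naive_subsample(w, f, 2))
  }
  expect_error(subsample(w, draw_mask_field(4, 4, 0, 1), 1), "match")

  # single-pixel mode picks exactly one of each block's selected pixels
  w <- array(runif(4 * 4 * 2), c(4, 4, 2))
  f <- draw_mask_field(4, 4, 0, 31)
  sp <- subsample(w, f, 1, mode = "single_pixel")
  expect_true(all(sp %in% w))
  i1 <- fastdenoise:::field_indices(f, 1L)$i1
  expect_equal(as.numeric(sp), as.numeric(matrix(w, 16, 2)[i1, ]))
})

test_that("branch index sets are disjoint and partition each block", {
  f <- draw_mask_field(16, 16, 0, 7)
  i1 <- fastdenoise:::field_indices(f, 1L)
  i2 <- fastdenoise:::field_indices(f, 2L)
  expect_length(intersect(c(i1$i1, i1$i2), c(i2$i1, i2$i2)), 0L)
  expect_setequal(c(i1$i1, i1$i2, i2$i1, i2$i2), seq_len(16 * 16))
})

test_that("mass is preserved across the two branches", {
  # averaging kernels partition each block, so the two branch means average to
  # the window mean over full blocks
  set.seed(3)
  w <- array(runif(12 * 12 * 5), c(12, 12, 5))
  f <- draw_mask_field(12, 12, 0, 9)
  g1 <- subsample(w, f, 1)
  g2 <- subsample(w, f, 2)
  expect_equal((mean(g1) + mean(g2)) / 2, mean(w), tolerance = 1e-12)
})

test_that("make_training_pair slices, subsamples and reproduces bit-identically", {
  cfg <- sampler_config(window_width = 4, shift_step = 2, seed = 17)
  stack <- tiny_stack(8, 8, 6)
  pw <- plan_windows(6, cfg)
  expect_equal(nrow(pw), 1L)
  pair <- make_training_pair(stack, pw[1, ], cfg)
  expect_equal(pair$x_window, stack[, , 1:4])
  expect_equal(pair$y_window, stack[, , 3:6])
  expect_equal(pair$g1_x, subsample(pair$x_window, pair$mask_field, 1))
  expect_equal(pair$g2_y, subsample(pair$y_window, pair$mask_field, 2))

  # constant stack propagates the constant
  cpair <- make_training_pair(array(2, c(4, 4, 6)), pw[1, ], cfg)
  expect_true(all(cpair$g1_x == 2) && all(cpair$g2_y == 2))

  # determinism under identical seed
  pair2 <- make_training_pair(stack, pw[1, ], cfg)
  expect_identical(pair, pair2)

  # odd spatial dims are cropped
  odd <- array(runif(7 * 9 * 6), c(7, 9, 6))
  opair <- make_training_pair(odd, pw[1, ], cfg)
  expect_equal(dim(opair$x_window), c(6L, 8L, 4L))
  expect_equal(dim(opair$g1_x), c(3L, 4L, 4L))
})
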