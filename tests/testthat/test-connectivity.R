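test_that("fisher_z is the arctanh transform with clipping at |r| = 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.2), 0.202733, tolerance = 1e-5)
  expect_equal(fisher_z(-0.5), -0.549306, tolerance = 1e-5)
  expect_equal(fisher_z(0.3), -fisher_z(-0.3))
  expect_true(all(diff(fisher_z(seq(-0.9, 0.9, by = 0.1))) > 0))
  expect_warning(z <- fisher_z(c(0.5, 1)), "clipped")
  expect_true(is.finite(z[2]))
})

test_that("compute_fcs matches the O(n^2) brute-force oracle", {
  set.seed(30)
  nt <- 60; n <- 30
  series <- matrix(rnorm(nt * n), nt, n)
  # add shared structure so many pairs pass the threshold
  shared <- rnorm(nt)
  series[, 1:12] <- series[, 1:12] + 1.2 * shared
  b <- bold_from_series(series, dims = c(5, 3, 2))
  mask <- full_mask(c(5, 3, 2))
  for (statistic in c("z_sum", "r_sum", "count")) {
    got <- compute_fcs(b, mask, r_threshold = 0.2, statistic = statistic)
    want <- oracle_fcs(b, mask, 0.2, statistic)
    expect_lt(max(abs(got$values - want)), 1e-10)
  }
  # blockwise contract: block size must not change the result
  small_blocks <- compute_fcs(b, mask, block_size = 4L)
  expect_equal(small_blocks$values, compute_fcs(b, mask)$values,
               tolerance = 1e-12)
})

test_that("exactly orthogonal series give zero FCS", {
  nt <- 64
  tt <- seq_len(nt)
  series <- sapply(1:6, function(k) sin(2 * pi * k * tt / nt))
  b <- bold_from_series(series, dims = c(3, 2, 1))
  f <- compute_fcs(b, full_mask(c(3, 2, 1)), r_threshold = 0.2)
  expect_true(all(f$values[1:6] == 0))
})

test_that("degenerate masks are rejected", {
  b <- bold_from_series(matrix(rnorm(40), ncol = 2), dims = c(2, 2, 1))
  one <- array(FALSE, c(2, 2, 1)); one[1] <- TRUE
  expect_error(compute_fcs(b, one), "at least 2")
})

test_that("FCS is monotone in the threshold and scale invariant", {
  set.seed(31)
  sp <- small_spec(seed = 4, grid = c(8, 8, 6), n_timepoints = 80)
  b <- generate_bold(sp, c(dmn = 1, occipital = 0.8), seed = 12)$bold
  mask <- sp$regions$gm
  f1 <- compute_fcs(b, mask, 0.1)$values
  f2 <- compute_fcs(b, mask, 0.2)$values
  f3 <- compute_fcs(b, mask, 0.3)$values
  expect_true(all(f1 - f2 >= -1e-12))
  expect_true(all(f2 - f3 >= -1e-12))
  # positive rescaling of one voxel's series changes nothing
  b2 <- b
  b2$data[3, 4, 2, ] <- b2$data[3, 4, 2, ] * 7.3
  expect_equal(compute_fcs(b2, mask, 0.2)$values, f2, tolerance = 1e-10)
})

test_that("zero-variance voxels are dropped with a warning, not errors", {
  set.seed(32)
  series <- cbind(matrix(rnorm(200), 50, 4), 0)
  b <- bold_from_series(series, dims = c(5, 1, 1))
  # make the fifth voxel exactly constant
  b$data[5, 1, 1, ] <- 3
  expect_warning(f <- compute_fcs(b, full_mask(c(5, 1, 1))), "zero-variance")
  expect_equal(f$n_dropped, 1L)
  expect_equal(f$values[5], 0)
})

test_that("seed timecourse is the spatial mean over the seed", {
  set.seed(33)
  dims <- c(4, 3, 2); nt <- 25
  b <- bold4d(array(rnorm(prod(dims) * nt), c(dims, nt)))
  one <- array(FALSE, dims); one[2, 2, 1] <- TRUE
  expect_equal(seed_timecourse(b, one), b$data[2, 2, 1, ], tolerance = 1e-15)
  # two opposite series cancel
  b2 <- b
  b2$data[1, 1, 1, ] <- 5 * sin(1:nt)
  b2$data[2, 1, 1, ] <- -5 * sin(1:nt)
  two <- array(FALSE, dims); two[1:2, 1, 1] <- TRUE
  expect_lt(max(abs(seed_timecourse(b2, two))), 1e-12)
  # brute-force mean oracle
  region <- array(FALSE, dims); region[, 2, ] <- TRUE
  got <- seed_timecourse(b, region)
  want <- sapply(1:nt, function(t) mean(b$data[, 2, , t]))
  expect_lt(max(abs(got - want)), 1e-12)
  expect_error(seed_timecourse(b, array(FALSE, dims)), "empty")
})

test_that("seed FC maps match the per-voxel correlation oracle", {
  set.seed(34)
  nt <- 60; n <- 25
  series <- matrix(rnorm(nt * n), nt, n)
  shared <- rnorm(nt)
  series[, 1:10] <- series[, 1:10] + shared
  b <- bold_from_series(series, dims = c(5, 5, 1))
  mask <- full_mask(c(5, 5, 1))
  seed_series <- series[, 1]
  m <- seed_fc_map(b, seed_series, mask)
  want <- oracle_seed_fc(b, seed_series, mask)
  expect_lt(max(abs(m$values - want)), 1e-10)
  # self-correlation hits the documented clipped maximum
  expect_equal(m$values[1], atanh(1 - 1e-7), tolerance = 1e-9)
  # orthogonal construction gives z ~ 0
  tt <- seq_len(nt)
  b2 <- bold_from_series(cbind(sin(2 * pi * tt / nt), sin(2 * pi * 2 * tt / nt)),
                         dims = c(2, 1, 1))
  m2 <- seed_fc_map(b2, b2$data[1, 1, 1, ], full_mask(c(2, 1, 1)))
  expect_lt(abs(m2$values[2]), 1e-10)
  # positive_only marks z > 0 voxels for downstream stats
  expect_identical(m$analysis_mask[1:n], as.vector(m$values[1:n] > 0))
  expect_error(seed_fc_map(b, rep(1, nt), mask), "zero variance")
})
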