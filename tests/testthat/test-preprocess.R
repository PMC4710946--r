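test_that("detrending removes a pure linear ramp", {
  nt <- 80
  series <- matrix(seq_len(nt) * 3.5 + 2, ncol = 1)
  b <- bold_from_series(series, dims = c(2, 2, 2))
  out <- temporal_clean(b, 0.01, 0.08)
  expect_lt(max(abs(out$data[1, 1, 1, ])), 1e-8)
})

test_that("band-pass keeps in-band and rejects out-of-band sinusoids", {
  nt <- 150; tr <- 2
  tt <- seq_len(nt) * tr
  inband <- sin(2 * pi * 0.05 * tt)
  outband <- sin(2 * pi * 0.2 * tt)
  b <- bold_from_series(cbind(inband, outband), dims = c(2, 2, 2), tr_s = tr)
  out <- temporal_clean(b, 0.01, 0.08)
  amp <- function(x) sqrt(2 * mean(x^2))
  expect_lt(abs(amp(out$data[1, 1, 1, ]) - 1), 0.05)
  # out-of-band residual measured in the frequency domain
  spec_out <- abs(fft(out$data[2, 1, 1, ]))
  expect_lt(max(spec_out) / max(abs(fft(outband))), 0.10)
})

test_that("band edges are validated against Nyquist", {
  b <- bold_from_series(matrix(rnorm(40), ncol = 1), dims = c(2, 2, 2), tr_s = 2)
  expect_error(temporal_clean(b, 0.01, 0.25), "Nyquist")
  expect_error(temporal_clean(b, 0.1, 0.05), "low_hz")
})

test_that("nuisance regression matches least squares and is idempotent", {
  set.seed(42)
  nt <- 60
  regs <- cbind(r1 = rnorm(nt), r2 = rnorm(nt))
  # voxel 1: equal to a regressor; voxel 2: exactly orthogonal to design
  ortho <- residuals(lm(rnorm(nt) ~ regs))
  series <- cbind(regs[, 1], ortho, matrix(rnorm(nt * 48), nt, 48))
  b <- bold_from_series(series, dims = c(5, 5, 2))
  out <- regress_nuisance(b, regs)
  expect_lt(max(abs(out$data[1, 1, 1, ])), 1e-10)
  expect_lt(max(abs(out$data[2, 1, 1, ] - ortho)), 1e-10)
  # brute-force normal-equations oracle on the random voxels
  X <- cbind(1, regs)
  beta <- solve(t(X) %*% X, t(X) %*% series)
  resid <- series - X %*% beta
  got <- bold_matrix(out, full_mask(c(5, 5, 2)))[, seq_len(ncol(series))]
  expect_lt(max(abs(got - resid)), 1e-8)
  # residuals orthogonal to every regressor; second pass changes nothing
  expect_lt(max(abs(crossprod(X, got))), 1e-6)
  twice <- regress_nuisance(out, regs)
  expect_lt(max(abs(twice$data - out$data)), 1e-10)
})

test_that("rank-deficient nuisance designs are rejected with column names", {
  nt <- 30
  regs <- cbind(a = rnorm(nt), b = 0)
  regs <- cbind(regs, c = regs[, "a"] * 2)
  b <- bold_from_series(matrix(rnorm(nt), ncol = 1), dims = c(2, 2, 2))
  expect_error(regress_nuisance(b, regs), "rank deficient")
  expect_error(regress_nuisance(b, regs), "b|c")
})

test_that("confound series are spatial means over their masks", {
  set.seed(7)
  dims <- c(4, 4, 4); nt <- 20
  b <- bold4d(array(rnorm(prod(dims) * nt), c(dims, nt)))
  g <- array(FALSE, dims); g[1:2, , ] <- TRUE
  w <- array(FALSE, dims); w[3, , ] <- TRUE
  s <- array(FALSE, dims); s[4, 1, 1] <- TRUE
  conf <- extract_confound_series(b, list(global = g, wm = w, csf = s))
  expect_equal(colnames(conf), c("global", "wm", "csf"))
  # brute-force mean oracle
  for (t in c(1, 7, nt)) {
    expect_equal(unname(conf[t, "global"]), mean(b$data[, , , t][g]),
                 tolerance = 1e-12)
  }
  # single-voxel mask returns that voxel's series verbatim
  expect_equal(conf[, "csf"], b$data[4, 1, 1, ], tolerance = 1e-15,
               ignore_attr = TRUE)
  # constant volume gives constant columns
  bc <- bold4d(array(7, c(dims, nt)))
  confc <- extract_confound_series(bc, list(global = g, wm = w, csf = s))
  expect_true(all(confc == 7))
  expect_error(extract_confound_series(b, list(global = g, wm = w,
                                               csf = array(FALSE, dims))),
               "empty")
})

test_that("framewise displacement follows the Power formulation", {
  nt <- 10
  tr0 <- matrix(0.3, nt, 3); ro0 <- matrix(0.01, nt, 3)
  expect_true(all(framewise_displacement(motion_trace(tr0, ro0))$fd_mm == 0))

  tr1 <- tr0; tr1[4:nt, 1] <- tr1[4:nt, 1] + 0.1
  fd <- framewise_displacement(motion_trace(tr1, ro0))
  expect_equal(fd$fd_mm[4], 0.1, tolerance = 1e-12)
  expect_equal(sum(fd$fd_mm != 0), 1)

  ro2 <- ro0; ro2[6:nt, 2] <- ro2[6:nt, 2] + 0.01
  fd2 <- framewise_displacement(motion_trace(tr0, ro2), head_radius_mm = 50)
  expect_equal(fd2$fd_mm[6], 0.5, tolerance = 1e-12)

  # invariant to constant offsets on all parameters
  fd3 <- framewise_displacement(motion_trace(tr1 + 5, ro2 + 0.2))
  fd4 <- framewise_displacement(motion_trace(tr1, ro2))
  expect_equal(fd3$fd_mm, fd4$fd_mm, tolerance = 1e-12)
  expect_equal(fd4$fd_mm[1], 0)
})

test_that("group GM mask thresholds the mean probability map at the cutoff", {
  dims <- c(5, 5, 3)
  ones <- array(1, dims)
  m <- group_gm_mask(list(ones, ones))
  expect_true(all(m$include))

  lo <- array(0.19, dims); hi <- array(0.21, dims)
  expect_false(any(group_gm_mask(list(lo))$include))
  expect_true(all(group_gm_mask(list(hi))$include))
  expect_true(all(group_gm_mask(list(array(0.2, dims)))$include))  # boundary >=

  set.seed(1)
  maps <- replicate(4, array(runif(prod(dims)), dims), simplify = FALSE)
  got <- group_gm_mask(maps, cutoff = 0.5)
  mean_map <- (maps[[1]] + maps[[2]] + maps[[3]] + maps[[4]]) / 4
  expect_identical(got$include, mean_map >= 0.5)
  expect_error(group_gm_mask(list()), "non-empty")
})

test_that("detrend+band-pass commutes with regression of band-limited regressors", {
  set.seed(5)
  nt <- 120
  sp <- cohort_spec(grid_dims = c(8, 8, 6),
                    n_per_group = c(AD = 1, MCI = 2, NC = 1), n_converters = 1,
                    n_timepoints = nt, seed = 1)
  b <- generate_bold(sp, c(dmn = 1, occipital = 1), seed = 2)$bold
  raw_reg <- matrix(rnorm(nt * 2), nt, 2)
  filt_reg <- apply(raw_reg, 2, function(x) {
    bb <- bold_from_series(matrix(x, ncol = 1), dims = c(2, 2, 2))
    temporal_clean(bb, 0.01, 0.08)$data[1, 1, 1, ]
  })
  a <- regress_nuisance(temporal_clean(b, 0.01, 0.08), filt_reg)
  z <- temporal_clean(regress_nuisance(b, filt_reg), 0.01, 0.08)
  # the linear detrend and the ideal band-pass do not commute exactly on a
  # finite window (a band-limited signal has a nonzero fitted trend), so the
  # two orders agree only up to that trend leakage: a few percent of the
  # data scale
  expect_lt(max(abs(a$data - z$data)), 0.1 * sd(b$data))
})
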