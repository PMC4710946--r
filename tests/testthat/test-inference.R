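# Build per-subject 3D maps from a subjects x voxels matrix on a tiny grid.
maps_from_matrix <- function(Y, dims = c(4, 4, 2)) {
  lapply(seq_len(nrow(Y)), function(i) array(Y[i, ], dims))
}

test_that("ANCOVA F without covariates equals the closed-form one-way F", {
  set.seed(50)
  n <- c(8, 10, 12)
  groups <- rep(c("A", "B", "C"), n)
  Y <- matrix(rnorm(sum(n) * 32), sum(n), 32)
  Y[groups == "A", 1:10] <- Y[groups == "A", 1:10] + 1
  sm <- ancova_f_map(maps_from_matrix(Y), groups, mask = full_mask(c(4, 4, 2)))
  expect_equal(sm$df, c(2, sum(n) - 3))
  for (v in c(1, 5, 20)) {
    per_group <- lapply(unique(groups), function(g) {
      y <- Y[groups == g, v]
      list(mean = mean(y), sd = sd(y), n = length(y))
    })
    want <- anova_f_from_summary(per_group)$F
    expect_equal(array(sm$values, 32)[v], want, tolerance = 1e-8)
  }
})

test_that("ANCOVA with covariates matches the nested-model lm oracle", {
  set.seed(51)
  n <- 30
  groups <- rep(c("A", "B", "C"), each = 10)
  covs <- cbind(age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5))
  Y <- matrix(rnorm(n * 16), n, 16)
  sm <- ancova_f_map(maps_from_matrix(Y, c(4, 2, 2)), groups, covs,
                     mask = full_mask(c(4, 2, 2)))
  expect_equal(sm$df, c(2, n - 3 - 2))
  for (v in c(2, 9)) {
    y <- Y[, v]
    full <- lm(y ~ covs + factor(groups))
    red <- lm(y ~ covs)
    want <- anova(red, full)$F[2]
    expect_equal(array(sm$values, 16)[v], want, tolerance = 1e-8)
  }
  # exact collinearity with the group dummies is rejected
  bad <- cbind(covs, dup = as.numeric(groups == "B"))
  expect_error(ancova_f_map(maps_from_matrix(Y, c(4, 2, 2)), groups, bad,
                            mask = full_mask(c(4, 2, 2))),
               "rank deficient")
})

test_that("two-group F equals t^2 and matches the pooled-t summary form", {
  set.seed(52)
  na <- 9; nb <- 13
  Y <- matrix(rnorm((na + nb) * 20), na + nb, 20)
  Y[1:na, 1:6] <- Y[1:na, 1:6] + 0.8
  maps <- maps_from_matrix(Y, c(5, 2, 2))
  mask <- full_mask(c(5, 2, 2))
  tm <- posthoc_t_map(maps[1:na], maps[(na + 1):(na + nb)], restrict_mask = mask)
  fm <- ancova_f_map(maps, rep(c("a", "b"), c(na, nb)), mask = mask)
  expect_equal(tm$df, na + nb - 2)
  expect_equal(as.vector(tm$values[mask]^2), as.vector(fm$values[mask]),
               tolerance = 1e-8)
  for (v in c(1, 12)) {
    want <- pooled_t_from_summary(
      list(mean = mean(Y[1:na, v]), sd = sd(Y[1:na, v]), n = na),
      list(mean = mean(Y[(na + 1):(na + nb), v]), sd = sd(Y[(na + 1):(na + nb), v]),
           n = nb))
    expect_equal(array(tm$values, 20)[v], want$t, tolerance = 1e-8)
  }
  # identical group data give t = 0 everywhere
  same <- posthoc_t_map(maps[1:5], maps[1:5], restrict_mask = mask)
  expect_true(all(abs(same$values) < 1e-8))
  # restriction zeroes voxels outside the mask
  half <- mask; half[1:3, , ] <- FALSE
  tr <- posthoc_t_map(maps[1:na], maps[(na + 1):(na + nb)], restrict_mask = half)
  expect_true(all(tr$values[!half] == 0))
})

test_that("behavior association recovers slopes and matches lm", {
  set.seed(53)
  n <- 24
  score <- rnorm(n, 22, 4)
  covs <- cbind(age = rnorm(n, 70, 6))
  noise <- matrix(rnorm(n * 12, sd = 0.7), n, 12)
  Y <- 2 * score + noise
  sm <- behavior_association_map(maps_from_matrix(Y, c(4, 3, 1)), score, covs,
                                 mask = full_mask(c(4, 3, 1)))
  for (v in c(3, 8)) {
    fit <- summary(lm(Y[, v] ~ covs + score))
    expect_equal(array(sm$values, 12)[v], fit$coefficients["score", "t value"],
                 tolerance = 1e-8)
    expect_equal(array(sm$extra$slope, 12)[v],
                 fit$coefficients["score", "Estimate"], tolerance = 1e-8)
  }
  # perfectly linear voxel: slope exact, |t| capped and flagged
  Yp <- cbind(2 * score, Y[, -1])
  smp <- behavior_association_map(maps_from_matrix(Yp, c(4, 3, 1)), score, covs,
                                  mask = full_mask(c(4, 3, 1)))
  expect_equal(array(smp$extra$slope, 12)[1], 2, tolerance = 1e-8)
  expect_equal(abs(array(smp$values, 12)[1]), 1e6)
  expect_gte(smp$extra$n_capped, 1)
  expect_error(behavior_association_map(maps_from_matrix(Y, c(4, 3, 1)),
                                        rep(1, n), covs,
                                        mask = full_mask(c(4, 3, 1))),
               "variance")
})

test_that("null slopes concentrate around zero as subjects grow", {
  set.seed(54)
  slopes <- function(n) {
    score <- rnorm(n)
    Y <- matrix(rnorm(n * 200), n, 200)
    sm <- behavior_association_map(maps_from_matrix(Y, c(10, 10, 2)), score,
                                   mask = full_mask(c(10, 10, 2)))
    mean(abs(sm$extra$slope[full_mask(c(10, 10, 2))]))
  }
  expect_gt(slopes(12), slopes(120))
})

test_that("summary-statistic tests agree with raw-data oracles", {
  # raw samples constructed to have exactly the stated means/SDs
  g <- list(c(16.8, 4.7, 25), c(23.5, 2.9, 31), c(28.0, 2.3, 42))
  raw <- lapply(seq_along(g), function(i) {
    exact_sample(g[[i]][3], g[[i]][1], g[[i]][2], seed = i)
  })
  y <- unlist(raw)
  grp <- factor(rep(seq_along(g), times = sapply(g, `[`, 3)))
  want <- summary(aov(y ~ grp))[[1]]$`F value`[1]
  got <- anova_f_from_summary(data.frame(mean = sapply(g, `[`, 1),
                                         sd = sapply(g, `[`, 2),
                                         n = sapply(g, `[`, 3)))
  expect_equal(got$F, want, tolerance = 1e-10)
  expect_equal(got$df1, 2)
  expect_equal(got$df2, 95)

  a <- exact_sample(21, 68.6, 9.3, seed = 4)
  b <- exact_sample(10, 66.5, 10.4, seed = 5)
  want_t <- t.test(a, b, var.equal = TRUE)
  got_t <- pooled_t_from_summary(list(mean = 68.6, sd = 9.3, n = 21),
                                 list(mean = 66.5, sd = 10.4, n = 10))
  expect_equal(got_t$t, unname(want_t$statistic), tolerance = 1e-10)
  expect_equal(got_t$df, 29)
  expect_equal(got_t$p, want_t$p.value, tolerance = 1e-10)
})

test_that("summary tests handle boundary and degenerate inputs", {
  eq <- data.frame(mean = c(5, 5, 5), sd = c(1, 2, 3), n = c(5, 6, 7))
  expect_equal(anova_f_from_summary(eq)$F, 0)
  expect_equal(pooled_t_from_summary(list(mean = 3, sd = 1, n = 5),
                                     list(mean = 3, sd = 2, n = 5))$t, 0)
  expect_error(anova_f_from_summary(data.frame(mean = c(1, 1), sd = c(0, 0),
                                               n = c(4, 4))),
               "undefined")
  expect_error(pooled_t_from_summary(list(mean = 1, sd = 0, n = 4),
                                     list(mean = 1, sd = 0, n = 4)),
               "undefined")
})

test_that("voxelwise type-I error is calibrated on null data", {
  set.seed(55)
  n <- 60
  groups <- rep(c("A", "B", "C"), each = 20)
  Y <- matrix(rnorm(n * 500), n, 500)
  sm <- ancova_f_map(maps_from_matrix(Y, c(10, 10, 5)), groups,
                     mask = full_mask(c(10, 10, 5)))
  p <- pf(sm$values[full_mask(c(10, 10, 5))], sm$df[1], sm$df[2],
          lower.tail = FALSE)
  rate <- mean(p < 0.05)
  # 99% binomial band around 0.05 with 500 independent voxels
  half <- 2.58 * sqrt(0.05 * 0.95 / 500)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})

test_that("adding an irrelevant covariate shifts df2 by one without flipping effects", {
  set.seed(56)
  n <- 36
  groups <- rep(c("A", "B", "C"), each = 12)
  Y <- matrix(rnorm(n * 8), n, 8)
  Y[groups == "A", 1] <- Y[groups == "A", 1] + 3
  m0 <- ancova_f_map(maps_from_matrix(Y, c(4, 2, 1)), groups,
                     mask = full_mask(c(4, 2, 1)))
  m1 <- ancova_f_map(maps_from_matrix(Y, c(4, 2, 1)), groups,
                     covariates = cbind(junk = rnorm(n)),
                     mask = full_mask(c(4, 2, 1)))
  expect_equal(m1$df[2], m0$df[2] - 1)
  expect_gt(m1$values[1], qf(0.999, m1$df[1], m1$df[2]))
})
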