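# Independent reference implementations used to cross-check the package's
# vectorized code paths. Deliberately naive: double loops, stats::cor, lm(),
# scan-order flood fill.

# O(n^2) FCS: per-voxel sum over all pairs via stats::cor.
oracle_fcs <- function(bold, mask, r_threshold = 0.2,
                       statistic = c("z_sum", "r_sum", "count")) {
  statistic <- match.arg(statistic)
  if (inherits(mask, "gm_mask")) mask <- mask$include
  X <- bold_matrix(bold, mask)
  idx <- attr(X, "voxel_index")
  n <- ncol(X)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      r <- stats::cor(X[, i], X[, j])
      if (r > r_threshold) {
        acc <- acc + switch(statistic,
                            z_sum = atanh(min(max(r, -(1 - 1e-7)), 1 - 1e-7)),
                            r_sum = r, count = 1)
      }
    }
    vals[i] <- acc
  }
  out <- array(0, dim(bold$data)[1:3])
  out[idx] <- vals
  out
}

# Per-voxel seed correlation via stats::cor.
oracle_seed_fc <- function(bold, seed_series, mask) {
  if (inherits(mask, "gm_mask")) mask <- mask$include
  X <- bold_matrix(bold, mask)
  idx <- attr(X, "voxel_index")
  z <- vapply(seq_len(ncol(X)), function(j) {
    r <- stats::cor(X[, j], seed_series)
    atanh(min(max(r, -(1 - 1e-7)), 1 - 1e-7))
  }, numeric(1))
  out <- array(0, dim(bold$data)[1:3])
  out[idx] <- z
  out
}

# Stack-based single-voxel flood fill, scanning neighbors one at a time.
oracle_flood_fill <- function(mask, connectivity) {
  d <- dim(mask)
  off <- switch(as.character(connectivity),
                "6" = 1, "18" = 2, "26" = 3)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) >= 1 &
                       rowSums(abs(offsets)) <= off, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  for (v in which(mask)) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    stack <- list(arrayInd(v, d)[1, ])
    lab[v] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offsets))) {
        q <- p + offsets[k, ]
        if (any(q < 1) || any(q > d)) next
        lin <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# From-scratch LOOCV with its own standardization and fold assembly.
oracle_loocv <- function(features, labels, positive, kernel = "linear",
                         cost = 1) {
  n <- nrow(features)
  classes <- sort(unique(labels))
  preds <- character(n)
  for (i in seq_len(n)) {
    tr <- scale(features[-i, , drop = FALSE])
    ctr <- attr(tr, "scaled:center")
    scl <- attr(tr, "scaled:scale")
    scl[scl == 0] <- 1
    tr[is.na(tr)] <- 0
    te <- (features[i, ] - ctr) / scl
    fit <- e1071::svm(x = tr, y = factor(labels[-i], levels = classes),
                      kernel = kernel, cost = cost, scale = FALSE)
    preds[i] <- as.character(predict(fit, matrix(te, nrow = 1)))
  }
  preds
}

# Raw samples with exact mean/sd via affine standardization.
exact_sample <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  mean + sd * x
}

# Compact BOLD builder from a t x n series matrix laid into a small grid.
bold_from_series <- function(series, dims = NULL, tr_s = 2) {
  nt <- nrow(series)
  n <- ncol(series)
  if (is.null(dims)) dims <- c(n, 1, 1)
  stopifnot(prod(dims) >= n)
  flat <- matrix(rnorm(prod(dims) * nt, sd = 1e-6), prod(dims), nt)
  flat[seq_len(n), ] <- t(series)
  bold4d(array(flat, c(dims, nt)), tr_s = tr_s)
}

full_mask <- function(dims) array(TRUE, dims)

# Small planted cohort spec for downstream tests.
small_spec <- function(seed = 1, n_per_group = c(AD = 4, MCI = 6, NC = 5),
                       n_converters = 3, grid = c(10, 10, 8),
                       n_timepoints = 100, ...) {
  cohort_spec(grid_dims = grid, n_per_group = n_per_group,
              n_converters = n_converters, n_timepoints = n_timepoints,
              seed = seed, ...)
}
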