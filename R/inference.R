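#' Voxelwise statistic map
#'
#' @param values 3D numeric array (F or t statistics; 0 outside the analysis
#'   mask).
#' @param stat_kind `"F"` or `"t"`.
#' @param df Degrees of freedom: `c(df1, df2)` for F, scalar for t.
#' @param mask 3D logical analysis mask.
#' @param design_description One-line description of the fitted design.
#' @param extra Optional named list of companion arrays (e.g. slopes).
#' @return Object of class `stat_map`.
#' @export
stat_map <- function(values, stat_kind, df, mask, design_description = "",
                     extra = list()) {
  .assert(stat_kind %in% c("F", "t"), "stat_kind must be 'F' or 't'")
  if (stat_kind == "F") .assert(all(values[mask] >= 0 | is.na(values[mask])),
                                "F values must be nonnegative")
  structure(list(values = values, stat_kind = stat_kind, df = df,
                 mask = mask, design_description = design_description,
                 extra = extra),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s, df = (%s), %d mask voxels; %s\n", x$stat_kind,
              paste(x$df, collapse = ", "), sum(x$mask), x$design_description))
  invisible(x)
}

# Stack a list of fcs_map / seed_fc_map / 3D arrays into a subjects x voxels
# matrix over `mask` (3D logical). Returns matrix with voxel_index attribute.
.stack_maps <- function(maps, mask) {
  vals <- lapply(maps, function(m) {
    if (inherits(m, c("fcs_map", "seed_fc_map"))) m$values else m
  })
  d <- dim(vals[[1]])
  .assert(identical(dim(mask), d), "mask dimensions must match the maps")
  idx <- which(mask)
  out <- t(vapply(vals, function(v) v[idx], numeric(length(idx))))
  attr(out, "voxel_index") <- idx
  attr(out, "dims") <- d
  out
}

.default_mask <- function(maps) {
  m <- maps[[1]]
  if (inherits(m, c("fcs_map", "seed_fc_map"))) {
    if (!is.null(m$mask)) return(m$mask)
    if (!is.null(m$analysis_mask)) return(m$analysis_mask)
  }
  array(TRUE, dim(if (is.list(m)) m$values else m))
}

.check_full_rank <- function(X, what = "design") {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(what, " is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  qx
}

.covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  .assert(nrow(covariates) == n, "covariate rows must match the number of subjects")
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
  covariates
}

#' Voxelwise ANCOVA F map for a group main effect
#'
#' Fits, per voxel, the general linear model with group dummies plus
#' covariates and an intercept, and the reduced model without the group
#' dummies; the partial F for the group factor comes from the nested
#' residual sums of squares, with `df1 = G - 1` and `df2 = N - G - k`.
#'
#' @param maps List of per-subject [compute_fcs()] maps (or 3D arrays).
#' @param groups Factor or character vector of group labels, one per map.
#' @param covariates Optional subjects x k numeric matrix (e.g. age and a
#'   0/1 sex indicator).
#' @param mask Optional 3D logical analysis mask; defaults to the first
#'   map's mask.
#' @return A [stat_map()] with `stat_kind = "F"`.
#' @export
ancova_f_map <- function(maps, groups, covariates = NULL, mask = NULL) {
  groups <- droplevels(as.factor(groups))
  .assert(nlevels(groups) >= 2L, "need at least 2 groups")
  .assert(length(maps) == length(groups), "one group label per map required")
  mask <- mask %||% .default_mask(maps)
  Y <- .stack_maps(maps, mask)
  n <- nrow(Y)
  covs <- .covariate_matrix(covariates, n)
  dummies <- stats::model.matrix(~groups)[, -1, drop = FALSE]
  X_full <- cbind(intercept = rep(1, n), covs, dummies)
  X_red <- cbind(intercept = rep(1, n), covs)
  qf <- .check_full_rank(X_full, "ANCOVA design")
  qr_red <- qr(X_red)
  rss_f <- colSums(qr.resid(qf, Y)^2)
  rss_r <- colSums(qr.resid(qr_red, Y)^2)
  df1 <- nlevels(groups) - 1L
  df2 <- n - ncol(X_full)
  .assert(df2 >= 1L, "not enough subjects for the requested design")
  f <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  f[!is.finite(f) & rss_f == 0 & rss_r == rss_f] <- 0
  f[f < 0] <- 0  # guard against roundoff
  vals <- array(0, attr(Y, "dims"))
  vals[attr(Y, "voxel_index")] <- f
  stat_map(vals, "F", c(df1, df2), mask,
           sprintf("group main effect (%d groups), %d covariate(s)",
                   nlevels(groups), if (is.null(covs)) 0L else ncol(covs)))
}

# Shared machinery: per-voxel t for the last design column.
.t_for_last_column <- function(Y, X) {
  qx <- .check_full_rank(X, "design")
  beta <- qr.coef(qx, Y)
  rss <- colSums(qr.resid(qx, Y)^2)
  df <- nrow(X) - ncol(X)
  .assert(df >= 1L, "not enough subjects for the requested design")
  xtx_inv_last <- solve(crossprod(X))[ncol(X), ncol(X)]
  sigma2 <- rss / df
  se <- sqrt(sigma2 * xtx_inv_last)
  slope <- beta[ncol(X), ]
  t <- slope / se
  cap <- 1e6
  capped <- is.infinite(t) | abs(t) > cap
  t[capped] <- sign(slope[capped]) * cap
  t[se == 0 & slope == 0] <- 0
  list(t = t, slope = slope, df = df, n_capped = sum(capped))
}

#' Covariate-adjusted post-hoc two-group t map
#'
#' Per-voxel t statistic for the group-difference coefficient (sign
#' convention: group a minus group b), adjusted for covariates, evaluated
#' inside `restrict_mask` only.
#'
#' @param maps_a,maps_b Lists of per-subject maps for the two groups.
#' @param covariates Optional covariate matrix, rows ordered as
#'   `c(maps_a, maps_b)`.
#' @param restrict_mask Optional 3D logical mask (e.g. the ANCOVA-significant
#'   region); defaults to the first map's mask.
#' @return A [stat_map()] with `stat_kind = "t"` and df `n - k - 2`.
#' @export
posthoc_t_map <- function(maps_a, maps_b, covariates = NULL,
                          restrict_mask = NULL) {
  .assert(length(maps_a) >= 2L && length(maps_b) >= 2L,
          "each group needs at least 2 subjects")
  maps <- c(maps_a, maps_b)
  mask <- restrict_mask %||% .default_mask(maps)
  Y <- .stack_maps(maps, mask)
  n <- nrow(Y)
  covs <- .covariate_matrix(covariates, n)
  grp <- c(rep(1, length(maps_a)), rep(0, length(maps_b)))
  X <- cbind(intercept = rep(1, n), covs, group_a = grp)
  fit <- .t_for_last_column(Y, X)
  vals <- array(0, attr(Y, "dims"))
  vals[attr(Y, "voxel_index")] <- fit$t
  stat_map(vals, "t", fit$df, mask,
           sprintf("two-group contrast (a - b), %d covariate(s)",
                   if (is.null(covs)) 0L else ncol(covs)),
           extra = list(n_capped = fit$n_capped))
}

#' Voxelwise association between maps and a behavioral score
#'
#' Per-voxel general linear model with the score as the predictor of
#' interest and covariates adjusted for; reports the slope and its t
#' statistic. Degenerate perfect fits are capped at |t| = 1e6 and counted in
#' `extra$n_capped`.
#'
#' @param maps List of per-subject maps.
#' @param score Numeric vector (one value per subject) with nonzero variance.
#' @param covariates Optional covariate matrix.
#' @param mask Optional 3D logical analysis mask.
#' @return A [stat_map()] (`stat_kind = "t"`) with `extra$slope` (3D array).
#' @export
behavior_association_map <- function(maps, score, covariates = NULL,
                                     mask = NULL) {
  score <- as.numeric(score)
  .assert(length(score) == length(maps), "one score per subject map required")
  .assert(stats::sd(score) > 0, "score has no variance")
  mask <- mask %||% .default_mask(maps)
  Y <- .stack_maps(maps, mask)
  covs <- .covariate_matrix(covariates, nrow(Y))
  X <- cbind(intercept = rep(1, nrow(Y)), covs, score = score)
  fit <- .t_for_last_column(Y, X)
  vals <- array(0, attr(Y, "dims"))
  slope <- array(0, attr(Y, "dims"))
  vals[attr(Y, "voxel_index")] <- fit$t
  slope[attr(Y, "voxel_index")] <- fit$slope
  stat_map(vals, "t", fit$df, mask,
           sprintf("score association, %d covariate(s)",
                   if (is.null(covs)) 0L else ncol(covs)),
           extra = list(slope = slope, n_capped = fit$n_capped))
}

#' One-way ANOVA F from group summary statistics
#'
#' Closed-form F from per-group means, SDs and ns:
#' `F = [sum n_g (m_g - m.)^2 / (G - 1)] / [sum (n_g - 1) s_g^2 / (N - G)]`
#' with `m.` the n-weighted grand mean.
#'
#' @param groups data.frame with columns `mean`, `sd`, `n` (one row per
#'   group, each `n >= 2`), or a list of such per-group lists.
#' @return List: `F`, `df1`, `df2`, `p`.
#' @export
#' @examples
#' anova_f_from_summary(data.frame(mean = c(16.8, 23.5, 28.0),
#'                                 sd = c(4.7, 2.9, 2.3), n = c(25, 31, 42)))
anova_f_from_summary <- function(groups) {
  if (!is.data.frame(groups))
    groups <- do.call(rbind, lapply(groups, as.data.frame))
  .assert(nrow(groups) >= 2L, "need at least 2 groups")
  .assert(all(groups$n >= 2), "every group needs n >= 2")
  .assert(all(groups$sd >= 0), "SDs must be nonnegative")
  G <- nrow(groups)
  N <- sum(groups$n)
  gm <- sum(groups$n * groups$mean) / N
  msb <- sum(groups$n * (groups$mean - gm)^2) / (G - 1)
  msw <- sum((groups$n - 1) * groups$sd^2) / (N - G)
  if (msw == 0) {
    if (msb == 0) stop("all SDs zero with equal means: F undefined", call. = FALSE)
    return(list(F = Inf, df1 = G - 1L, df2 = N - G, p = 0))
  }
  f <- msb / msw
  list(F = f, df1 = as.integer(G - 1), df2 = as.integer(N - G),
       p = stats::pf(f, G - 1, N - G, lower.tail = FALSE))
}

#' Pooled two-sample t from group summary statistics
#'
#' Equal-variance two-sample t with `df = n_a + n_b - 2` (the convention
#' matching printed df in the subgroup comparison table).
#'
#' @param a,b Lists or one-row data.frames with `mean`, `sd`, `n` (n >= 2).
#' @return List: `t`, `df`, `p` (two-tailed).
#' @export
#' @examples
#' pooled_t_from_summary(list(mean = 68.6, sd = 9.3, n = 21),
#'                       list(mean = 66.5, sd = 10.4, n = 10))
pooled_t_from_summary <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  .assert(a$n >= 2 && b$n >= 2, "both groups need n >= 2")
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 == 0) {
    if (a$mean == b$mean) stop("zero pooled variance with equal means: t undefined",
                               call. = FALSE)
    return(list(t = Inf * sign(a$mean - b$mean), df = as.integer(df), p = 0))
  }
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  list(t = t, df = as.integer(df), p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}
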