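# Clip bound applied to correlations before arctanh; synthetic data can
# produce exact duplicates (r = 1), whose Fisher z would be infinite.
.r_clip <- 1 - 1e-7

#' Fisher r-to-z transform
#'
#' `z = arctanh(r)`, the approximately variance-stabilizing transform of a
#' Pearson correlation. Correlations with `|r| >= 1` are clipped to
#' `+/-(1 - 1e-7)` with a warning.
#'
#' @param r Numeric vector of correlations.
#' @return Numeric vector of Fisher z values.
#' @export
#' @examples
#' fisher_z(c(0, 0.2, -0.5))
fisher_z <- function(r) {
  n_clip <- sum(abs(r) >= 1)
  if (n_clip > 0) {
    warning(sprintf("%d correlation(s) with |r| >= 1 clipped to +/-%.7f",
                    n_clip, .r_clip))
    r <- pmin(pmax(r, -.r_clip), .r_clip)
  }
  atanh(r)
}

#' Voxelwise functional connectivity strength (FCS)
#'
#' For every GM voxel i, sums its suprathreshold connections to all other GM
#' voxels: `FCS(i) = sum_{j != i, r_ij > r_threshold} z(r_ij)` with `z` the
#' Fisher transform (the default `statistic = "z_sum"`). The raw-r sum and a
#' plain suprathreshold count are available behind the `statistic` flag for
#' sensitivity checks. The threshold comparison is strict (`r >` threshold).
#'
#' Correlations are computed in column blocks so the full n x n matrix is
#' never materialized; peak memory is O(block_size x n). Zero-variance
#' voxels inside the mask are dropped from the computation with a warning
#' and receive FCS 0.
#'
#' @param bold A [bold4d()].
#' @param mask A [gm_mask()] or 3D logical array with >= 2 voxels.
#' @param r_threshold Correlation threshold in (0, 1); default 0.2.
#' @param statistic `"z_sum"` (default), `"r_sum"` or `"count"`.
#' @param block_size Number of voxels per correlation block.
#' @return Object of class `fcs_map`: `values` (3D array, 0 outside mask),
#'   `r_threshold`, `statistic`, `mask` (the logical include array),
#'   `n_clipped` (connections clipped at |r| = 1), `n_dropped`
#'   (zero-variance voxels dropped).
#' @export
compute_fcs <- function(bold, mask, r_threshold = 0.2,
                        statistic = c("z_sum", "r_sum", "count"),
                        block_size = 512L) {
  statistic <- match.arg(statistic)
  .assert(r_threshold > 0 && r_threshold < 1, "r_threshold must be in (0, 1)")
  if (inherits(mask, "gm_mask")) mask <- mask$include
  .assert(sum(mask) >= 2L, "FCS needs at least 2 mask voxels")
  X <- bold_matrix(bold, mask)
  idx <- attr(X, "voxel_index")
  Xs <- .standardize_columns(X)
  zero <- attr(Xs, "zero_variance")
  n_dropped <- sum(zero)
  if (n_dropped > 0) {
    warning(sprintf("%d zero-variance voxel(s) dropped from the FCS mask", n_dropped))
    Xs <- Xs[, !zero, drop = FALSE]
    idx <- idx[!zero]
  }
  n <- ncol(Xs)
  .assert(n >= 2L, "fewer than 2 voxels with signal variance in the mask")
  vals <- numeric(n)
  n_clipped <- 0L
  clip <- .r_clip
  for (start in seq(1L, n, by = block_size)) {
    cols <- start:min(start + block_size - 1L, n)
    r <- crossprod(Xs[, cols, drop = FALSE], Xs)   # block x n
    r[cbind(seq_along(cols), cols)] <- 0           # exclude self-connection
    keep <- r > r_threshold
    n_clipped <- n_clipped + sum(r >= 1)
    contrib <- switch(statistic,
      z_sum = atanh(pmin(pmax(r, -clip), clip)) * keep,
      r_sum = r * keep,
      count = keep * 1)
    vals[cols] <- rowSums(contrib)
  }
  out <- array(0, dim(bold$data)[1:3])
  out[idx] <- vals
  structure(list(values = out, r_threshold = r_threshold,
                 statistic = statistic, mask = mask,
                 n_clipped = n_clipped, n_dropped = n_dropped),
            class = "fcs_map")
}

#' @export
print.fcs_map <- function(x, ...) {
  cat(sprintf("<fcs_map> %d mask voxels, r > %.2g, statistic = %s\n",
              sum(x$mask), x$r_threshold, x$statistic))
  invisible(x)
}

#' Mean time course of a seed region
#'
#' @param bold A [bold4d()].
#' @param seed_mask 3D logical array, non-empty, inside the grid.
#' @return Numeric vector of length t (per-frame mean over seed voxels).
#' @export
seed_timecourse <- function(bold, seed_mask) {
  .assert(sum(seed_mask) >= 1L, "seed mask is empty")
  rowMeans(bold_matrix(bold, seed_mask))
}

#' Seed-based functional connectivity map
#'
#' Correlates every GM voxel's series with the seed series and applies the
#' Fisher r-to-z transform. With `positive_only = TRUE` (the convention for
#' downstream statistics, since negative connections have ambiguous
#' interpretation), the returned `analysis_mask` marks voxels with z > 0.
#'
#' @param bold A [bold4d()].
#' @param seed_series Numeric vector of length t with nonzero variance.
#' @param mask A [gm_mask()] or 3D logical array.
#' @param positive_only Logical; mark only positive-z voxels in
#'   `analysis_mask`.
#' @param seed_name Label carried along with the map.
#' @return Object of class `seed_fc_map`: `values` (3D Fisher-z array, 0
#'   outside mask), `analysis_mask`, `seed_name`, `n_clipped`.
#' @export
seed_fc_map <- function(bold, seed_series, mask, positive_only = TRUE,
                        seed_name = "seed") {
  if (inherits(mask, "gm_mask")) mask <- mask$include
  nt <- dim(bold$data)[4]
  .assert(length(seed_series) == nt, "seed series length must equal t")
  .assert(stats::sd(seed_series) > 0, "seed series has zero variance")
  X <- bold_matrix(bold, mask)
  idx <- attr(X, "voxel_index")
  Xs <- .standardize_columns(X)
  zero <- attr(Xs, "zero_variance")
  s <- seed_series - mean(seed_series)
  s <- s / sqrt(sum(s^2))
  r <- as.numeric(crossprod(Xs, s))
  r[zero] <- 0
  n_clipped <- sum(abs(r) >= 1)
  z <- atanh(pmin(pmax(r, -.r_clip), .r_clip))
  vals <- array(0, dim(bold$data)[1:3])
  vals[idx] <- z
  amask <- array(FALSE, dim(bold$data)[1:3])
  amask[idx] <- if (positive_only) z > 0 else TRUE
  structure(list(values = vals, analysis_mask = amask,
                 seed_name = seed_name, n_clipped = n_clipped),
            class = "seed_fc_map")
}
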