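#' Separable 3D Gaussian smoothing
#'
#' Smooths a 3D array with an isotropic Gaussian of the given FWHM via three
#' one-dimensional convolutions (truncated at 3 sigma, renormalized at the
#' boundaries). `fwhm_mm = 0` returns the input unchanged.
#'
#' @param arr 3D numeric array.
#' @param fwhm_mm Full width at half maximum, mm (>= 0).
#' @param voxel_size_mm Voxel edge lengths, mm.
#' @return Smoothed array of identical dimensions.
#' @export
smooth_gaussian_3d <- function(arr, fwhm_mm, voxel_size_mm = c(3, 3, 3)) {
  .assert(fwhm_mm >= 0, "fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(arr)
  ks <- .smoothing_kernels(dim(arr), fwhm_mm, voxel_size_mm)
  .apply_separable(arr, ks)
}

.smoothing_kernels <- function(d, fwhm_mm, voxel_size_mm) {
  lapply(1:3, function(i) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm[i]
    pos <- seq_len(d[i])
    K <- exp(-outer(pos, pos, "-")^2 / (2 * sigma^2))
    K[abs(outer(pos, pos, "-")) > ceiling(3 * sigma)] <- 0
    K / rowSums(K)
  })
}

.apply_separable <- function(arr, ks) {
  d <- dim(arr)
  arr <- array(ks[[1]] %*% matrix(arr, d[1], d[2] * d[3]), d)
  a2 <- aperm(arr, c(2, 1, 3))
  a2 <- array(ks[[2]] %*% matrix(a2, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
  arr <- aperm(a2, c(2, 1, 3))
  a3 <- aperm(arr, c(3, 1, 2))
  a3 <- array(ks[[3]] %*% matrix(a3, d[3], d[1] * d[2]), c(d[3], d[1], d[2]))
  aperm(a3, c(2, 3, 1))
}

.neighbor_offsets <- function(connectivity = 18) {
  .assert(connectivity %in% c(6, 18, 26), "connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dist <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = dist == 1, "18" = dist >= 1 & dist <= 2, "26" = dist >= 1)
  off[keep, , drop = FALSE]
}

#' Label connected components of a 3D binary mask
#'
#' Breadth-first flood fill under 6- (face), 18- (face + edge) or 26-
#' (face + edge + corner) connectivity.
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26; default 18.
#' @return Integer array of the same dimensions: 0 outside the mask,
#'   component id (1, 2, ...) inside. Component sizes are attached as
#'   attribute `"sizes"`.
#' @export
label_components_3d <- function(mask, connectivity = 18) {
  d <- dim(mask)
  off <- .neighbor_offsets(connectivity)
  lab <- array(0L, d)
  todo <- which(mask)
  if (!length(todo)) {
    attr(lab, "sizes") <- integer(0)
    return(lab)
  }
  next_label <- 0L
  sizes <- integer(0)
  for (seed_idx in todo) {
    if (lab[seed_idx] != 0L) next
    next_label <- next_label + 1L
    lab[seed_idx] <- next_label
    frontier <- matrix(arrayInd(seed_idx, d), ncol = 3)
    count <- 1L
    while (nrow(frontier)) {
      cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(frontier)), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- unique(cand[, 1] + (cand[, 2] - 1L) * d[1] +
                      (cand[, 3] - 1L) * d[1] * d[2])
      lin <- lin[mask[lin] & lab[lin] == 0L]
      if (!length(lin)) break
      lab[lin] <- next_label
      count <- count + length(lin)
      frontier <- arrayInd(lin, d)
    }
    sizes <- c(sizes, count)
  }
  # recount exactly (frontier bookkeeping counts assignments, recount is cheap)
  sizes <- tabulate(lab[lab > 0L], nbins = next_label)
  attr(lab, "sizes") <- sizes
  lab
}

# One null field: smooth iid Gaussian noise, standardize within the mask,
# threshold |z| two-tailed at voxel_p, return the largest component size.
.null_max_cluster <- function(d, mask_arr, ks, z_thr, connectivity) {
  field <- array(stats::rnorm(prod(d)), d)
  if (!is.null(ks)) field <- .apply_separable(field, ks)
  v <- field[mask_arr]
  z <- (v - mean(v)) / stats::sd(v)
  supra <- array(FALSE, d)
  supra[which(mask_arr)[abs(z) > z_thr]] <- TRUE
  sizes <- attr(label_components_3d(supra, connectivity), "sizes")
  if (length(sizes)) max(sizes) else 0L
}

#' Monte-Carlo cluster-extent threshold (AlphaSim-style)
#'
#' Estimates the minimum cluster extent, in voxels, such that the
#' probability of observing any suprathreshold cluster of that size or
#' larger in a smooth Gaussian null field is at most `alpha`. Each
#' iteration: an iid standard Gaussian field on the mask's grid, Gaussian
#' smoothing at `fwhm_mm`, re-standardization within the mask (so `voxel_p`
#' maps exactly to a z quantile), two-tailed voxelwise thresholding at
#' `voxel_p`, and recording of the largest connected component.
#'
#' @param mask A [gm_mask()] or 3D logical array (non-empty).
#' @param fwhm_mm Smoothness of the null fields (the applied smoothing
#'   kernel), mm.
#' @param voxel_p Voxelwise (two-tailed) p threshold in (0, 1).
#' @param alpha Corrected familywise alpha in (0, 1); must be
#'   >= 1/n_iterations to be resolvable.
#' @param n_iterations Number of null simulations (>= 100).
#' @param connectivity 6, 18 or 26 (default 18, the rmm ~ 5 mm convention at
#'   3 mm voxels).
#' @param seed Integer seed.
#' @param voxel_size_mm Voxel edge lengths, mm.
#' @return Object of class `cluster_threshold` with fields
#'   `min_extent_voxels`, `min_extent_mm3`, `voxel_p`, `alpha`, `fwhm_mm`,
#'   `n_iterations`, `connectivity`, `null_max_sizes` (sorted).
#' @export
estimate_cluster_extent_threshold <- function(mask, fwhm_mm = 4,
                                              voxel_p = 0.05, alpha = 0.05,
                                              n_iterations = 1000,
                                              connectivity = 18, seed = 1L,
                                              voxel_size_mm = c(3, 3, 3)) {
  if (inherits(mask, "gm_mask")) mask <- mask$include
  .assert(sum(mask) >= 1L, "mask is empty")
  .assert(voxel_p > 0 && voxel_p < 1 && alpha > 0 && alpha <= 1,
          "voxel_p and alpha must lie in (0, 1)")
  .assert(n_iterations >= 100, "need at least 100 iterations")
  .assert(alpha >= 1 / n_iterations,
          "alpha below 1/n_iterations cannot be resolved")
  d <- dim(mask)
  ks <- if (fwhm_mm > 0) .smoothing_kernels(d, fwhm_mm, voxel_size_mm) else NULL
  z_thr <- stats::qnorm(1 - voxel_p / 2)
  set.seed(as.integer(seed))
  max_sizes <- vapply(seq_len(n_iterations), function(i) {
    .null_max_cluster(d, mask, ks, z_thr, connectivity)
  }, numeric(1))
  max_sizes <- sort(max_sizes)
  # smallest k whose null exceedance fraction is <= alpha
  k <- 1L
  n <- length(max_sizes)
  while (sum(max_sizes >= k) / n > alpha) k <- k + 1L
  structure(list(min_extent_voxels = as.integer(k),
                 min_extent_mm3 = k * prod(voxel_size_mm),
                 voxel_p = voxel_p, alpha = alpha, fwhm_mm = fwhm_mm,
                 n_iterations = as.integer(n_iterations),
                 connectivity = connectivity,
                 null_max_sizes = as.integer(max_sizes)),
            class = "cluster_threshold")
}

#' @export
print.cluster_threshold <- function(x, ...) {
  cat(sprintf(paste0("<cluster_threshold> min extent %d voxels (%.0f mm3) at ",
                     "voxel p < %.3g, alpha %.3g, FWHM %.3g mm, %d iterations\n"),
              x$min_extent_voxels, x$min_extent_mm3, x$voxel_p, x$alpha,
              x$fwhm_mm, x$n_iterations))
  invisible(x)
}

#' Extract suprathreshold clusters from a statistic map
#'
#' Connected components of suprathreshold voxels (strict `>`), dropping
#' components smaller than `min_extent_voxels`. The table is sorted by size
#' descending, ties broken by peak value (descending) then lexicographic
#' peak index.
#'
#' @param stat A [stat_map()] or 3D numeric array.
#' @param stat_threshold Finite statistic threshold.
#' @param min_extent_voxels Minimum cluster extent (voxels).
#' @param connectivity 6, 18 or 26.
#' @param two_sided Threshold on `|value|` (for t maps) rather than `value`.
#' @param voxel_size_mm Voxel edge lengths (mm), for the mm^3 column.
#' @return List of class `cluster_table`: `clusters` (data.frame with id,
#'   size_voxels, size_mm3, peak_value, peak_i, peak_j, peak_k) and
#'   `labels` (integer array; ids match the table).
#' @export
extract_clusters <- function(stat, stat_threshold, min_extent_voxels = 1L,
                             connectivity = 18, two_sided = FALSE,
                             voxel_size_mm = c(3, 3, 3)) {
  .assert(is.finite(stat_threshold), "stat_threshold must be finite")
  vals <- if (inherits(stat, "stat_map")) stat$values else stat
  mask <- if (inherits(stat, "stat_map")) stat$mask else array(TRUE, dim(vals))
  supra <- if (two_sided) abs(vals) > stat_threshold else vals > stat_threshold
  supra <- supra & mask
  lab <- label_components_3d(supra, connectivity)
  sizes <- attr(lab, "sizes")
  keep <- which(sizes >= min_extent_voxels)
  if (!length(keep)) {
    empty <- data.frame(id = integer(0), size_voxels = integer(0),
                        size_mm3 = numeric(0), peak_value = numeric(0),
                        peak_i = integer(0), peak_j = integer(0),
                        peak_k = integer(0))
    return(structure(list(clusters = empty, labels = array(0L, dim(vals))),
                     class = "cluster_table"))
  }
  rows <- lapply(keep, function(id) {
    vox <- which(lab == id)
    score <- if (two_sided) abs(vals[vox]) else vals[vox]
    peak_lin <- vox[order(-score, vox)[1]]
    pk <- arrayInd(peak_lin, dim(vals))
    data.frame(id = id, size_voxels = sizes[id],
               size_mm3 = sizes[id] * prod(voxel_size_mm),
               peak_value = vals[peak_lin],
               peak_i = pk[1], peak_j = pk[2], peak_k = pk[3])
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$size_voxels, -abs(tab$peak_value),
               tab$peak_i, tab$peak_j, tab$peak_k)
  tab <- tab[ord, , drop = FALSE]
  # relabel so ids are 1..n in table order
  relab <- array(0L, dim(vals))
  for (new_id in seq_len(nrow(tab))) relab[lab == tab$id[new_id]] <- new_id
  tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(clusters = tab, labels = relab), class = "cluster_table")
}

#' Empirical familywise error of an extent threshold on fresh nulls
#'
#' Simulates `n_fresh` new null fields (independent seed) under the same
#' smoothing/thresholding pipeline used for estimation and reports the
#' fraction containing any cluster at least as large as the estimated
#' extent.
#'
#' @param mask A [gm_mask()] or 3D logical array.
#' @param fwhm_mm Smoothness of the null fields, mm.
#' @param voxel_p Voxelwise two-tailed p threshold.
#' @param threshold_estimate A [estimate_cluster_extent_threshold()] result
#'   (or an integer extent).
#' @param n_fresh Number of fresh null fields (>= 100).
#' @param seed Integer seed (use one independent of the estimation seed).
#' @param connectivity 6, 18 or 26.
#' @param voxel_size_mm Voxel edge lengths, mm.
#' @return Observed familywise error rate (numeric scalar).
#' @export
fwe_calibration <- function(mask, fwhm_mm, voxel_p, threshold_estimate,
                            n_fresh = 1000, seed = 2L, connectivity = 18,
                            voxel_size_mm = c(3, 3, 3)) {
  .assert(n_fresh >= 100, "need at least 100 fresh null fields")
  k <- if (inherits(threshold_estimate, "cluster_threshold"))
    threshold_estimate$min_extent_voxels else as.integer(threshold_estimate)
  if (inherits(mask, "gm_mask")) mask <- mask$include
  d <- dim(mask)
  ks <- if (fwhm_mm > 0) .smoothing_kernels(d, fwhm_mm, voxel_size_mm) else NULL
  z_thr <- stats::qnorm(1 - voxel_p / 2)
  set.seed(as.integer(seed))
  hits <- vapply(seq_len(n_fresh), function(i) {
    .null_max_cluster(d, mask, ks, z_thr, connectivity) >= k
  }, logical(1))
  mean(hits)
}
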