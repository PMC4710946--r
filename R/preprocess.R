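#' Gray-matter analysis mask
#'
#' @param include 3D logical array.
#' @param source_probability 3D numeric array in `[0, 1]` the mask was built
#'   from (the mean GM probability map).
#' @return Object of class `gm_mask`.
#' @export
gm_mask <- function(include, source_probability) {
  .assert(is.array(include) && is.logical(include) && length(dim(include)) == 3L,
          "`include` must be a 3D logical array")
  .assert(identical(dim(include), dim(source_probability)),
          "mask and probability map dimensions differ")
  .assert(all(source_probability >= 0 & source_probability <= 1),
          "probabilities must lie in [0, 1]")
  structure(list(include = include, source_probability = source_probability),
            class = "gm_mask")
}

#' Build the group GM mask from per-subject probability maps
#'
#' The mask includes every voxel whose mean probability across subjects is
#' greater than or equal to the cutoff (boundary inclusive).
#'
#' @param gm_maps Non-empty list of 3D probability arrays, equal dims.
#' @param cutoff Probability cutoff, default 0.2.
#' @return A [gm_mask()].
#' @export
group_gm_mask <- function(gm_maps, cutoff = 0.2) {
  .assert(is.list(gm_maps) && length(gm_maps) >= 1L, "gm_maps must be a non-empty list")
  d <- dim(gm_maps[[1]])
  for (m in gm_maps) {
    .assert(identical(dim(m), d), "all GM maps must share dimensions")
    .assert(all(m >= 0 & m <= 1), "GM probabilities must lie in [0, 1]")
  }
  mean_map <- Reduce(`+`, gm_maps) / length(gm_maps)
  gm_mask(mean_map >= cutoff, mean_map)
}

# Ideal FFT band-pass applied column-wise to a t x n matrix. Frequency bins
# with low_hz <= f <= high_hz are kept (both tails of the spectrum), all
# others (including DC) are zeroed.
.fft_bandpass <- function(x, tr_s, low_hz, high_hz) {
  nt <- nrow(x)
  freqs <- seq(0, nt - 1) / (nt * tr_s)
  freqs <- pmin(freqs, 1 / tr_s - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= low_hz & freqs <= high_hz
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  Re(stats::mvfft(xf, inverse = TRUE)) / nt
}

#' Temporal cleaning: linear detrend + ideal band-pass filter
#'
#' Removes each voxel's least-squares linear trend (intercept + slope), then
#' applies an ideal (FFT-mask) band-pass filter retaining spectral power in
#' `[low_hz, high_hz]`. The defaults give the conventional resting-state
#' band 0.01-0.08 Hz.
#'
#' @param bold A [bold4d()].
#' @param low_hz,high_hz Band edges in Hz; requires
#'   `0 <= low_hz < high_hz < 1/(2 * tr_s)`.
#' @return A [bold4d()] of identical dimensions.
#' @export
temporal_clean <- function(bold, low_hz = 0.01, high_hz = 0.08) {
  .assert(inherits(bold, "bold4d"), "bold must be a bold4d")
  nyq <- 1 / (2 * bold$tr_s)
  .assert(low_hz >= 0 && low_hz < high_hz, "need 0 <= low_hz < high_hz")
  .assert(high_hz < nyq, sprintf("high_hz must be below Nyquist (%.3g Hz)", nyq))
  d <- dim(bold$data)
  nt <- d[4]
  .assert(nt >= 8L, "series too short for band-pass filtering")
  flat <- t(matrix(bold$data, nrow = prod(d[1:3]), ncol = nt))  # t x voxels
  tt <- seq_len(nt)
  X <- cbind(1, tt - mean(tt))
  flat <- flat - X %*% qr.coef(qr(X), flat)
  flat <- .fft_bandpass(flat, bold$tr_s, low_hz, high_hz)
  bold$data <- array(t(flat), d)
  bold
}

#' Regress nuisance signals out of every voxel
#'
#' Replaces each voxel's series by the least-squares residual of its series
#' on `[intercept | regressors]`. Residuals are orthogonal to every
#' regressor column.
#'
#' @param bold A [bold4d()].
#' @param regressors t x k numeric matrix (e.g. six motion parameters plus
#'   global/WM/CSF confound series). Column names are used in rank-deficiency
#'   error messages.
#' @return A [bold4d()] of identical dimensions.
#' @export
regress_nuisance <- function(bold, regressors) {
  .assert(inherits(bold, "bold4d"), "bold must be a bold4d")
  regressors <- as.matrix(regressors)
  d <- dim(bold$data)
  nt <- d[4]
  .assert(nrow(regressors) == nt, "regressor rows must match the number of frames")
  X <- cbind(intercept = 1, regressors)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    bad <- bad[!is.na(bad) & nzchar(bad)]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
         call. = FALSE)
  }
  flat <- t(matrix(bold$data, nrow = prod(d[1:3]), ncol = nt))
  flat <- qr.resid(qx, flat)
  bold$data <- array(t(flat), d)
  bold
}

#' Extract global / white-matter / CSF confound series
#'
#' Each column is the spatial mean time course over its mask; column order
#' is fixed to (global, wm, csf).
#'
#' @param bold A [bold4d()].
#' @param masks Named list with 3D logical arrays (or `gm_mask` objects)
#'   `global`, `wm`, `csf`; every mask must be non-empty.
#' @return t x 3 numeric matrix with columns global, wm, csf.
#' @export
extract_confound_series <- function(bold, masks) {
  .assert(all(c("global", "wm", "csf") %in% names(masks)),
          "masks must name global, wm and csf")
  out <- sapply(c("global", "wm", "csf"), function(nm) {
    m <- masks[[nm]]
    if (inherits(m, "gm_mask")) m <- m$include
    .assert(sum(m) >= 1L, paste0("mask '", nm, "' is empty"))
    rowMeans(bold_matrix(bold, m))
  })
  colnames(out) <- c("global", "wm", "csf")
  out
}

#' Framewise displacement (Power formulation)
#'
#' `FD_i = sum(|delta translations_i|) + r * sum(|delta rotations_i|)` with
#' head radius `r` converting rotation angles to arc lengths; the first
#' frame's FD is 0 by convention.
#'
#' @param motion A [motion_trace()].
#' @param head_radius_mm Assumed head radius, default 50 mm.
#' @return List of class `fd_series`: `fd_mm` (per-frame FD, first = 0) and
#'   `mean_fd_mm`.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  .assert(inherits(motion, "motion_trace"), "motion must be a motion_trace")
  nt <- nrow(motion$translations_mm)
  .assert(nt >= 2L, "need at least 2 frames")
  dt <- abs(diff(motion$translations_mm))
  dr <- abs(diff(motion$rotations_rad))
  fd <- c(0, rowSums(dt) + head_radius_mm * rowSums(dr))
  structure(list(fd_mm = fd, mean_fd_mm = mean(fd)), class = "fd_series")
}

#' Standard temporal preprocessing for one subject
#'
#' Fixed order: linear detrend, band-pass filter, then nuisance regression of
#' the six motion parameters and the global / WM / CSF confound series
#' (global signal regression optional). The global mean is taken over the
#' analysis GM mask.
#'
#' @param bold A [bold4d()].
#' @param motion A [motion_trace()].
#' @param gm A [gm_mask()] (analysis mask; also the "global" mask).
#' @param wm_mask,csf_mask 3D logical arrays for the WM and CSF compartments.
#' @param low_hz,high_hz Band edges in Hz.
#' @param gsr Logical: include the global mean series in the nuisance set.
#' @return A cleaned [bold4d()].
#' @export
preprocess_subject <- function(bold, motion, gm, wm_mask, csf_mask,
                               low_hz = 0.01, high_hz = 0.08, gsr = TRUE) {
  cleaned <- temporal_clean(bold, low_hz, high_hz)
  conf <- extract_confound_series(cleaned,
                                  list(global = gm, wm = wm_mask, csf = csf_mask))
  regs <- cbind(motion$translations_mm, motion$rotations_rad,
                if (gsr) conf[, c("global", "wm", "csf")] else
                  conf[, c("wm", "csf")])
  colnames(regs) <- c(paste0("trans_", c("x", "y", "z")),
                      paste0("rot_", c("x", "y", "z")),
                      if (gsr) c("global", "wm", "csf") else c("wm", "csf"))
  regress_nuisance(cleaned, regs)
}
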