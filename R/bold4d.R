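#' 4D BOLD container
#'
#' Holds a 4D voxel-by-time BOLD array together with its voxel size and
#' repetition time (TR). This is the unit of data every preprocessing and
#' connectivity operation consumes.
#'
#' @param data 4D numeric array, dimensions (x, y, z, t), t >= 2.
#' @param voxel_size_mm Positive numeric triple, voxel edge lengths in mm.
#' @param tr_s Positive scalar, repetition time in seconds.
#' @return An object of class `bold4d` with elements `data`, `voxel_size_mm`,
#'   `tr_s`.
#' @export
#' @examples
#' b <- bold4d(array(rnorm(4 * 4 * 2 * 10), c(4, 4, 2, 10)))
#' dim(b$data)
bold4d <- function(data, voxel_size_mm = c(3, 3, 3), tr_s = 2) {
  .assert(is.array(data) && length(dim(data)) == 4L,
          "`data` must be a 4D array (x, y, z, t)")
  .assert(dim(data)[4] >= 2L, "BOLD series needs at least 2 timepoints")
  .assert(all(dim(data) >= 1L), "all dimensions must be >= 1")
  .assert(!anyNA(data) && all(is.finite(data)), "BOLD data must be finite")
  .assert(length(voxel_size_mm) == 3L && all(voxel_size_mm > 0),
          "`voxel_size_mm` must be a positive triple")
  .assert(length(tr_s) == 1L && tr_s > 0, "`tr_s` must be a positive scalar")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 tr_s = as.numeric(tr_s)),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> %d x %d x %d voxels, %d frames, voxel %.3g mm, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$voxel_size_mm[1], x$tr_s))
  invisible(x)
}

#' Six-parameter rigid-body motion trace
#'
#' @param translations_mm t x 3 numeric matrix (mm).
#' @param rotations_rad t x 3 numeric matrix (radians).
#' @return Object of class `motion_trace`.
#' @export
motion_trace <- function(translations_mm, rotations_rad) {
  translations_mm <- as.matrix(translations_mm)
  rotations_rad <- as.matrix(rotations_rad)
  .assert(ncol(translations_mm) == 3L && ncol(rotations_rad) == 3L,
          "motion parameters must have 3 translation and 3 rotation columns")
  .assert(nrow(translations_mm) == nrow(rotations_rad),
          "translation and rotation traces must have equal length")
  .assert(all(is.finite(translations_mm)) && all(is.finite(rotations_rad)),
          "motion parameters must be finite")
  structure(list(translations_mm = translations_mm,
                 rotations_rad = rotations_rad),
            class = "motion_trace")
}

#' Extract the time-by-voxel matrix of masked series
#'
#' @param bold A [bold4d()] object.
#' @param mask 3D logical array (or a `gm_mask`) selecting voxels.
#' @return A t x n numeric matrix; columns follow column-major voxel order of
#'   the mask (the package-wide fixed voxel ordering). The linear voxel
#'   indices are attached as attribute `"voxel_index"`.
#' @export
bold_matrix <- function(bold, mask) {
  if (inherits(mask, "gm_mask")) mask <- mask$include
  d <- dim(bold$data)
  .assert(identical(dim(mask), d[1:3]), "mask dimensions must match the volume")
  idx <- which(mask)
  .assert(length(idx) >= 1L, "mask selects no voxels")
  nt <- d[4]
  m <- matrix(bold$data, nrow = prod(d[1:3]), ncol = nt)[idx, , drop = FALSE]
  out <- t(m)
  attr(out, "voxel_index") <- idx
  out
}

# Write a t x n matrix back into the masked voxels of a 4D array.
.matrix_to_bold <- function(mat, bold, mask) {
  if (inherits(mask, "gm_mask")) mask <- mask$include
  d <- dim(bold$data)
  idx <- which(mask)
  flat <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
  flat[idx, ] <- t(mat)
  bold$data <- array(flat, d)
  bold
}
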