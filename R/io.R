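#' Write / read a BOLD volume as NIfTI-1
#'
#' @param bold A [bold4d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly (writer); a [bold4d()] (reader).
#' @export
write_bold_nifti <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(bold$voxel_size_mm, bold$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  bold4d(array(as.numeric(img), dim(img)),
         voxel_size_mm = pd[1:3],
         tr_s = if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2)
}

#' Write / read a single 3D volume (mask, probability or statistic map)
#'
#' Data are written as float32, the conventional on-disk type for derived
#' maps.
#'
#' @param arr 3D numeric or logical array.
#' @param path Output path.
#' @param voxel_size_mm Voxel edge lengths, mm.
#' @return `path`, invisibly (writer); a 3D array (reader).
#' @export
write_volume_nifti <- function(arr, path, voxel_size_mm = c(3, 3, 3)) {
  img <- RNifti::asNifti(array(as.numeric(arr), dim(arr)))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Write / read a motion trace as 6-column whitespace-delimited text
#'
#' Column order: three translations (mm), three rotations (rad); one row per
#' frame, no header.
#'
#' @param motion A [motion_trace()].
#' @param path File path.
#' @return `path`, invisibly (writer); a [motion_trace()] (reader).
#' @export
write_motion_text <- function(motion, path) {
  m <- cbind(motion$translations_mm, motion$rotations_rad)
  utils::write.table(m, path, sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_text
#' @export
read_motion_text <- function(path) {
  m <- as.matrix(utils::read.table(path))
  .assert(ncol(m) == 6L, "motion file must have 6 columns")
  motion_trace(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
}

.subject_columns <- c("id", "group", "mci_subgroup", "age", "sex", "education",
                      "MMSE", "MoCA", "CDT", "AVLT_I", "AVLT_D", "AVLT_R")

#' Write / read the subject table as TSV
#'
#' Fixed header: id, group, mci_subgroup, age, sex, education, MMSE, MoCA,
#' CDT, AVLT_I, AVLT_D, AVLT_R.
#'
#' @param subjects data.frame with the columns above.
#' @param path File path.
#' @return `path`, invisibly (writer); a data.frame (reader).
#' @export
write_subjects_tsv <- function(subjects, path) {
  .assert(all(.subject_columns %in% names(subjects)),
          "subject table is missing required columns")
  utils::write.table(subjects[, .subject_columns], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subjects_tsv
#' @export
read_subjects_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a framewise-displacement series as single-column TSV
#'
#' @param fd A [framewise_displacement()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fd_tsv <- function(fd, path) {
  utils::write.table(data.frame(fd_mm = fd$fd_mm), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / restore a cohort spec as YAML
#'
#' Round-trip stable: `load_cohort_spec(save_cohort_spec(spec, f))`
#' reproduces an identical spec (and hence, via the seed, an identical
#' cohort).
#'
#' @param spec A [cohort_spec()].
#' @param path File path.
#' @return `path`, invisibly (save); a [cohort_spec()] (load).
#' @export
save_cohort_spec <- function(spec, path) {
  obj <- list(
    grid_dims = spec$grid_dims,
    n_per_group = as.list(spec$n_per_group),
    n_converters = spec$n_converters,
    network_rois = lapply(spec$network_rois, as.integer),
    coupling_by_group = list(networks = rownames(spec$coupling_by_group),
                             groups = colnames(spec$coupling_by_group),
                             values = as.numeric(spec$coupling_by_group)),
    noise_sd = spec$noise_sd,
    confound_amplitudes = as.list(spec$confound_amplitudes),
    motion_sd = spec$motion_sd,
    n_timepoints = spec$n_timepoints,
    tr_s = spec$tr_s,
    seed = spec$seed,
    age_confounding = spec$age_confounding
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname save_cohort_spec
#' @export
load_cohort_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  cb <- matrix(obj$coupling_by_group$values,
               nrow = length(obj$coupling_by_group$networks),
               dimnames = list(obj$coupling_by_group$networks,
                               obj$coupling_by_group$groups))
  cohort_spec(grid_dims = unlist(obj$grid_dims),
              n_per_group = unlist(obj$n_per_group),
              n_converters = obj$n_converters,
              network_rois = lapply(obj$network_rois, as.integer),
              coupling_by_group = cb,
              noise_sd = obj$noise_sd,
              confound_amplitudes = unlist(obj$confound_amplitudes),
              motion_sd = obj$motion_sd,
              n_timepoints = obj$n_timepoints,
              tr_s = obj$tr_s,
              seed = obj$seed,
              age_confounding = obj$age_confounding)
}
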