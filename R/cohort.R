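#' Default brain-compartment layout for a synthetic grid
#'
#' Splits the grid along z into a gray-matter slab (lower ~65%), a
#' white-matter slab and a CSF slab, and places two disjoint network ROIs in
#' the GM slab: a bilateral "DMN-like" network (two parietal-ish blocks,
#' standing in for angular-gyrus territory) and a posterior "occipital-like"
#' block. The layout scales with the grid so small test grids keep the same
#' structure.
#'
#' @param grid_dims Integer triple.
#' @return List with logical 3D arrays `gm`, `wm`, `csf` and
#'   `network_rois`, a named list of linear voxel index vectors
#'   (`dmn`, `occipital`), both inside `gm`.
#' @export
default_grid_regions <- function(grid_dims) {
  d <- as.integer(grid_dims)
  .assert(length(d) == 3L && all(d >= 6L),
          "grid_dims must be a triple with every dimension >= 6")
  fr <- function(n, lo, hi) {
    out <- max(1L, ceiling(lo * n)):min(n, max(1L, floor(hi * n)))
    out
  }
  z_gm <- 1:floor(0.65 * d[3])
  z_wm <- (max(z_gm) + 1):floor(0.85 * d[3])
  z_csf <- (max(z_wm) + 1):d[3]
  zeros <- array(FALSE, d)
  gm <- wm <- csf <- zeros
  gm[, , z_gm] <- TRUE
  wm[, , z_wm] <- TRUE
  csf[, , z_csf] <- TRUE

  roi_block <- function(xs, ys, zs) {
    a <- zeros
    a[xs, ys, zs] <- TRUE
    which(a)
  }
  # networks cover a substantial share of GM (~1/3), as resting-state
  # networks do; tiny ROIs would let chance connections dominate the FCS sum
  z_roi <- fr(d[3], 0.15, 0.5)
  dmn <- c(roi_block(fr(d[1], 0.08, 0.42), fr(d[2], 0.50, 0.92), z_roi),
           roi_block(fr(d[1], 0.58, 0.92), fr(d[2], 0.50, 0.92), z_roi))
  occ <- roi_block(fr(d[1], 0.25, 0.75), fr(d[2], 0.05, 0.40), z_roi)
  list(gm = gm, wm = wm, csf = csf,
       network_rois = list(dmn = sort(unique(dmn)), occipital = sort(occ)))
}

#' Default per-group network coupling weights
#'
#' Coupling weight `a` of the shared latent signal for each (network, group)
#' cell. The ordering NC > MCI-nc > MCI-c encodes a graded converter deficit
#' in both networks, with AD lowest; the gaps themselves are free parameters
#' of the generator (no published effect sizes exist for them).
#'
#' @return Numeric matrix, rows = networks (dmn, occipital),
#'   columns = NC, MCI_nc, MCI_c, AD.
#' @export
default_coupling <- function() {
  m <- rbind(dmn       = c(NC = 1.0, MCI_nc = 0.85, MCI_c = 0.65, AD = 0.55),
             occipital = c(NC = 1.0, MCI_nc = 0.85, MCI_c = 0.65, AD = 0.55))
  m
}

#' Specification of a synthetic resting-state cohort
#'
#' Bundles every parameter of the generative model: grid geometry, group
#' sizes, network ROIs, per-group coupling weights, observation noise,
#' confound amplitudes, motion magnitude, scan length and the master seed.
#'
#' @param grid_dims Integer triple; default 24 x 24 x 18 voxels at 3 mm.
#' @param n_per_group Named integer vector with entries AD, MCI, NC.
#' @param n_converters Number of MCI subjects flagged as converters
#'   (must be <= n_per_group["MCI"]).
#' @param network_rois Named list of disjoint linear voxel index vectors;
#'   default from [default_grid_regions()].
#' @param coupling_by_group Networks x groups matrix of coupling weights
#'   (columns NC, MCI_nc, MCI_c, AD); default [default_coupling()].
#' @param noise_sd Observation noise SD (per voxel, per frame).
#' @param confound_amplitudes Named numeric vector (global, wm, csf): the
#'   amplitudes with which the shared confound signals enter GM voxels.
#' @param motion_sd SD of the per-frame random-walk motion steps (mm for
#'   translations, rad for rotations).
#' @param n_timepoints Frames per scan (>= 2).
#' @param tr_s Repetition time, seconds.
#' @param seed Master integer seed; all per-subject randomness is derived
#'   from it via [derive_seed()].
#' @param age_confounding Optional scalar in `[0, 1)`: when positive, a
#'   subject's coupling is scaled by `1 - age_confounding * age_z` (age
#'   z-scored within group), coupling age to connectivity for
#'   covariate-adjustment experiments. Default 0 (age independent of
#'   coupling).
#' @param regions Compartment layout as returned by
#'   [default_grid_regions()]; recomputed from `grid_dims` when NULL.
#' @return Object of class `cohort_spec`.
#' @export
#' @examples
#' sp <- cohort_spec(grid_dims = c(12, 12, 8), n_per_group = c(AD = 3, MCI = 4, NC = 3),
#'                   n_converters = 2, n_timepoints = 40, seed = 1)
#' sp$n_per_group
cohort_spec <- function(grid_dims = c(24, 24, 18),
                        n_per_group = c(AD = 25, MCI = 31, NC = 42),
                        n_converters = 21,
                        network_rois = NULL,
                        coupling_by_group = default_coupling(),
                        noise_sd = 1,
                        confound_amplitudes = c(global = 0.4, wm = 0.2, csf = 0.2),
                        motion_sd = 0.02,
                        n_timepoints = 150,
                        tr_s = 2,
                        seed = 1L,
                        age_confounding = 0,
                        regions = NULL) {
  grid_dims <- as.integer(grid_dims)
  regions <- regions %||% default_grid_regions(grid_dims)
  network_rois <- network_rois %||% regions$network_rois
  .assert(all(c("AD", "MCI", "NC") %in% names(n_per_group)),
          "n_per_group must name AD, MCI and NC")
  n_per_group <- n_per_group[c("AD", "MCI", "NC")]
  .assert(all(n_per_group >= 1), "every requested group needs at least one subject")
  .assert(n_converters >= 0 && n_converters <= n_per_group[["MCI"]],
          "n_converters must be between 0 and n_per_group['MCI']")
  nv <- prod(grid_dims)
  all_idx <- unlist(network_rois, use.names = FALSE)
  .assert(all(all_idx >= 1 & all_idx <= nv), "network ROI voxels fall outside the grid")
  .assert(!anyDuplicated(all_idx), "network ROIs must be disjoint")
  .assert(is.matrix(coupling_by_group) &&
            all(rownames(coupling_by_group) %in% names(network_rois)) &&
            all(c("NC", "MCI_nc", "MCI_c", "AD") %in% colnames(coupling_by_group)),
          "coupling_by_group must be a networks x {NC,MCI_nc,MCI_c,AD} matrix")
  .assert(all(is.finite(coupling_by_group)) && all(coupling_by_group >= 0),
          "coupling weights must be finite and >= 0")
  .assert(noise_sd >= 0, "noise_sd must be nonnegative")
  .assert(n_timepoints >= 2, "need at least 2 timepoints")
  .assert(all(c("global", "wm", "csf") %in% names(confound_amplitudes)),
          "confound_amplitudes must name global, wm, csf")
  structure(list(grid_dims = grid_dims, n_per_group = n_per_group,
                 n_converters = as.integer(n_converters),
                 network_rois = network_rois,
                 coupling_by_group = coupling_by_group,
                 noise_sd = noise_sd,
                 confound_amplitudes = confound_amplitudes[c("global", "wm", "csf")],
                 motion_sd = motion_sd,
                 n_timepoints = as.integer(n_timepoints), tr_s = tr_s,
                 seed = as.integer(seed),
                 age_confounding = age_confounding,
                 regions = regions),
            class = "cohort_spec")
}

# Band-limited unit-variance latent signal (white noise passed through the
# same ideal band-pass used by temporal_clean, then scaled to unit sample SD).
.latent_signal <- function(n, tr_s, low_hz = 0.01, high_hz = 0.08) {
  x <- stats::rnorm(n)
  y <- .fft_bandpass(matrix(x, ncol = 1), tr_s, low_hz, high_hz)[, 1]
  s <- stats::sd(y)
  if (s < .Machine$double.eps) return(rep(0, n))
  y / s
}

#' Generate one subject's BOLD volume and motion trace
#'
#' Generative model: a voxel in network k follows
#' `a_k * s_k + sum_j c_j * g_j + noise_sd * eps`, where `s_k` and the
#' confound signals `g_j` (global, white-matter, CSF) are independent
#' band-limited unit-variance latent signals and `eps` is iid Gaussian.
#' Voxels in the GM slab outside any network receive confounds + noise only;
#' WM and CSF compartment voxels carry their respective confound signal at
#' unit amplitude plus noise (so compartment means recover the confounds).
#' Under this model the expected correlation between two voxels of network k
#' is `a_k^2 / (a_k^2 + sum(c^2) + noise_sd^2)`.
#'
#' @param spec A [cohort_spec()].
#' @param subject_coupling Named numeric vector: coupling weight per network
#'   (names must cover `names(spec$network_rois)`).
#' @param seed Integer seed for this subject's scan.
#' @return List with elements `bold` ([bold4d()]) and `motion`
#'   ([motion_trace()]); deterministic for a fixed seed.
#' @export
generate_bold <- function(spec, subject_coupling, seed) {
  .assert(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  nets <- names(spec$network_rois)
  .assert(all(nets %in% names(subject_coupling)),
          "subject_coupling must name every network in the spec")
  set.seed(as.integer(seed))
  d <- spec$grid_dims
  nt <- spec$n_timepoints
  nv <- prod(d)

  latents <- lapply(nets, function(k) .latent_signal(nt, spec$tr_s))
  names(latents) <- nets
  g_global <- .latent_signal(nt, spec$tr_s)
  g_wm <- .latent_signal(nt, spec$tr_s)
  g_csf <- .latent_signal(nt, spec$tr_s)
  camp <- spec$confound_amplitudes
  confound_sum <- camp[["global"]] * g_global + camp[["wm"]] * g_wm +
    camp[["csf"]] * g_csf

  flat <- matrix(stats::rnorm(nv * nt, sd = spec$noise_sd), nrow = nv, ncol = nt)
  gm_idx <- which(spec$regions$gm)
  wm_idx <- which(spec$regions$wm)
  csf_idx <- which(spec$regions$csf)
  # air voxels keep only a sliver of the noise
  air <- setdiff(seq_len(nv), c(gm_idx, wm_idx, csf_idx))
  if (length(air)) flat[air, ] <- flat[air, ] * 0.1

  flat[gm_idx, ] <- flat[gm_idx, ] +
    rep(confound_sum, each = length(gm_idx))
  for (k in nets) {
    idx <- spec$network_rois[[k]]
    a <- subject_coupling[[k]]
    if (a > 0) flat[idx, ] <- flat[idx, ] + a * rep(latents[[k]], each = length(idx))
  }
  flat[wm_idx, ] <- flat[wm_idx, ] + rep(g_wm, each = length(wm_idx))
  flat[csf_idx, ] <- flat[csf_idx, ] + rep(g_csf, each = length(csf_idx))

  bold <- bold4d(array(flat, c(d, nt)), voxel_size_mm = c(3, 3, 3),
                 tr_s = spec$tr_s)
  steps <- matrix(stats::rnorm(nt * 6, sd = spec$motion_sd), nrow = nt)
  walk <- apply(steps, 2, cumsum)
  motion <- motion_trace(walk[, 1:3, drop = FALSE], walk[, 4:6, drop = FALSE])
  list(bold = bold, motion = motion)
}

# Group score model: means/SDs per group for covariates and instruments,
# parameterized from the three-group summary table shipped with the package.
.score_model <- function() {
  tab <- reference_cohort_table("three_group")
  split(tab, tab$variable)
}

.instrument_ranges <- list(
  MMSE = c(0, 30), MoCA = c(0, 30), CDT = c(0, 3),
  AVLT_I = c(0, 15), AVLT_D = c(0, 15), AVLT_R = c(-5, 15),
  age = c(40, 95), education = c(0, 25)
)

.draw_score <- function(model_rows, group, n, varname) {
  row <- model_rows[model_rows$group == group, ]
  x <- stats::rnorm(n, mean = row$mean, sd = row$sd)
  rng <- .instrument_ranges[[varname]]
  if (!is.null(rng)) x <- pmin(pmax(x, rng[1]), rng[2])
  x
}

#' Generate a full synthetic cohort
#'
#' Draws the subject table (demographics and instrument scores from
#' group-specific normal models parameterized to the shipped three-group
#' summary table), then one BOLD scan, motion trace and GM probability map
#' per subject. Converters receive the lowest coupling in both planted
#' networks per `spec$coupling_by_group`.
#'
#' @param spec A [cohort_spec()].
#' @return List with elements:
#'   \describe{
#'     \item{subjects}{data.frame: id, group, mci_subgroup, age, sex,
#'       education, MMSE, MoCA, CDT, AVLT_I, AVLT_D, AVLT_R.}
#'     \item{bold}{list of [bold4d()] per subject.}
#'     \item{motion}{list of [motion_trace()] per subject.}
#'     \item{gm_maps}{list of 3D GM probability arrays per subject.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
generate_cohort <- function(spec) {
  .assert(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  n <- spec$n_per_group
  groups <- rep(c("AD", "MCI", "NC"), times = n)
  n_tot <- sum(n)
  subgroup <- rep("not_applicable", n_tot)
  mci_rows <- which(groups == "MCI")
  subgroup[mci_rows] <- c(rep("converter", spec$n_converters),
                          rep("nonconverter", n[["MCI"]] - spec$n_converters))
  eff_group <- groups
  eff_group[subgroup == "converter"] <- "MCI_c"
  eff_group[subgroup == "nonconverter"] <- "MCI_nc"

  set.seed(derive_seed(spec$seed, "cohort", "subjects"))
  model <- .score_model()
  sex_p_male <- c(AD = 9 / 25, MCI = 14 / 31, NC = 15 / 42)
  subjects <- data.frame(
    id = sprintf("S%03d", seq_len(n_tot)),
    group = groups, mci_subgroup = subgroup,
    stringsAsFactors = FALSE
  )
  draw_all <- function(varname) {
    out <- numeric(n_tot)
    for (g in c("AD", "MCI", "NC")) {
      rows <- which(groups == g)
      out[rows] <- .draw_score(model[[varname]], g, length(rows), varname)
    }
    out
  }
  subjects$age <- round(draw_all("age"), 1)
  subjects$sex <- ifelse(stats::runif(n_tot) < sex_p_male[groups], "M", "F")
  subjects$education <- round(draw_all("education"), 1)
  for (v in c("MMSE", "MoCA", "CDT", "AVLT_I", "AVLT_D", "AVLT_R")) {
    subjects[[v]] <- round(draw_all(v), 1)
  }

  nets <- names(spec$network_rois)
  bold <- vector("list", n_tot)
  motion <- vector("list", n_tot)
  gm_maps <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    coupling <- spec$coupling_by_group[nets, eff_group[i]]
    names(coupling) <- nets
    if (spec$age_confounding > 0) {
      g <- groups[i]
      row <- model[["age"]][model[["age"]]$group == g, ]
      age_z <- (subjects$age[i] - row$mean) / row$sd
      coupling <- pmax(coupling * (1 - spec$age_confounding * age_z), 0.05)
    }
    sub <- generate_bold(spec, coupling,
                         seed = derive_seed(spec$seed, "cohort", "scan", i))
    bold[[i]] <- sub$bold
    motion[[i]] <- sub$motion
    set.seed(derive_seed(spec$seed, "cohort", "gm_map", i))
    pr <- array(0.02, spec$grid_dims)
    pr[spec$regions$gm] <- 0.9
    pr <- pmin(pmax(pr + stats::rnorm(length(pr), sd = 0.03), 0), 1)
    pr[unlist(spec$network_rois, use.names = FALSE)] <-
      pmax(pr[unlist(spec$network_rois, use.names = FALSE)], 0.6)
    gm_maps[[i]] <- pr
  }
  list(subjects = subjects, bold = bold, motion = motion, gm_maps = gm_maps,
       spec = spec)
}

#' Load the shipped demographic/clinical summary tables
#'
#' Printed group summary statistics (mean, SD, n per variable and group) for
#' the three diagnostic groups and for the MCI converter/nonconverter
#' subgroups, shipped as plain TSV. They parameterize the synthetic score
#' model and serve as inputs to the summary-statistic group tests.
#'
#' @param which `"three_group"` or `"mci_subgroup"`.
#' @return data.frame.
#' @export
reference_cohort_table <- function(which = c("three_group", "mci_subgroup")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0(which, "_summary.tsv"),
                   package = "fcstrength", mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE)
}
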