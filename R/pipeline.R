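#' Analysis configuration
#'
#' Bundles every pipeline parameter: the cohort spec, band edges, GM cutoff,
#' FCS correlation threshold, cluster-forming p and corrected alpha,
#' smoothing FWHM for the null simulator, covariate names, classifier
#' settings, the master seed and the output directory.
#'
#' @param cohort A [cohort_spec()].
#' @param low_hz,high_hz Band-pass edges, Hz.
#' @param gm_cutoff GM mask probability cutoff.
#' @param r_threshold FCS correlation threshold.
#' @param voxel_p Cluster-forming voxelwise p.
#' @param alpha Corrected familywise alpha.
#' @param fwhm_mm Smoothness of the Monte-Carlo null fields, mm.
#' @param connectivity Cluster connectivity (6/18/26).
#' @param cluster_iterations Null iterations for the extent threshold.
#' @param covariates Subject-table columns used as nuisance covariates.
#' @param classifier List with `kernel` and `cost`.
#' @param behavior_score Instrument column for the behavior association map.
#' @param seed Master pipeline seed (stage seeds derived via
#'   [derive_seed()]).
#' @param output_dir Directory for artifacts; NULL keeps everything
#'   in memory.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(cohort,
                            low_hz = 0.01, high_hz = 0.08,
                            gm_cutoff = 0.2, r_threshold = 0.2,
                            voxel_p = 0.05, alpha = 0.05,
                            fwhm_mm = 4, connectivity = 18,
                            cluster_iterations = 1000,
                            covariates = c("age", "sex"),
                            classifier = list(kernel = "linear", cost = 1),
                            behavior_score = "MMSE",
                            seed = 1L, output_dir = NULL) {
  .assert(inherits(cohort, "cohort_spec"), "cohort must be a cohort_spec")
  .assert(r_threshold > 0 && r_threshold < 1, "r_threshold must be in (0, 1)")
  .assert(voxel_p > 0 && voxel_p < 1 && alpha > 0 && alpha <= 1,
          "voxel_p and alpha must lie in (0, 1)")
  structure(list(cohort = cohort, low_hz = low_hz, high_hz = high_hz,
                 gm_cutoff = gm_cutoff, r_threshold = r_threshold,
                 voxel_p = voxel_p, alpha = alpha, fwhm_mm = fwhm_mm,
                 connectivity = connectivity,
                 cluster_iterations = cluster_iterations,
                 covariates = covariates, classifier = classifier,
                 behavior_score = behavior_score,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "analysis_config")
}

.covariates_from_subjects <- function(subjects, covariates) {
  if (!length(covariates)) return(NULL)
  cols <- lapply(covariates, function(v) {
    x <- subjects[[v]]
    if (v == "sex") as.numeric(x == "M") else as.numeric(x)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- covariates
  out
}

.roi_to_mask <- function(idx, dims) {
  m <- array(FALSE, dims)
  m[idx] <- TRUE
  m
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end reproduction of the analysis: cohort generation, temporal
#' preprocessing, voxelwise FCS, ANCOVA group F map with Monte-Carlo
#' cluster-extent correction, covariate-adjusted post-hoc t maps, the
#' converter-vs-nonconverter t map (restricted to the AD-vs-control
#' significant region), seed-based connectivity maps for the two largest
#' converter-deficit clusters, a behavior association map, LOOCV SVM
#' discrimination of converters from nonconverters, and the robustness
#' suite. When `config$output_dir` is set, artifacts are written (NIfTI
#' volumes, TSV tables, JSON reports) and a manifest with per-file MD5
#' hashes and all seeds is emitted.
#'
#' @param config An [analysis_config()].
#' @param verbose Print stage progress to stderr.
#' @return List with elements `cohort`, `gm`, `fcs_maps`, `ancova`,
#'   `cluster_threshold`, `group_clusters`, `posthoc`, `converter`,
#'   `seed_fc`, `behavior`, `classification`, `validation`, `manifest`.
#' @export
run_full_analysis <- function(config, verbose = TRUE) {
  .assert(inherits(config, "analysis_config"), "config must be an analysis_config")
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  out_dir <- config$output_dir
  artifacts <- list()
  emit <- function(name, path) {
    artifacts[[name]] <<- path
    path
  }
  odir <- function(...) {
    p <- file.path(out_dir, ...)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    p
  }
  writing <- !is.null(out_dir)
  spec <- config$cohort

  say("stage: cohort (seed %d)", spec$seed)
  cohort <- generate_cohort(spec)
  n_sub <- nrow(cohort$subjects)
  if (writing) {
    emit("subjects", write_subjects_tsv(cohort$subjects, odir("subjects.tsv")))
    emit("cohort_spec", save_cohort_spec(spec, odir("cohort_spec.yaml")))
  }

  say("stage: gm mask")
  gm <- group_gm_mask(cohort$gm_maps, cutoff = config$gm_cutoff)
  if (writing)
    emit("gm_mask", write_volume_nifti(gm$include, odir("gm_mask.nii.gz")))

  say("stage: preprocessing (%d subjects)", n_sub)
  cleaned <- vector("list", n_sub)
  mean_fd <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    cleaned[[i]] <- preprocess_subject(cohort$bold[[i]], cohort$motion[[i]],
                                       gm, spec$regions$wm, spec$regions$csf,
                                       config$low_hz, config$high_hz, gsr = TRUE)
    mean_fd[i] <- framewise_displacement(cohort$motion[[i]])$mean_fd_mm
  }

  say("stage: FCS (r > %.2g)", config$r_threshold)
  fcs_maps <- lapply(cleaned, compute_fcs, mask = gm,
                     r_threshold = config$r_threshold)
  if (writing) {
    for (i in seq_len(n_sub)) {
      emit(paste0("fcs_", cohort$subjects$id[i]),
           write_volume_nifti(fcs_maps[[i]]$values,
                              odir("fcs", paste0(cohort$subjects$id[i], ".nii.gz"))))
    }
  }

  say("stage: ANCOVA group F map")
  covs <- .covariates_from_subjects(cohort$subjects, config$covariates)
  ancova <- ancova_f_map(fcs_maps, cohort$subjects$group, covs, mask = gm$include)

  say("stage: cluster-extent threshold (%d iterations)", config$cluster_iterations)
  alphasim_seed <- derive_seed(config$seed, "alphasim")
  thr <- estimate_cluster_extent_threshold(
    gm, fwhm_mm = config$fwhm_mm, voxel_p = config$voxel_p,
    alpha = config$alpha, n_iterations = config$cluster_iterations,
    connectivity = config$connectivity, seed = alphasim_seed)
  f_cut <- stats::qf(1 - config$voxel_p, ancova$df[1], ancova$df[2])
  group_clusters <- extract_clusters(ancova, f_cut, thr$min_extent_voxels,
                                     config$connectivity)
  group_sig <- group_clusters$labels > 0L
  if (writing) {
    emit("ancova_f", write_volume_nifti(ancova$values, odir("stats", "ancova_f.nii.gz")))
    emit("cluster_threshold",
         {p <- odir("cluster_threshold.json")
          jsonlite::write_json(thr[c("min_extent_voxels", "min_extent_mm3",
                                     "voxel_p", "alpha", "fwhm_mm",
                                     "n_iterations", "connectivity")],
                               p, auto_unbox = TRUE); p})
    emit("group_clusters",
         {p <- odir("stats", "group_clusters.tsv")
          utils::write.table(group_clusters$clusters, p, sep = "\t",
                             row.names = FALSE, quote = FALSE); p})
  }

  say("stage: post-hoc t maps (%d significant voxels)", sum(group_sig))
  grp <- cohort$subjects$group
  pairs <- list(AD_vs_NC = c("AD", "NC"), MCI_vs_NC = c("MCI", "NC"),
                AD_vs_MCI = c("AD", "MCI"))
  posthoc <- list()
  restrict <- if (any(group_sig)) group_sig else gm$include
  for (nm in names(pairs)) {
    a <- which(grp == pairs[[nm]][1]); b <- which(grp == pairs[[nm]][2])
    posthoc[[nm]] <- posthoc_t_map(fcs_maps[a], fcs_maps[b],
                                   covariates = rbind(covs[a, , drop = FALSE],
                                                      covs[b, , drop = FALSE]),
                                   restrict_mask = restrict)
    if (writing)
      emit(paste0("t_", nm),
           write_volume_nifti(posthoc[[nm]]$values,
                              odir("stats", paste0(nm, "_t.nii.gz"))))
  }

  say("stage: converter vs nonconverter t map")
  ad_nc <- extract_clusters(posthoc$AD_vs_NC,
                            stats::qt(1 - config$voxel_p / 2, posthoc$AD_vs_NC$df),
                            thr$min_extent_voxels, config$connectivity,
                            two_sided = TRUE)
  conv_restrict <- if (any(ad_nc$labels > 0L)) ad_nc$labels > 0L else restrict
  conv_i <- which(cohort$subjects$mci_subgroup == "converter")
  nonc_i <- which(cohort$subjects$mci_subgroup == "nonconverter")
  converter_t <- posthoc_t_map(fcs_maps[conv_i], fcs_maps[nonc_i],
                               covariates = rbind(covs[conv_i, , drop = FALSE],
                                                  covs[nonc_i, , drop = FALSE]),
                               restrict_mask = conv_restrict)
  conv_clusters <- extract_clusters(converter_t,
                                    stats::qt(1 - config$voxel_p / 2, converter_t$df),
                                    thr$min_extent_voxels, config$connectivity,
                                    two_sided = TRUE)
  if (writing) {
    emit("t_converter", write_volume_nifti(converter_t$values,
                                           odir("stats", "converter_t.nii.gz")))
    emit("converter_clusters",
         {p <- odir("stats", "converter_clusters.tsv")
          utils::write.table(conv_clusters$clusters, p, sep = "\t",
                             row.names = FALSE, quote = FALSE); p})
  }

  say("stage: seed-based connectivity (%d converter clusters)",
      nrow(conv_clusters$clusters))
  mci_i <- c(conv_i, nonc_i)
  seed_fc <- list()
  n_seeds <- min(2L, nrow(conv_clusters$clusters))
  for (s in seq_len(n_seeds)) {
    seed_mask <- conv_clusters$labels == conv_clusters$clusters$id[s]
    seed_name <- sprintf("converter_cluster_%d", s)
    maps <- lapply(mci_i, function(i) {
      seed_fc_map(cleaned[[i]], seed_timecourse(cleaned[[i]], seed_mask),
                  gm, positive_only = TRUE, seed_name = seed_name)
    })
    pos_any <- Reduce(`|`, lapply(maps, function(m) m$analysis_mask))
    tmap <- posthoc_t_map(maps[seq_along(conv_i)],
                          maps[seq_along(nonc_i) + length(conv_i)],
                          covariates = rbind(covs[conv_i, , drop = FALSE],
                                             covs[nonc_i, , drop = FALSE]),
                          restrict_mask = pos_any)
    seed_fc[[seed_name]] <- list(seed_mask = seed_mask, maps = maps, t_map = tmap)
    if (writing)
      emit(paste0("seedfc_t_", s),
           write_volume_nifti(tmap$values, odir("stats", paste0(seed_name, "_t.nii.gz"))))
  }

  say("stage: behavior association (%s)", config$behavior_score)
  pat_i <- which(grp %in% c("AD", "MCI"))
  behavior <- behavior_association_map(
    fcs_maps[pat_i], cohort$subjects[[config$behavior_score]][pat_i],
    covariates = covs[pat_i, , drop = FALSE],
    mask = if (any(group_sig)) group_sig else gm$include)
  if (writing)
    emit("behavior_t", write_volume_nifti(behavior$values,
                                          odir("stats", "behavior_t.nii.gz")))

  say("stage: LOOCV SVM")
  feat_mask <- if (any(conv_clusters$labels > 0L)) {
    conv_clusters$labels > 0L
  } else if (any(abs(converter_t$values) > 2 & converter_t$mask)) {
    abs(converter_t$values) > 2 & converter_t$mask
  } else {
    .roi_to_mask(unlist(spec$network_rois, use.names = FALSE), spec$grid_dims) &
      gm$include
  }
  features <- extract_features(fcs_maps[mci_i], feat_mask)
  for (s in seq_along(seed_fc)) {
    sf <- seed_fc[[s]]
    sig <- extract_clusters(sf$t_map, stats::qt(1 - config$voxel_p / 2, sf$t_map$df),
                            thr$min_extent_voxels, config$connectivity,
                            two_sided = TRUE)
    if (any(sig$labels > 0L))
      features <- cbind(features, extract_features(sf$maps, sig$labels > 0L))
  }
  labels <- cohort$subjects$mci_subgroup[mci_i]
  classification <- loocv_svm(features, labels, positive = "converter",
                              kernel = config$classifier$kernel,
                              cost = config$classifier$cost)
  if (writing)
    emit("classification",
         {p <- odir("classification.json")
          jsonlite::write_json(list(confusion = classification$confusion,
                                    accuracy = classification$accuracy,
                                    sensitivity = classification$sensitivity,
                                    specificity = classification$specificity,
                                    predicted = classification$predicted),
                               p, auto_unbox = TRUE, digits = NA); p})

  say("stage: robustness suite")
  validation <- run_validation_suite(cohort, gm_cutoff = config$gm_cutoff,
                                     low_hz = config$low_hz,
                                     high_hz = config$high_hz)
  if (writing)
    emit("validation",
         {p <- odir("validation.tsv")
          utils::write.table(as.data.frame(validation), p, sep = "\t",
                             row.names = FALSE, quote = FALSE); p})

  manifest <- list(
    seeds = list(master = config$seed, cohort = spec$seed,
                 alphasim = alphasim_seed),
    parameters = config[c("low_hz", "high_hz", "gm_cutoff", "r_threshold",
                          "voxel_p", "alpha", "fwhm_mm", "connectivity",
                          "cluster_iterations", "behavior_score")],
    n_subjects = n_sub,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = list(clipped_correlations = sum(vapply(fcs_maps, `[[`, 0, "n_clipped")),
                    dropped_voxels = sum(vapply(fcs_maps, `[[`, 0, "n_dropped")))
  )
  if (writing) {
    paths <- unlist(artifacts)
    manifest$artifacts <- data.frame(name = names(paths), path = unname(paths),
                                     md5 = unname(tools::md5sum(paths)))
    mpath <- odir("manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  }
  say("pipeline complete (%.1f s)", manifest$elapsed_s)
  list(cohort = cohort, gm = gm, fcs_maps = fcs_maps, ancova = ancova,
       cluster_threshold = thr, group_clusters = group_clusters,
       posthoc = posthoc, converter = list(t_map = converter_t,
                                           clusters = conv_clusters),
       seed_fc = seed_fc, behavior = behavior,
       classification = classification, validation = validation,
       manifest = manifest)
}
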