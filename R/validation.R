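# One correlation pass, several thresholds: returns a (mask voxels) x
# (thresholds) matrix of Fisher-z FCS sums. Results are identical to calling
# compute_fcs once per threshold (tested), but the expensive crossprod is
# done once.
.fcs_multi_threshold <- function(bold, mask, thresholds, block_size = 512L) {
  if (inherits(mask, "gm_mask")) mask <- mask$include
  X <- bold_matrix(bold, mask)
  idx <- attr(X, "voxel_index")
  Xs <- .standardize_columns(X)
  zero <- attr(Xs, "zero_variance")
  if (any(zero)) {
    Xs <- Xs[, !zero, drop = FALSE]
    idx <- idx[!zero]
  }
  n <- ncol(Xs)
  vals <- matrix(0, n, length(thresholds))
  clip <- .r_clip
  for (start in seq(1L, n, by = block_size)) {
    cols <- start:min(start + block_size - 1L, n)
    r <- crossprod(Xs[, cols, drop = FALSE], Xs)
    r[cbind(seq_along(cols), cols)] <- 0
    z <- atanh(pmin(pmax(r, -clip), clip))
    for (j in seq_along(thresholds)) {
      vals[cols, j] <- rowSums(z * (r > thresholds[j]))
    }
  }
  list(values = vals, voxel_index = idx)
}

#' Robustness suite for the converter-vs-nonconverter FCS comparison
#'
#' Re-runs the MCI converter vs nonconverter ROI comparison under three
#' robustness axes: (i) FCS correlation thresholds 0.1 / 0.2 / 0.3, (ii)
#' mean framewise displacement added as a nuisance covariate, and (iii)
#' global signal regression switched off. The ROI-level test compares the
#' mean FCS within each ROI between the two MCI subgroups via a linear model
#' with age and sex (and optionally mean FD) as covariates; the reported t
#' is for the converter-minus-nonconverter coefficient (fixed sign
#' convention). The threshold sweep reuses a single correlation pass per
#' subject.
#'
#' @param cohort A [generate_cohort()] result (or a list with the same
#'   `subjects`, `bold`, `motion`, `gm_maps`, `spec` fields).
#' @param roi_masks Named list of 3D logical ROI masks; defaults to the
#'   spec's planted networks.
#' @param variants Character vector of variant ids among
#'   `"thr_0.1"`, `"thr_0.2"`, `"thr_0.3"`, `"fd_covariate"`, `"no_gsr"`.
#' @param gm_cutoff GM mask cutoff for [group_gm_mask()].
#' @param low_hz,high_hz Band-pass edges.
#' @return Object of class `validation_report`: a data.frame with one row
#'   per (variant, ROI): variant_id, r_threshold, fd_covariate, gsr, roi,
#'   roi_t, roi_p; the converter/nonconverter mean-FD comparison p value is
#'   attached as attribute `"group_fd_p"`.
#' @export
run_validation_suite <- function(cohort, roi_masks = NULL,
                                 variants = c("thr_0.1", "thr_0.2", "thr_0.3",
                                              "fd_covariate", "no_gsr"),
                                 gm_cutoff = 0.2,
                                 low_hz = 0.01, high_hz = 0.08) {
  known <- c("thr_0.1", "thr_0.2", "thr_0.3", "fd_covariate", "no_gsr")
  bad <- setdiff(variants, known)
  .assert(length(bad) == 0, paste0("unknown variant id(s): ", paste(bad, collapse = ", ")))
  spec <- cohort$spec
  mci <- which(cohort$subjects$group == "MCI")
  .assert(length(mci) >= 4L, "need MCI subjects of both subgroups")
  sub <- cohort$subjects[mci, ]
  .assert(all(c("converter", "nonconverter") %in% sub$mci_subgroup),
          "both MCI subgroups must be present")
  if (is.null(roi_masks)) {
    roi_masks <- lapply(spec$network_rois, function(idx) {
      m <- array(FALSE, spec$grid_dims)
      m[idx] <- TRUE
      m
    })
  }
  .assert(all(vapply(roi_masks, sum, numeric(1)) >= 1), "empty ROI mask")
  gm <- group_gm_mask(cohort$gm_maps[mci], cutoff = gm_cutoff)
  wm_mask <- spec$regions$wm
  csf_mask <- spec$regions$csf
  thresholds <- c(0.1, 0.2, 0.3)

  mean_fd <- vapply(mci, function(i) {
    framewise_displacement(cohort$motion[[i]])$mean_fd_mm
  }, numeric(1))
  conv <- as.numeric(sub$mci_subgroup == "converter")
  covs_base <- cbind(age = sub$age, sex = as.numeric(sub$sex == "M"))

  # ROI-mean FCS per subject, per preprocessing variant, per threshold
  roi_means <- function(gsr) {
    out <- array(NA_real_, c(length(mci), length(roi_masks), length(thresholds)),
                 dimnames = list(NULL, names(roi_masks), paste0("thr_", thresholds)))
    for (s in seq_along(mci)) {
      i <- mci[s]
      cleaned <- preprocess_subject(cohort$bold[[i]], cohort$motion[[i]], gm,
                                    wm_mask, csf_mask, low_hz, high_hz, gsr = gsr)
      fcs <- .fcs_multi_threshold(cleaned, gm, thresholds)
      for (rj in seq_along(roi_masks)) {
        roi_idx <- which(roi_masks[[rj]] & gm$include)
        pos <- match(roi_idx, fcs$voxel_index)
        pos <- pos[!is.na(pos)]
        out[s, rj, ] <- colMeans(fcs$values[pos, , drop = FALSE])
      }
    }
    out
  }

  need_gsr_on <- any(variants %in% c("thr_0.1", "thr_0.2", "thr_0.3", "fd_covariate"))
  rm_on <- if (need_gsr_on) roi_means(TRUE) else NULL
  rm_off <- if ("no_gsr" %in% variants) roi_means(FALSE) else NULL

  roi_test <- function(y, covs) {
    fit <- stats::lm(y ~ covs + conv)
    co <- summary(fit)$coefficients
    c(t = co["conv", "t value"], p = co["conv", "Pr(>|t|)"])
  }

  rows <- list()
  for (v in variants) {
    thr <- switch(v, thr_0.1 = 0.1, thr_0.3 = 0.3, 0.2)
    gsr <- v != "no_gsr"
    fdc <- v == "fd_covariate"
    rmat <- if (gsr) rm_on else rm_off
    covs <- if (fdc) cbind(covs_base, mean_fd = mean_fd) else covs_base
    for (rj in names(roi_masks)) {
      res <- roi_test(rmat[, rj, paste0("thr_", thr)], covs)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = v, r_threshold = thr, fd_covariate = fdc, gsr = gsr,
        roi = rj, roi_t = unname(res["t"]), roi_p = unname(res["p"]))
    }
  }
  report <- do.call(rbind, rows)
  fd_test <- stats::t.test(mean_fd[conv == 1], mean_fd[conv == 0])
  attr(report, "group_fd_p") <- fd_test$p.value
  class(report) <- c("validation_report", class(report))
  report
}
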