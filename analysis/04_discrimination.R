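#!/usr/bin/env Rscript
# LOOCV SVM discrimination of MCI converters from nonconverters.
#
# Features are the FCS values at voxels showing a corrected
# converter-vs-nonconverter difference (falling back to uncorrected |t| > 2
# voxels when no cluster survives at this scale). A linear SVM (C = 1) is
# evaluated by leave-one-out cross-validation with per-fold feature
# standardization; performance is reported as accuracy / sensitivity /
# specificity from the pooled confusion counts.

source(file.path("analysis", "config.R"))

st <- demo_connectivity_state()
co <- st$cohort; sp <- st$spec; gm <- st$gm
covs <- demo_covariates(co$subjects)

conv <- which(co$subjects$mci_subgroup == "converter")
nonc <- which(co$subjects$mci_subgroup == "nonconverter")
mci <- c(conv, nonc)

tmap <- posthoc_t_map(st$fcs[conv], st$fcs[nonc],
                      covariates = rbind(covs[conv, ], covs[nonc, ]),
                      restrict_mask = gm$include)
thr <- estimate_cluster_extent_threshold(
  gm, fwhm_mm = 4, voxel_p = 0.05, alpha = 0.05, n_iterations = 1000,
  connectivity = 18, seed = derive_seed(MASTER_SEED, "alphasim"))
ct <- extract_clusters(tmap, qt(0.975, tmap$df), thr$min_extent_voxels, 18,
                       two_sided = TRUE)
feat_mask <- if (nrow(ct$clusters)) ct$labels > 0L else
  abs(tmap$values) > 2 & tmap$mask
cat(sprintf("Feature mask: %d voxels (%s)\n", sum(feat_mask),
            if (nrow(ct$clusters)) "corrected clusters" else "uncorrected |t| > 2"))

X <- extract_features(st$fcs[mci], feat_mask)
res <- loocv_svm(X, co$subjects$mci_subgroup[mci], positive = "converter")
print(res)

jsonlite::write_json(
  list(n_features = ncol(X), confusion = res$confusion,
       accuracy = res$accuracy, sensitivity = res$sensitivity,
       specificity = res$specificity, predicted = res$predicted),
  file.path(RESULTS_DIR, "classification.json"), auto_unbox = TRUE, digits = NA)
cat("Wrote", file.path(RESULTS_DIR, "classification.json"), "\n")
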