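#!/usr/bin/env Rscript
# Temporal preprocessing and voxelwise functional connectivity strength.
#
# Each scan is linearly detrended, band-pass filtered to 0.01-0.08 Hz, and
# cleaned of the six motion parameters plus global / WM / CSF confound
# series. FCS is the per-voxel sum of Fisher-z connectivity over GM
# connections with r > 0.2. Writes per-group mean FCS inside and outside
# the planted networks.

source(file.path("analysis", "config.R"))

st <- demo_connectivity_state()
co <- st$cohort; sp <- st$spec; gm <- st$gm

cat("GM mask:", sum(gm$include), "voxels (cutoff 0.2 on the mean map)\n")

eff <- ifelse(co$subjects$mci_subgroup == "converter", "MCI-c",
              ifelse(co$subjects$mci_subgroup == "nonconverter", "MCI-nc",
                     co$subjects$group))
rows <- list()
for (net in names(sp$network_rois)) {
  roi <- sp$network_rois[[net]]
  roi_mean <- vapply(st$fcs, function(f) mean(f$values[roi]), numeric(1))
  for (g in unique(eff)) {
    rows[[length(rows) + 1L]] <- data.frame(
      network = net, group = g, n = sum(eff == g),
      mean_fcs = mean(roi_mean[eff == g]), sd_fcs = sd(roi_mean[eff == g]))
  }
}
tab <- do.call(rbind, rows)
tab <- tab[order(tab$network, -tab$mean_fcs), ]
write.table(tab, file.path(RESULTS_DIR, "roi_fcs_by_group.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("\nGroup-mean FCS inside the planted networks (sum of Fisher-z):\n")
print(tab, row.names = FALSE, digits = 4)
cat("\nExpected ordering NC > MCI-nc > MCI-c within each network;",
    "AD lowest, matching the graded coupling.\n")
cat("Wrote", file.path(RESULTS_DIR, "roi_fcs_by_group.tsv"), "\n")
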