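# Shared configuration for the analysis scripts. Sourced by every numbered
# driver; all state is regenerated deterministically from the seeds here, so
# the scripts can be run independently and in any order.

library(fcstrength)

MASTER_SEED <- 42L
RESULTS_DIR <- file.path("results", "analysis")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# Desk-scale cohort: same structure as the clinical sample (three groups,
# MCI split into converters/nonconverters ~2:1), scaled down so the
# all-pairs correlation stage runs in seconds.
demo_spec <- function() {
  cohort_spec(grid_dims = c(14, 14, 10),
              n_per_group = c(AD = 10, MCI = 12, NC = 14),
              n_converters = 8,
              n_timepoints = 120,
              seed = MASTER_SEED)
}

demo_config <- function(output_dir = NULL) {
  analysis_config(demo_spec(), cluster_iterations = 1000,
                  seed = MASTER_SEED, output_dir = output_dir)
}

# Rebuild the preprocessed cohort + FCS maps (deterministic from the seed).
demo_connectivity_state <- function() {
  sp <- demo_spec()
  co <- generate_cohort(sp)
  gm <- group_gm_mask(co$gm_maps, cutoff = 0.2)
  n <- nrow(co$subjects)
  cleaned <- vector("list", n)
  for (i in seq_len(n)) {
    cleaned[[i]] <- preprocess_subject(co$bold[[i]], co$motion[[i]], gm,
                                       sp$regions$wm, sp$regions$csf)
  }
  fcs <- lapply(cleaned, compute_fcs, mask = gm, r_threshold = 0.2)
  list(spec = sp, cohort = co, gm = gm, cleaned = cleaned, fcs = fcs)
}

demo_covariates <- function(subjects) {
  cbind(age = subjects$age, sex = as.numeric(subjects$sex == "M"))
}
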