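# fcstrength

Voxelwise functional connectivity strength (FCS) analysis of resting-state
fMRI for the study of conversion from mild cognitive impairment (MCI) to
Alzheimer's disease (AD).

MCI patients are at high risk of progressing to AD, and resting-state
functional connectivity — in particular in default-mode and occipital
territory — degrades along that trajectory. This package implements, as a
tested and reproducible pipeline, the full analysis such a study requires:

* a **synthetic cohort generator** (three diagnostic groups plus MCI
  converter/nonconverter subgroups, planted network coupling graded
  NC > MCI-nc > MCI-c, shared confound signals, motion traces, covariates
  and instrument scores), so every stage is testable without clinical data;
* **temporal preprocessing**: linear detrend, ideal band-pass
  (0.01–0.08 Hz), nuisance regression (six motion parameters + global /
  white-matter / CSF signals), framewise displacement (Power formulation),
  group gray-matter masking (probability cutoff 0.2);
* **connectivity mapping**: voxelwise FCS and seed-based Fisher-z
  correlation maps;
* **group inference**: voxelwise ANCOVA partial-F and covariate-adjusted
  t maps, plus closed-form one-way ANOVA F and pooled two-sample t from
  printed summary statistics;
* **Monte-Carlo cluster-extent correction** (AlphaSim-style null
  simulation) with empirical familywise-error calibration;
* **discrimination**: leave-one-out cross-validated linear SVM separating
  converters from nonconverters, with exact confusion-matrix metrics;
* a **robustness suite** re-running the converter comparison across
  correlation thresholds {0.1, 0.2, 0.3}, with a framewise-displacement
  covariate, and without global signal regression.

The central statistic: for gray-matter voxel $i$,

$$\mathrm{FCS}(i) \;=\; \sum_{j \neq i,\; r_{ij} > 0.2} \operatorname{arctanh}(r_{ij}),$$

the sum of Fisher-z transformed Pearson correlations over all suprathreshold
connections of voxel $i$ within the gray-matter mask — a weighted
degree-centrality measure. Group effects on FCS are tested voxelwise with
age and sex as covariates and corrected by the minimum cluster extent whose
occurrence probability under smooth Gaussian null fields is below 0.05.

## Worked example

The numbered drivers under `analysis/` run the complete study on a
desk-scale synthetic cohort (36 subjects, 14×14×10 grid, 120 frames,
seed 42) and write their tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_preprocess_connectivity.R
Rscript analysis/03_group_inference.R
Rscript analysis/04_discrimination.R
Rscript analysis/05_validation.R
Rscript analysis/06_full_pipeline.R
```

Script 02 prints the group-mean FCS inside the planted networks:

```
   network  group  n mean_fcs sd_fcs
       dmn     NC 14   172.08  7.346
       dmn MCI-nc  4   154.95  7.575
       dmn  MCI-c  8   117.84  8.297
       dmn     AD 10   100.63  6.984
```

— the planted ordering NC > MCI-nc > MCI-c > AD, recovered from the raw
synthetic scans. Script 03 estimates the corrected cluster extent and
localizes the converter deficit:

```
Cluster-extent threshold: 12 voxels (324 mm3) at voxel P<0.05, alpha 0.05
MCI-c vs MCI-nc: 2 corrected cluster(s)
Largest deficit cluster: 212 voxels, peak t = -8.93, 82% inside a planted network
```

Script 05 shows the deficit's sign is stable across correlation thresholds
and FD adjustment, but vanishes without global signal regression (the
planted global confound buries it):

```
   variant_id r_threshold fd_covariate   gsr       roi  roi_t    roi_p
      thr_0.1         0.1        FALSE  TRUE       dmn -5.991 0.000327
      thr_0.2         0.2        FALSE  TRUE       dmn -6.007 0.000321
      thr_0.3         0.3        FALSE  TRUE       dmn -5.642 0.000486
 fd_covariate         0.2         TRUE  TRUE       dmn -5.484 0.000922
       no_gsr         0.2        FALSE FALSE       dmn  0.812 0.440153
```

Published summary statistics can be checked directly from their printed
means/SDs/ns:

```r
library(fcstrength)
anova_f_from_summary(data.frame(mean = c(16.8, 23.5, 28.0),
                                sd   = c(4.7, 2.9, 2.3),
                                n    = c(25, 31, 42)))$F
#> [1] 93.54238   # MMSE across AD / MCI / NC, F(2, 95)
confusion_metrics(list(tp = 18, fn = 3, tn = 7, fp = 3))$accuracy
#> [1] 0.8064516  # 25/31 converter classification accuracy
```

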