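---
title: "Functional connectivity strength analysis of MCI conversion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectivity strength analysis of MCI conversion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fcstrength` implements a complete voxelwise functional connectivity
strength (FCS) analysis for resting-state BOLD fMRI, aimed at the question
of which connectivity changes distinguish mild cognitive impairment (MCI)
patients who later convert to Alzheimer's disease (AD) from those who do
not. Because no raw clinical data are available for this design, the
package pairs the analysis stack with a first-class synthetic cohort
generator whose statistical structure matches the assumptions of every
downstream stage. This vignette explains the models, the tunable
parameters, the numerical decisions, and what the synthetic experiments do
and do not establish about real data.

## The generative model for synthetic cohorts

A cohort is described by a `cohort_spec()`: a 3D grid (default
24 x 24 x 18 voxels at 3 mm), group sizes (default AD = 25, MCI = 31 with
21 converters, NC = 42, mirroring the clinical sample this design targets),
scan length (default 150 frames at TR = 2 s), and two planted networks — a
bilateral "DMN-like" set of blocks and a posterior "occipital-like" block —
inside a gray-matter slab, with white-matter and CSF slabs above it.

The voxel model is deliberately minimal. A voxel in network $k$ follows

$$x_v(t) = a_k\, s_k(t) + \sum_j c_j\, g_j(t) + \sigma\, \varepsilon_{v}(t),$$

where $s_k$ is a network-specific latent signal, $g_j$ are global /
white-matter / CSF confound signals with amplitudes $c_j$ (defaults 0.4,
0.2, 0.2), and $\varepsilon_v$ is iid Gaussian observation noise
($\sigma = 1$). All latent signals are white noise passed through the same
ideal 0.01–0.08 Hz band-pass used in preprocessing and scaled to unit
variance, so their spectra survive temporal cleaning. Under this model the
expected correlation between two voxels of network $k$ is the closed form

$$r_k = \frac{a_k^2}{a_k^2 + \sum_j c_j^2 + \sigma^2},$$

which the tests exploit as an oracle. Group structure enters only through
the coupling weights $a_k$: the defaults grade them NC (1.0) > MCI-nc
(0.85) > MCI-c (0.65) > AD (0.55) in both networks. No published effect
sizes exist for FCS group gaps, so these weights are free parameters of the
generator, chosen once to produce clearly separated but overlapping group
distributions at desk scale; they are not tuned per experiment.

Two structural choices deserve comment:

* **Network extent.** The planted networks cover roughly a third of the GM
  slab. This is not cosmetic: the FCS of a voxel is a sum over *all* GM
  partners, so chance correlations contribute a background term that grows
  with mask size, and raising a voxel's own variance (stronger coupling)
  *dilutes* its chance correlations with non-network voxels. If the
  networks were tiny, that dilution would dominate the in-network gain and
  coupling increases could paradoxically lower FCS. With realistically
  extended networks — as actual resting-state networks are — the in-network
  term dominates and mean network FCS is monotone in coupling, which is the
  regime the analysis assumes and the tests verify.
* **Motion.** Motion traces are random walks (iid Gaussian steps, default
  SD 0.02) that do not feed back into the BOLD signal. Framewise
  displacement is therefore a pure nuisance variable here; the FD-covariate
  robustness variant checks that including it does not destroy a real
  effect, not that it removes a planted artifact.

Subject covariates (age, sex, education) and instrument scores (MMSE, MoCA,
CDT, AVLT immediate/delayed/recognition) are drawn from group-specific
normal models parameterized by the summary table shipped in
`inst/extdata/`, truncated to instrument ranges. By default age is
independent of coupling; `age_confounding > 0` couples them for
covariate-adjustment experiments.

All randomness flows from the single spec seed through `derive_seed()`, a
keyed hash (polynomial rolling hash modulo $2^{31}-1$) that assigns each
subject and stage its own stream, so any stage can be regenerated in
isolation and identical specs give bit-identical cohorts.

## Temporal preprocessing

`preprocess_subject()` applies, in fixed order: per-voxel linear detrend,
ideal (FFT-mask) band-pass to 0.01–0.08 Hz, and least-squares regression of
nuisance signals (six motion parameters plus global, WM and CSF compartment
means; global signal regression is a toggle). The ideal filter was chosen
because the analysis convention this design follows names no filter family
and rectangular FFT masks are the norm in the REST/DPARSF lineage of
toolboxes. The global mean is taken over the analysis GM mask (toggleable
in principle to whole-brain; the GM mean is the default because the
analysis itself is GM-restricted).

One numerical caveat is worth stating explicitly: a linear detrend and an
ideal band-pass do not commute exactly on a finite window, because a
band-limited signal still has a nonzero fitted linear trend. Swapping the
order of temporal cleaning and nuisance regression (with identically
filtered regressors) therefore reproduces the result only up to a few
percent of the data scale, and the test suite checks commutation at that
fidelity rather than machine precision.

Framewise displacement uses the sum-of-absolute-derivatives form
$FD_i = \sum |\Delta d_i| + r \sum |\Delta \theta_i|$ with an assumed head
radius of $r = 50$ mm and $FD_1 = 0$. The GM group mask includes a voxel
when the mean probability across subjects is $\ge$ the cutoff (default
0.2); the boundary is inclusive, a decision made explicit because
"thresholding" alone does not determine it.

## Functional connectivity strength

For each GM voxel $i$,

$$\mathrm{FCS}(i) = \sum_{j \ne i,\; r_{ij} > \theta} \operatorname{arctanh}(r_{ij}),$$

with $\theta = 0.2$ by default and the comparison strict ("above"
threshold). The field's phrase "sum of the connections" is ambiguous
between summing $z$, summing $r$, or counting connections; the Fisher-z sum
is the default (it is the weighted degree-centrality convention and matches
the variance-stabilizing transform applied elsewhere in the pipeline), and
`statistic = "r_sum"` / `"count"` are provided for sensitivity checks.
Correlations at $|r| = 1$ (exact duplicates can occur in synthetic data)
are clipped to $1 - 10^{-7}$ before `arctanh`; clip events are counted on
the returned object. Zero-variance voxels inside the mask are dropped with
a warning rather than raising an error, since censoring artifacts can zero
a series. Correlation matrices are computed in column blocks (default 512
voxels) so peak memory stays $O(\text{block} \times n)$; the block size
provably does not change the result.

Seed-based maps average the series over a seed region, correlate every GM
voxel with it, and Fisher-transform; the downstream group statistics are
restricted to positive connections (`positive_only`), since negative
connections have ambiguous interpretation after global signal regression.

## Group inference

`ancova_f_map()` computes the per-voxel partial F for the group factor from
nested least-squares fits (full: intercept + covariates + group dummies;
reduced: intercept + covariates), giving $df_1 = G - 1$,
$df_2 = N - G - k$. Partial F from nested residual sums of squares was
preferred over sequential ANOVA because it is unambiguous in the presence
of covariates. Sex enters as a single 0/1 column; no interactions. Post-hoc
and converter comparisons use the t statistic of a group indicator in the
same GLM (sign convention: first group minus second), evaluated inside a
restriction mask. Behavior associations report the score slope and its t;
degenerate perfect fits are capped at $|t| = 10^6$ and counted. The
summary-statistic tests (`anova_f_from_summary()`,
`pooled_t_from_summary()`) implement the closed-form one-way F and the
pooled equal-variance t (df $= n_a + n_b - 2$, the convention matching the
printed degrees of freedom in the subgroup table this design reproduces).

## Monte-Carlo cluster-extent correction

`estimate_cluster_extent_threshold()` is an AlphaSim-style simulator: each
iteration draws an iid Gaussian field on the grid, smooths it (default
FWHM 4 mm, the applied smoothing kernel of the design; estimated smoothness
can be passed but is not computed from data), re-standardizes within the
mask so the voxel threshold maps exactly to a z-quantile, thresholds
two-tailed at `voxel_p`, and records the largest connected component. The
returned extent is the smallest $k$ whose null exceedance fraction is at
most `alpha`. Cluster connectivity defaults to 18 (face + edge), the
rmm ≈ 5 mm convention at 3 mm voxels; 6 and 26 are selectable. For F maps
the map-side threshold is the upper-tail F quantile at `voxel_p` and for t
maps the two-tailed t quantile — both have marginal exceedance probability
`voxel_p`, which is the only property the null extent distribution depends
on, so one simulation serves both. `fwe_calibration()` replays fresh null
fields under an independent seed and reports the observed familywise error;
at `alpha = 0.05` it should fall within binomial error of the nominal rate,
and the acceptance suite requires $\le 0.08$ on 1000 fresh fields.

The specific corrected extents quoted for the original clinical analysis
(1350 / 324 / 216 mm³) are not reproduction targets: they depend on that
study's mask and smoothness estimate, neither of which is available.

## Discrimination and its metrics

`loocv_svm()` trains a linear SVM (C = 1, no class reweighting by default —
a balanced-weights flag exists) on $N-1$ subjects and predicts the held-out
one, for every subject. Feature standardization is fit on each training
fold only; the held-out subject is scaled with the training fold's
statistics, so no test information leaks. Kernel and cost are exposed but
deliberately not searched: the design this follows reports no nested
hyperparameter selection, and none is performed. Metrics follow the exact
ratio definitions (accuracy, sensitivity, specificity from TP/FN/TN/FP
with converters as the positive class). The implementation takes the
definitions literally; for 21 converters and 10 nonconverters the unique
confusion matrix compatible with 80.6% accuracy is (TP, FN, TN, FP) =
(18, 3, 7, 3), whose sensitivity is 85.7% and specificity 70.0% — the
reverse assignment of the two printed companion rates, which are not
integer-consistent under the stated definitions.

## Robustness suite

`run_validation_suite()` re-runs the converter-vs-nonconverter comparison
as a scalar ROI test (mean FCS within each planted network — chosen so each
subject contributes one number per ROI; the voxelwise route remains
available through the group-inference functions) under five variants:
correlation thresholds 0.1 / 0.2 / 0.3, mean FD appended as a covariate,
and GSR off. The threshold sweep reuses a single correlation pass per
subject; the suite asserts this shortcut is numerically identical to
independent recomputation. The FD covariate is the subject's mean FD — a
standard scalar summary, chosen here because the source convention leaves
it unstated. One fixed sign convention (converter minus nonconverter) is
used throughout; a planted deficit therefore appears as a negative t in
every variant.

## Problem sizes and what the tests show

The shipped tests and analysis scripts run at desk scale: grids of
$10^3$–$14^2 \times 10$ voxels (500–1200 GM voxels), 100–150 frames, 20–36
subjects, 200–2000 Monte-Carlo iterations. These sizes were chosen so the
complete suite exercises every stage — including 3000 null-field
simulations for the familywise-error check — in about two minutes of CPU
time, while keeping every statistical property (effect ordering, FWE
control, chance-level classification under label shuffles) measurable with
meaningful Monte-Carlo precision. The default `cohort_spec()` grid is
larger (about 6300 GM voxels) and remains all-pairs tractable thanks to the
blockwise FCS path.

The generator emulates: group-graded network coupling, shared global /
WM / CSF confounds, Gaussian observation noise, random-walk motion, and
covariate distributions matched to the published cohort summaries. It does
not emulate: spatial autocorrelation of the BOLD signal within networks
(voxels share a latent signal but noise is spatially white), scanner
artifacts, slice timing, spatial misregistration, physiological
quasi-periodic noise, motion-coupled signal corruption, or anatomical
heterogeneity. Consequently, passing tests establish the *statistical
machinery* — estimator correctness, type-I control, monotone effect
recovery, leakage-free cross-validation — not the claim that real MCI
converters would be classified with any particular accuracy. The perfect
LOOCV accuracy seen in the demo pipeline reflects the cleanly planted
synthetic effect, and should be read only as evidence that the
discrimination stage recovers a separable signal when one exists.

## Known limitations

* The ideal FFT band-pass assumes (implicitly) circular continuation;
  edge effects are not tapered. For the detrended, band-interior signals
  used here this is benign, but filtered series should not be interpreted
  near the first/last few frames in other contexts.
* The cluster-extent simulator models stationary Gaussian smoothness; it
  inherits AlphaSim's known optimism under heavier-tailed or nonstationary
  real-data noise.
* `anova_f_from_summary()` can only be as accurate as its printed inputs;
  one-decimal summary rounding limits agreement to a few percent for small
  F values (and worse when a group SD is printed as a single coarse digit).
* The SVM stage intentionally performs no feature selection beyond the
  significance mask and no hyperparameter search; with small validation
  samples, reported LOOCV metrics have wide binomial error bars.
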