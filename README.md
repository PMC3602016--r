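# restconn

Resting-state fMRI connectivity analysis combining group independent
component analysis (ICA) with Granger-causal effective connectivity, for
two-condition within-subject designs — the motivating study design is a
cohort of heavy smokers scanned once after overnight abstinence and once
after smoking to satiety. The package is written for methods researchers
who need every stage of such a pipeline as tested, seedable R functions,
together with a synthetic cohort generator with planted ground truth so
that recovery can be *scored*, not just eyeballed.

## What it computes

**Group ICA.** Sessions are temporally concatenated (abstinence block
first), reduced by three-stage PCA, and unmixed by natural-gradient
Infomax with a logistic nonlinearity. Infomax is repeated from 20 random
initializations and stabilized ICASSO-style: components pooled, clustered
by `1 − |spatial correlation|` with average linkage, and each cluster's
centrotype retained with a stability index. Per-subject maps and time
courses come from GICA back-reconstruction through the stored stage
projections. The component count can be estimated by the
minimum-description-length criterion on the covariance eigenspectrum

    MDL(k) = −N (V−k) log( geoMean(λ_{k+1..V}) / mean(λ_{k+1..V}) ) + ½ k (2V−k) log N .

**Functional connectivity statistics.** Voxelwise one-sample t maps per
condition on z-scored subject maps, paired t maps between conditions
(native map scale), Benjamini–Hochberg FDR, connected-component cluster
extraction (26-connectivity, extent ≥ 20 voxels by default), and 27-voxel
ROIs (a peak voxel plus its 26 neighbours, 9×9×9 mm³ at 3 mm).

**Effective connectivity.** For node time series x(t) (network time
courses or ROI BOLD averages), a VAR(p) is fitted by pooled within-segment
least squares — per-subject segments are never concatenated across the
seam — with p chosen by BIC. Directed influence source → target is tested
by the nested-model F statistic

    F = ((RSS_restricted − RSS_full)/p) / (RSS_full/(n − k_full)) ,

evaluated for every ordered pair, FDR-thresholded into a causal graph, and
summarized by out−in degrees (out-degree − in-degree; positive = causal
source, negative = causal target).

**Synthetic cohorts.** `default_truth()` + `make_cohort()` generate a
seeded 21-subject × 2-condition × 150-volume cohort (TR 2 s, 24×28×24 grid
of 3 mm voxels): four Gaussian-blob networks (aDMN, pDMN, ECN, SN) mixed
with stationary VAR(2) time courses, a planted causal difference
(SN → pDMN in abstinence, ECN → SN in satiety, coefficient 0.4), a 20% SN
amplitude increase in abstinence, per-subject amplitude jitter, and
screening metadata (FTND, exhaled CO) matching the reference cohort's
ranges.

## Worked example

```r
library(restconn)

truth  <- default_truth(seed = 1)
cohort <- make_cohort(truth, n_subjects = 21, n_timepoints = 150)
cohort_summary(cohort$subjects, round_digits = 2)
#>     variable  mean   sd  min  max  n
#> 1       ftnd  6.38 1.16  5.0  8.0 21
#> 2 co_abs_ppm 10.70 3.20  4.0 18.2 21
#> 3 co_sat_ppm 25.04 5.56 14.7 37.5 21

## preprocess (detrend; smoothed copy for the spatial analyses) and
## run group ICA with ICASSO, extracting time courses from the
## unsmoothed data
detrended <- lapply(cohort$sessions, prep_session, detrend = TRUE)
sessions  <- lapply(detrended, prep_session, smooth_fwhm_mm = 8)
cond <- vapply(sessions, `[[`, "", "condition")
ord  <- order(match(cond, c("abstinence", "satiety")), names(sessions))
sessions <- sessions[ord]; detrended <- detrended[ord]; cond <- cond[ord]

ica <- group_ica(sessions, n_components = 8, n_runs = 20, seed = 1,
                 tc_sessions = detrended)
m <- match_components(ica$group$maps, truth$sources)
m
#>   network component     score
#> 1    aDMN         3 0.9704028
#> 2    pDMN         1 0.9743031
#> 3     ECN         6 0.9629351
#> 4      SN         2 0.9747958
```

All four planted networks are recovered (spatial correlation ≈ 0.97 —
slightly below 1 because the 8 mm smoothing widens the estimated blobs),
with ICASSO stability ≈ 0.98 for the matched components, and the
back-reconstructed time courses track their generators at |r| ≥ 0.996 in
every session. The network-level causal analysis then recovers the
planted directed difference:

```r
segs <- lapply(ica$subject_timecourses[cond == "abstinence"], function(tc) {
  s <- tc[, m$component]; colnames(s) <- m$network
  standardize(s, "zscore")
})
edges <- pairwise_granger(concatenate_segments(segs), order = "bic",
                          max_order = 5)
build_causal_graph(edges, q = 0.01, condition = "abstinence")
#> <causal_graph> 4 nodes, 1 significant edges at FDR q = 0.01 (abstinence)
#>   SN -> pDMN (F = 278.19)
```

The satiety sessions instead yield exactly `ECN -> SN (F = 279.74)` — the
planted reversal of the salience-network coupling after smoking
replenishment.

The numbered drivers under `analysis/` run this whole study —
simulation, preprocessing, group ICA, voxel statistics with ROI
definition, and both causal analyses — writing their tables under
`results/`.

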