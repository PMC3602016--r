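---
title: "Methods: group ICA and Granger causality for two-condition resting-state fMRI"
author: "restconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group ICA and Granger causality for two-condition resting-state fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

`restconn` implements a combined blind-source-separation and effective-
connectivity framework for resting-state fMRI studies that scan the same
subjects under two conditions — the motivating design is heavy smokers
scanned once after overnight abstinence and once after smoking to satiety.
The framework asks three questions:

1. **Which large-scale networks are present?** Group independent component
   analysis (ICA) over the temporally concatenated cohort yields spatial
   networks — the anterior and posterior default-mode network (aDMN, pDMN,
   "task-negative"), and the executive-control and salience networks
   (ECN, SN, "task-positive") — plus per-subject maps and time courses by
   back-reconstruction.
2. **Where does functional connectivity differ between conditions?**
   Voxelwise one-sample t maps (per condition) and paired t maps (between
   conditions) over the back-reconstructed subject maps, with
   false-discovery-rate (FDR) control, cluster extraction and 27-voxel
   region-of-interest (ROI) definition at cluster peaks.
3. **How do networks and regions drive one another?** Granger causality:
   vector autoregressions (VAR) fitted to network time courses and to ROI
   BOLD averages, pairwise F-tests for directed influence, FDR-thresholded
   causal graphs and out−in degree summaries.

Because no public accession exists for data of this design, the package is
organized around a seeded synthetic cohort generator with planted ground
truth, so that every stage can be exercised and *scored* rather than only
run.

## Generative model of the synthetic cohort

A session is the linear mixture

$$ y(v, t) = \sum_{k} a_k \, s_k(v)\, x_k(t) + \varepsilon(v,t), \qquad
\varepsilon \sim \mathcal N(0, \sigma^2), $$

with $s_k$ the spatial source of network $k$ (a sum of two isotropic
Gaussian blobs at fixed documented centres), $x_k$ its time course, and
$a_k$ an amplitude factor. This is exactly the model under which spatial
ICA is identifiable, plus sensor noise.

Time courses follow a stationary VAR(2),
$x(t) = A_1 x(t-1) + A_2 x(t-2) + e(t)$, with diagonal self-coupling
(0.3 at lag 1, 0.2 at lag 2, unit innovation variance) and one planted
cross edge per condition: SN → pDMN (coefficient 0.4, lag 1) in
abstinence, replaced by ECN → SN in satiety. Stationarity (companion
spectral radius < 1) is asserted at construction. The first 100 samples of
every simulation are burn-in.

Condition effects and variability:

* **Amplitude difference.** The SN amplitude factor is 1.2 in abstinence
  and 1.0 in satiety (the insula blob carries the largest peak amplitude,
  3.0 against 2.0–2.5 elsewhere, so SN amplitude effects peak there).
* **Subject variability.** Each subject carries one multiplicative
  lognormal(0, 0.1) amplitude jitter per network, *shared by both of the
  subject's sessions*. This is a subject trait: it makes one-sample and
  paired tests non-degenerate while cancelling from within-subject
  contrasts, as traits do in a paired design. (Redrawing the jitter per
  session would instead inject rank-one between-condition noise aligned
  with the network map — the paired t field then saturates across the
  network and localized amplitude effects become undetectable.)
* **Metadata.** Screening records emulate the cohort the defaults mirror:
  nicotine-dependence score (FTND) discrete uniform on 5–8, abstinence
  exhaled CO truncated-normal (9.6, 3.5²) ppm, satiety CO adding a
  strictly positive truncated-normal (13, 5²) increment, so CO rises for
  every subject.

Defaults: 21 subjects × 2 conditions × 150 retained volumes at TR = 2 s on
a 24 × 28 × 24 grid of 3 mm voxels; voxel noise σ = 1 (peak blob
signal-to-noise 2–3). The study never reported its spatial SNR or
between-subject variance, so these two are honest free parameters, chosen
once at a level a desk-scale recovery study can support and exposed as
arguments.

What the generator does **not** emulate: hemodynamic convolution,
physiological (cardiac/respiratory) noise, head motion, spatial
autocorrelation of the noise, and anatomical variability. Passing recovery
tests therefore demonstrate correctness of the *estimators* under the
stated model, not robustness to everything real data contain.

## Preprocessing

Fixed order: discard initial volumes → per-voxel linear detrend (OLS
against intercept and time index) → optional zero-phase band-pass →
optional spatial smoothing.

* **Band-pass**: 4th-order Butterworth, 0.01–0.08 Hz, applied
  forward-backward (zero phase). The filter family and order are package
  choices with a testable frequency response (passband gain within 10%,
  DC and 0.2 Hz attenuated below 10%).
* **Smoothing**: separable Gaussian, FWHM 8 mm by default,
  σ = FWHM/(2√(2 ln 2)) per axis in voxel units, mirror-reflected
  boundaries with boundary columns renormalized so total mass is conserved
  exactly.
* **Standardization**: `zero_mean` or `zscore`, always with the n−1
  standard-deviation denominator.

## Group ICA

1. **Component count.** Minimum-description-length (MDL) selection on the
   eigenvalue spectrum: for candidate $k$, code length
   $-N(V-k)\log(g_k/a_k) + \tfrac12 k(2V-k)\log N$ with $g_k, a_k$ the
   geometric and arithmetic means of the trailing eigenvalues. When
   estimated from voxel samples, every 3rd voxel is used to soften the
   violation of independent sampling. The default synthetic analyses fix 8
   components (the four planted networks plus headroom) rather than
   re-estimating per run.
2. **Stagewise PCA.** Stage 1 reduces each session's time dimension to 40;
   stage 2 concatenates blocks of 7 sessions and reduces to 30; stage 3
   concatenates everything and reduces to the component count. All
   projections are stored. Sessions are ordered abstinence block first.
3. **Infomax.** Natural-gradient maximization of the output entropy of a
   logistic nonlinearity on internally whitened data; block updates
   (256 samples), learning rate 0.01 annealed ×0.9 whenever successive
   weight updates point in obtuse directions, convergence when the
   relative weight change drops below 1e−7, at most 512 passes
   (non-convergence warns and flags the result). Numerical blow-up
   restarts the run at half the rate. Component sign is fixed so each
   spatial map has non-negative skewness; maps are scaled to unit
   variance. Components whose excess kurtosis is all ≈ 0 are flagged
   non-identifiable (Gaussian sources are only determined up to rotation).
4. **ICASSO.** Infomax is repeated 20 times (seeds seed + run index), all
   components pooled, clustered by average-linkage agglomeration of
   1 − |spatial correlation|, and each cluster's centrotype (the member
   with maximal summed intra-cluster similarity) is kept. The stability
   index is mean intra-cluster similarity minus mean similarity to the
   nearest other cluster, clipped to [0, 1]. Similarity is computed on the
   spatial maps, which are the quantity later tested.
5. **Back-reconstruction.** Each session's time courses are the session's
   composite projection (stage-1 × stage-2 × stage-3 partitions) applied
   to the group mixing matrix; its maps are the least-squares regression
   of the voxel-centred session data on those time courses. Two
   conventions matter and are deliberate:
   * *Unit-variance time courses.* Session time courses are scaled to
     unit variance before the map regression, so map intensity carries
     the session's component amplitude. Without this, amplitude is
     absorbed into the time courses and between-condition amplitude
     effects become invisible to map-based tests.
   * *Time courses from unsmoothed data.* When an unsmoothed session list
     is supplied (`tc_sessions`), time courses are re-estimated by dual
     regression of the unsmoothed data on the session maps. Smoothing
     helps the voxelwise map statistics but spatially correlates the
     noise with the blurred templates, measurably degrading extracted
     time courses; the full-resolution data contain the cleaner temporal
     signal.
6. **Template matching.** Greedy best-first assignment of components to
   network templates by spatial correlation, ties toward the lower
   component index, sub-threshold (0.3) assignments reported unmatched.
   This replaces by-eye component selection with a reproducible surrogate.

## Voxel statistics, clusters and ROIs

One-sample t maps use z-scored subject maps (mean 0, sd 1 per map) — the
group-pattern question is about map *shape*. The paired contrast runs on
the back-reconstructed maps in **native scale**: per-map z-normalization
divides out each map's overall amplitude, which is precisely the quantity
a between-condition amplitude modulation changes. (A network-wide scale
change is invisible in z-maps; a blob-level change even re-expresses as a
spurious relative decrease of the network's other blob, because the map's
standard deviation rises with the scaled blob.)

Degenerate voxels (zero variance, non-zero mean — exact in synthetic
noiseless corners) receive a signed-infinity t sentinel with p = 0 and are
counted, never silently NaN. FDR control is Benjamini–Hochberg step-up.
Clusters are connected components of the suprathreshold mask (uncorrected
p < 0.005 by default), per direction (A>B / B>A), under 26-connectivity
(6 and 18 available), dropped below 20 voxels — the extent matching the
smallest tabulated cluster of the reference analysis — and ordered by
direction then descending peak |t|. An ROI is a peak voxel plus its 26
neighbours (3×3×3 block, 9×9×9 mm³ at 3 mm); peaks whose block would leave
the grid raise an error rather than truncating. ROI series are unweighted
27-voxel means, shifted to zero mean so they concatenate across subjects
without level jumps.

## Granger causality

The bivariate VAR underlies the directed test: source lags are added to
the target's autoregression and the improvement is tested with

$$ F = \frac{(\mathrm{RSS}_r - \mathrm{RSS}_f)/p}{\mathrm{RSS}_f/(n - k_f)}
\sim F(p,\; n - k_f) \text{ under the null.} $$

Key choices:

* **Segments, not naive concatenation.** Per-subject series are kept as
  segments; lagged design rows never cross a subject boundary. Fitting
  equals explicit block OLS over pooled normal equations (tested against
  that oracle) and differs from concatenation across the seam.
* **No intercepts**: inputs are zero-meaned (or z-scored) per segment.
* **Order selection**: BIC
  $n \log\det\hat\Sigma + k^2 p \log n$ over the full multivariate system,
  computed on a common row set (rows available at the maximum candidate
  order) so candidates are comparable; one order per condition and node
  set.
* **Pairwise by default** (the model statement is bivariate); a
  conditional mode (all other nodes' lags in both models) is available.
  Pairwise tests can flag mediated influences (a→b→c may show a→c); this
  caveat is documented rather than resolved.
* **No band-pass before causal analysis.** Zero-phase filtering mixes
  future samples into the past and badly distorts finite-order VAR
  inference: in our pilots, filtering the planted-network series at
  0.01–0.08 Hz inflated the BIC order from 2 to 6 and produced spurious
  edges in every replicate (0/30 exact recoveries, against 94/100 without
  filtering). The GCA path therefore normalizes to zero mean/unit variance
  only; a band-pass argument exists for sensitivity analyses.
* **Graphs and degrees.** BH-FDR across all evaluated directed edges of
  one condition and node set (12 network-level, 56 ROI-level tests);
  out-degree, in-degree and out−in degree per node; out−in sums to zero
  over any graph. FDR levels default to q = 0.01 (networks) and q = 0.001
  (ROIs).

Degenerate deterministic dependence (zero full-model residual) raises an
explicit undefined-F error naming the pair.

## Verification studies and problem sizes

The package ships seeded experiments (`R/experiments.R`) that regenerate
their inputs and score recovery; `scripts/acceptance.R` runs all of them:

* **F-test calibration**: 1000 white-noise pairs (T = 300): rejection
  fraction at α = 0.05 within [0.035, 0.065]; power for a 0.8 lag-1
  coefficient above 0.95.
* **BIC order recovery**: VAR(2) with lag-2 diagonal 0.4 (T = 500):
  order 2 selected in ≥ 90/100 seeds.
* **ICA recovery**: one full default cohort (42 sessions, 16 128 voxels):
  all four centrotypes match their planted networks at spatial r ≥ 0.95
  and back-reconstructed time courses correlate with their generators at
  |r| ≥ 0.9 in every session. Time courses are compared against the
  generator *after the same linear detrending the data received*: a
  realized autoregressive series occasionally carries an incidental
  drift component that detrending removes from the data, and no
  estimator applied to detrended data can recover it — the comparison
  scores the estimator, not the deliberate filter.
* **Planted causal difference**: 100 replicate cohorts at the network-
  time-course level (21 subjects × 150 volumes each): FDR q = 0.01 graphs
  equal the planted edge sets exactly in ≥ 90/100 replicates.
* **Paired-t localization**: 100 replicate cohorts with a 20% insula-blob
  increase in abstinence, on a reduced 16 × 18 × 16 grid with the compact
  on-lattice blob layout (so one hundred replicates stay affordable);
  subject maps estimated by regression on the generating time courses —
  the map half of back-reconstruction; the time-course half is what the
  ICA recovery study establishes. The abstinence > satiety peak falls in
  the blob's half-maximum footprint in ≥ 95/100 replicates and the ROI
  defined there has exactly 27 voxels.

The reference study's voxel-level tables (anatomical clusters, ROI-level
F-scores, the 23-component decomposition of real scans) are not
reproducible without the original scanner data; they are covered instead
by exact oracle equivalences (cluster extraction vs union-find flood fill,
segmented VAR vs block OLS, BH vs hand step-up) plus the two packaged
reference tables (screening descriptives; significant ROI edges whose
out−in degrees the package recomputes).

## Numerical conventions

* Voxel indices are 1-based; world coordinates come from the grid affine
  (origin + (index − 1) · voxel size); reported coordinates are world mm.
* Sample standard deviations use n − 1 everywhere (this is what makes the
  packaged screening descriptives reproduce to the printed precision).
* Stored values are full precision; rounding to 2 decimals is
  presentation-only.
* Sub-seeds derive from the master seed by a fixed integer scheme and stay
  below 2³¹; identical configuration and seed give byte-identical outputs.
* Tables are TSV (tab-separated, header, '.' decimal); volumes NIfTI-1
  gzip; graphs and provenance JSON.

## Known limitations

No hemodynamic deconvolution precedes the causal analysis (defensible at
TR = 2 s, but systematic regional hemodynamic delays can still bias
directionality on real data). Pairwise Granger tests inherit the mediated-
edge caveat above. The Infomax implementation is the logistic (super-
Gaussian) variant without the extended sub-Gaussian switch. Cluster
inference is voxel-thresholded with an extent filter, not random-field or
permutation-corrected. The synthetic generator's omissions listed above
bound what green tests can promise about scanner data.
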