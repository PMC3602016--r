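#' Build Gaussian-blob network templates on a voxel grid
#'
#' Each network map is a sum of isotropic Gaussian blobs evaluated at voxel
#' centres. Alongside the continuous maps, a binary template mask is
#' returned per network marking voxels where any of its blobs exceeds half
#' that blob's peak amplitude (the half-maximum footprint).
#'
#' @param grid a [volume_grid()].
#' @param blob_specs data.frame with columns `network`, `x_mm`, `y_mm`,
#'   `z_mm`, `fwhm_mm`, `amplitude`; one row per blob. Networks may own
#'   several blobs.
#' @return A `spatial_source_set`: list with `grid`, `maps` (V x K matrix,
#'   one column per network), `masks` (V x K logical) and `names`.
#' @export
make_network_templates <- function(grid, blob_specs) {
  req <- c("network", "x_mm", "y_mm", "z_mm", "fwhm_mm", "amplitude")
  if (!all(req %in% names(blob_specs))) {
    stop("blob_specs must have columns: ", paste(req, collapse = ", "))
  }
  if (any(blob_specs$fwhm_mm <= 0)) stop("fwhm must be > 0")
  nets <- unique(blob_specs$network)
  if (anyDuplicated(nets)) stop("network name collision")
  mm <- voxel_to_mm(grid, voxel_coords(grid))
  V <- n_voxels(grid)
  maps <- matrix(0, V, length(nets), dimnames = list(NULL, nets))
  masks <- matrix(FALSE, V, length(nets), dimnames = list(NULL, nets))
  for (b in seq_len(nrow(blob_specs))) {
    centre <- c(blob_specs$x_mm[b], blob_specs$y_mm[b], blob_specs$z_mm[b])
    if (!mm_in_grid(grid, centre)) {
      stop(sprintf("blob centre (%g, %g, %g) lies outside the grid",
                   centre[1], centre[2], centre[3]))
    }
    sigma <- blob_specs$fwhm_mm[b] / (2 * sqrt(2 * log(2)))
    d2 <- (mm[, 1] - centre[1])^2 + (mm[, 2] - centre[2])^2 + (mm[, 3] - centre[3])^2
    blob <- blob_specs$amplitude[b] * exp(-d2 / (2 * sigma^2))
    net <- blob_specs$network[b]
    maps[, net] <- maps[, net] + blob
    masks[, net] <- masks[, net] | (blob > blob_specs$amplitude[b] / 2)
  }
  bad <- colnames(maps)[apply(maps, 2, function(m) !any(m > 0))]
  if (length(bad)) {
    stop("network map has no strictly positive voxel: ", paste(bad, collapse = ", "))
  }
  structure(list(grid = grid, maps = maps, masks = masks, names = nets),
            class = "spatial_source_set")
}

#' Default network templates for the synthetic cohort
#'
#' Four canonical resting-state networks (aDMN, pDMN, ECN, SN), two Gaussian
#' blobs each at fixed documented world coordinates loosely mimicking their
#' usual anterior-medial, posterior-medial, lateral fronto-parietal and
#' insular/cingulate loci. The SN insula blob carries the largest peak
#' amplitude so that amplitude-modulation effects on the SN localise there.
#'
#' @param grid a [volume_grid()]; defaults to the cohort default grid. The
#'   documented centres refer to the default 24 x 28 x 24 extent; for other
#'   extents they are scaled proportionally so the layout stays inside the
#'   volume.
#' @return A `spatial_source_set` with networks aDMN, pDMN, ECN, SN.
#' @export
default_network_templates <- function(grid = default_grid()) {
  specs <- data.frame(
    network = c("aDMN", "aDMN", "pDMN", "pDMN", "ECN", "ECN", "SN", "SN"),
    x_mm    = c(0,   0,    0,  -9,  -30,  33,  33,   0),
    y_mm    = c(30,  39, -39, -27,   27, -27,   9,  15),
    z_mm    = c(9,  -6,   21,  36,   24,  30,   3,  30),
    fwhm_mm = c(12, 12, 12, 12, 12, 12, 12, 12),
    amplitude = c(2.5, 2.0, 2.5, 2.0, 2.2, 2.2, 3.0, 2.0)
  )
  ref_half <- (default_grid()$dims - 1) / 2 * default_grid()$voxel_size_mm
  half <- (grid$dims - 1) / 2 * grid$voxel_size_mm
  ratio <- half / ref_half
  specs$x_mm <- specs$x_mm * ratio[1]
  specs$y_mm <- specs$y_mm * ratio[2]
  specs$z_mm <- specs$z_mm * ratio[3]
  specs$fwhm_mm <- specs$fwhm_mm * min(1, min(ratio) * 1.5)
  make_network_templates(grid, specs)
}

#' Default voxel grid for the synthetic cohort
#'
#' 24 x 28 x 24 voxels at 3 mm isotropic, centred on the world origin: a
#' desk-scale analogue of a 3 mm standard-space sampling.
#' @return a [volume_grid()].
#' @export
default_grid <- function() volume_grid(c(24L, 28L, 24L), c(3, 3, 3))

#' Specify a stationary VAR causal structure
#'
#' @param coeffs numeric array `[lag, target, source]` of autoregressive
#'   coefficients; `coeffs[j, a, b]` is the influence of node `b` at lag `j`
#'   on node `a`.
#' @param noise_sd positive innovation standard deviation, one per node
#'   (recycled if scalar).
#' @param names node names (defaults to dimnames or x1..xk).
#' @return A `causal_spec` with the companion-matrix spectral radius
#'   attached. Construction fails if the process is non-stationary.
#' @export
causal_spec <- function(coeffs, noise_sd = 1, names = NULL) {
  if (length(dim(coeffs)) != 3 || dim(coeffs)[2] != dim(coeffs)[3]) {
    stop("coeffs must be a [lag, target, source] array with square node slices")
  }
  if (!all(is.finite(coeffs))) stop("coeffs must be finite")
  k <- dim(coeffs)[2]
  p <- dim(coeffs)[1]
  noise_sd <- rep_len(as.numeric(noise_sd), k)
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  if (is.null(names)) names <- dimnames(coeffs)[[2]]
  if (is.null(names)) names <- paste0("x", seq_len(k))
  rho <- companion_spectral_radius(coeffs)
  if (rho >= 1) {
    stop(sprintf("non-stationary VAR: companion spectral radius %.3f >= 1", rho))
  }
  structure(list(order = p, coeffs = coeffs, noise_sd = noise_sd,
                 names = names, spectral_radius = rho),
            class = "causal_spec")
}

#' Spectral radius of the VAR companion matrix
#' @param coeffs `[lag, target, source]` coefficient array.
#' @return the largest eigenvalue modulus of the companion form.
#' @export
companion_spectral_radius <- function(coeffs) {
  p <- dim(coeffs)[1]; k <- dim(coeffs)[2]
  comp <- matrix(0, k * p, k * p)
  for (j in seq_len(p)) comp[1:k, ((j - 1) * k + 1):(j * k)] <- coeffs[j, , ]
  if (p > 1) comp[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate stationary VAR time courses
#'
#' Draws `x(t) = sum_j A_j x(t-j) + e(t)` with independent Gaussian
#' innovations, discarding an initial burn-in to remove initial-condition
#' transients. Identical seeds give identical output.
#'
#' @param n_timepoints number of retained samples T (must exceed 10 * order).
#' @param spec a [causal_spec()].
#' @param seed integer RNG seed.
#' @param burn_in samples discarded before retention (default 100).
#' @return T x k matrix with node-name columns.
#' @export
simulate_var_timecourses <- function(n_timepoints, spec, seed, burn_in = 100) {
  stopifnot(inherits(spec, "causal_spec"))
  p <- spec$order; k <- dim(spec$coeffs)[2]
  if (n_timepoints <= 10 * p) stop("n_timepoints must exceed 10 * order")
  Ttot <- n_timepoints + burn_in
  x <- matrix(0, Ttot, k)
  e <- with_seed(seed, matrix(rnorm(Ttot * k), Ttot, k))
  e <- sweep(e, 2, spec$noise_sd, `*`)
  A <- lapply(seq_len(p), function(j) spec$coeffs[j, , , drop = TRUE])
  if (k == 1) A <- lapply(A, function(a) matrix(a, 1, 1))
  for (t in (p + 1):Ttot) {
    acc <- e[t, ]
    for (j in seq_len(p)) acc <- acc + A[[j]] %*% x[t - j, ]
    x[t, ] <- acc
  }
  out <- x[(burn_in + 1):Ttot, , drop = FALSE]
  colnames(out) <- spec$names
  out
}

#' Mix spatial sources and time courses into a session
#'
#' The voxel signal is the linear mixture
#' `sum_k scale_k * source_k(voxel) * timecourse_k(t)` plus iid Gaussian
#' sensor noise: the generative model under which spatial ICA is exact.
#'
#' @param sources a `spatial_source_set`.
#' @param timecourses T x K matrix, one column per source network.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param amplitude_scales positive per-network multipliers (recycled).
#' @param seed integer RNG seed for the noise.
#' @param tr_s repetition time in seconds.
#' @param subject_id,condition session labels.
#' @return An `fmri_session`: list with `subject_id`, `condition`, `grid`,
#'   `tr_s` and `data` (T x V matrix).
#' @export
synthesize_session <- function(sources, timecourses, noise_sd,
                               amplitude_scales = 1, seed = 1, tr_s = 2,
                               subject_id = "sub-01",
                               condition = "abstinence") {
  stopifnot(inherits(sources, "spatial_source_set"))
  K <- ncol(sources$maps)
  if (ncol(timecourses) != K) {
    stop(sprintf("dimension mismatch: %d sources but %d timecourses",
                 K, ncol(timecourses)))
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  amplitude_scales <- rep_len(amplitude_scales, K)
  data <- timecourses %*% (amplitude_scales * t(sources$maps))
  if (noise_sd > 0) {
    data <- data + with_seed(seed, matrix(rnorm(length(data), sd = noise_sd),
                                          nrow(data), ncol(data)))
  }
  fmri_session(subject_id, condition, sources$grid, tr_s, data)
}

#' Construct an fMRI session container
#' @param subject_id subject label.
#' @param condition one of "abstinence", "satiety".
#' @param grid a [volume_grid()].
#' @param tr_s repetition time in seconds (> 0).
#' @param data T x V matrix of voxel time series (V = `n_voxels(grid)`).
#' @return an `fmri_session`.
#' @export
fmri_session <- function(subject_id, condition, grid, tr_s, data) {
  condition <- match.arg(condition, c("abstinence", "satiety"))
  if (tr_s <= 0) stop("tr_s must be > 0")
  if (ncol(data) != n_voxels(grid)) stop("data columns must equal grid voxel count")
  if (!all(is.finite(data))) stop("session data must be finite")
  structure(list(subject_id = subject_id, condition = condition, grid = grid,
                 tr_s = tr_s, data = data),
            class = "fmri_session")
}

#' @export
print.fmri_session <- function(x, ...) {
  cat(sprintf("<fmri_session> %s / %s: %d volumes x %d voxels, TR %gs\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$tr_s))
  invisible(x)
}

#' Ground truth for a synthetic two-condition cohort
#'
#' Bundles the planted spatial sources, the per-condition VAR causal
#' structure and the per-condition network amplitude scaling so recovery can
#' be scored after analysis. The default truth plants (i) a directed edge
#' SN -> pDMN in abstinence replaced by ECN -> SN in satiety (lag-1
#' coefficient `edge_coef` within a VAR(2)), and (ii) a 20% amplitude
#' increase of the SN in abstinence, peaking in its insula blob.
#'
#' @param seed integer master seed for the cohort.
#' @param grid a [volume_grid()].
#' @param sources a `spatial_source_set`.
#' @param edge_coef lag-1 cross coefficient of the planted edges.
#' @param noise_sd voxel noise standard deviation.
#' @param sn_abstinence_scale SN amplitude multiplier in abstinence.
#' @return A `synthetic_ground_truth` list.
#' @export
default_truth <- function(seed = 1, grid = default_grid(),
                          sources = default_network_templates(grid),
                          edge_coef = 0.4, noise_sd = 1,
                          sn_abstinence_scale = 1.2) {
  nets <- sources$names
  k <- length(nets)
  if (k < 2) stop("need at least two networks to plant a causal difference")
  base <- array(0, c(2, k, k), dimnames = list(NULL, nets, nets))
  for (n in nets) {
    base[1, n, n] <- 0.3
    base[2, n, n] <- 0.2
  }
  ## planted difference: SN -> pDMN in abstinence, ECN -> SN in satiety for
  ## the canonical layout; positional analogues for other source sets
  canonical <- all(c("pDMN", "ECN", "SN") %in% nets)
  e_abst <- if (canonical) c("SN", "pDMN") else c(nets[k], nets[1])
  e_sat <- if (canonical) c("ECN", "SN") else c(nets[1], nets[k])
  abst <- base; abst[1, e_abst[2], e_abst[1]] <- edge_coef
  sat <- base; sat[1, e_sat[2], e_sat[1]] <- edge_coef
  amplitude_delta <- rbind(
    abstinence = stats::setNames(rep(1, k), nets),
    satiety = stats::setNames(rep(1, k), nets)
  )
  amplitude_delta["abstinence", if (canonical) "SN" else nets[k]] <-
    sn_abstinence_scale
  structure(list(
    sources = sources,
    causal_by_condition = list(abstinence = causal_spec(abst, 1, nets),
                               satiety = causal_spec(sat, 1, nets)),
    amplitude_delta = amplitude_delta,
    planted_edges = list(
      abstinence = data.frame(source = e_abst[1], target = e_abst[2]),
      satiety = data.frame(source = e_sat[1], target = e_sat[2])),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_ground_truth")
}

## Deterministic sub-seed scheme: one stream per (subject, condition, use).
## Kept well below 2^31 for 32-bit R integers.
sub_seed <- function(seed, subject, condition_index, use) {
  (seed %% 100000L) * 10000L + subject * 100L + condition_index * 10L + use
}

#' Simulate subject screening records
#'
#' Nicotine-dependence scores (FTND, discrete uniform 5..8) and exhaled
#' carbon monoxide in ppm: abstinence CO from a truncated normal
#' (mean 9.6, sd 3.5, > 0), satiety CO as the abstinence value plus a
#' strictly positive increment (truncated normal mean 13, sd 5, > 1), so
#' every subject shows the expected CO rise after smoking.
#'
#' @param n_subjects number of subjects.
#' @param seed integer RNG seed.
#' @return data.frame with `subject_id`, `ftnd`, `co_abs_ppm`, `co_sat_ppm`.
#' @export
simulate_subject_records <- function(n_subjects, seed = 1) {
  with_seed(seed, {
    trunc_norm <- function(n, mean, sd, lower) {
      x <- rnorm(n, mean, sd)
      while (any(bad <- x <= lower)) x[bad] <- rnorm(sum(bad), mean, sd)
      x
    }
    data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n_subjects)),
      ftnd = sample(5:8, n_subjects, replace = TRUE),
      co_abs_ppm = round(trunc_norm(n_subjects, 9.6, 3.5, 0), 1),
      co_sat_ppm = NA_real_
    ) -> rec
    rec$co_sat_ppm <- round(rec$co_abs_ppm + trunc_norm(n_subjects, 13, 5, 1), 1)
    rec
  })
}

#' Generate a seeded two-condition synthetic cohort
#'
#' For each subject and condition, network time courses are drawn from that
#' condition's VAR causal spec, scaled by the condition's network amplitude
#' factors times a per-subject lognormal(0, 0.1) jitter, mixed with the
#' planted spatial sources and degraded with Gaussian noise. The jitter is
#' a subject-level trait: one draw per subject and network, shared by both
#' of the subject's sessions (so paired contrasts compare conditions within
#' subject, as in a within-subject design). All randomness derives
#' deterministically from `truth$seed`.
#'
#' @param truth a `synthetic_ground_truth` (see [default_truth()]).
#' @param n_subjects number of subjects (>= 2; default 21).
#' @param n_timepoints retained volumes per session (default 150).
#' @param tr_s repetition time in seconds (default 2).
#' @return list with `sessions` (2 * n_subjects `fmri_session`s, abstinence
#'   block first), `subjects` (metadata data.frame), `truth`, and
#'   `session_truth` (per-session true time courses and amplitude scales).
#' @export
make_cohort <- function(truth, n_subjects = 21, n_timepoints = 150, tr_s = 2) {
  stopifnot(inherits(truth, "synthetic_ground_truth"))
  if (n_subjects < 2) stop("n_subjects must be >= 2 (paired test undefined)")
  nets <- truth$sources$names
  conditions <- c("abstinence", "satiety")
  sessions <- list()
  session_truth <- list()
  jitter_by_subject <- lapply(seq_len(n_subjects), function(s) {
    with_seed(sub_seed(truth$seed, s, 0L, 2), exp(rnorm(length(nets), 0, 0.1)))
  })
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    spec <- truth$causal_by_condition[[cond]]
    for (s in seq_len(n_subjects)) {
      id <- sprintf("sub-%03d", s)
      tc <- simulate_var_timecourses(n_timepoints, spec,
                                     seed = sub_seed(truth$seed, s, ci, 1))
      scales <- truth$amplitude_delta[cond, nets] * jitter_by_subject[[s]]
      ses <- synthesize_session(truth$sources, tc, truth$noise_sd,
                                amplitude_scales = scales,
                                seed = sub_seed(truth$seed, s, ci, 3),
                                tr_s = tr_s, subject_id = id, condition = cond)
      key <- paste(id, cond, sep = ".")
      sessions[[key]] <- ses
      session_truth[[key]] <- list(timecourses = tc, amplitude_scales = scales)
    }
  }
  subjects <- simulate_subject_records(n_subjects,
                                       seed = sub_seed(truth$seed, 0L, 0L, 4))
  list(sessions = sessions, subjects = subjects, truth = truth,
       session_truth = session_truth)
}

#' Write a cohort to disk
#'
#' Sessions are written as gzipped NIfTI-1 4D volumes, subject metadata as a
#' tab-separated `subjects.tsv`, and the ground truth as NIfTI source maps
#' plus a `truth.json` with the causal specification and amplitude factors.
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- cohort$truth$sources$grid
  for (key in names(cohort$sessions)) {
    ses <- cohort$sessions[[key]]
    arr <- array(t(ses$data), c(grid$dims, nrow(ses$data)))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(grid$voxel_size_mm, ses$tr_s)
    RNifti::writeNifti(img, file.path(dir, paste0(key, ".nii.gz")))
  }
  utils::write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  src <- array(cohort$truth$sources$maps,
               c(grid$dims, ncol(cohort$truth$sources$maps)))
  src_img <- RNifti::asNifti(src)
  RNifti::pixdim(src_img) <- c(grid$voxel_size_mm, 1)
  RNifti::writeNifti(src_img, file.path(dir, "truth_sources.nii.gz"))
  truth_json <- list(
    seed = cohort$truth$seed,
    networks = cohort$truth$sources$names,
    noise_sd = cohort$truth$noise_sd,
    amplitude_delta = as.data.frame(cohort$truth$amplitude_delta),
    causal_by_condition = lapply(cohort$truth$causal_by_condition, function(sp) {
      list(order = sp$order, noise_sd = sp$noise_sd, coeffs = sp$coeffs)
    })
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a session written by [write_cohort()]
#' @param path path to a `<subject>.<condition>.nii.gz` file.
#' @param grid the cohort [volume_grid()].
#' @return an `fmri_session`.
#' @export
read_session <- function(path, grid) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  stopifnot(length(dim(arr)) == 4)
  key <- sub("\\.nii(\\.gz)?$", "", basename(path))
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  tr <- RNifti::pixdim(img)[4]
  data <- t(matrix(arr, prod(dim(arr)[1:3]), dim(arr)[4]))
  fmri_session(parts[1], parts[2], grid, tr, data)
}
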