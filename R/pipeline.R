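#' Descriptive statistics of a subject cohort
#'
#' Arithmetic mean, sample standard deviation (n - 1), minimum, maximum and
#' n for each screening variable. Values are kept at full precision;
#' rounding to two decimals is presentation-only (see `round_digits`).
#'
#' @param records data.frame with columns `ftnd`, `co_abs_ppm`,
#'   `co_sat_ppm` (as from [simulate_subject_records()] or the packaged
#'   subject table).
#' @param round_digits optional number of decimals for presentation.
#' @return data.frame with one row per variable: `variable`, `mean`, `sd`,
#'   `min`, `max`, `n`.
#' @export
cohort_summary <- function(records, round_digits = NULL) {
  vars <- c("ftnd", "co_abs_ppm", "co_sat_ppm")
  stopifnot(all(vars %in% names(records)))
  if (nrow(records) < 2) stop("sd undefined for fewer than 2 subjects")
  out <- do.call(rbind, lapply(vars, function(v) {
    x <- records[[v]]
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x), n = length(x))
  }))
  if (!is.null(round_digits)) {
    out$mean <- round(out$mean, round_digits)
    out$sd <- round(out$sd, round_digits)
  }
  out
}

#' Path to the packaged subject screening table
#'
#' Tab-separated per-subject nicotine-dependence scores and exhaled CO
#' levels for the 21-subject two-condition cohort the defaults emulate.
#'
#' @return file path to `subjects_table.tsv`.
#' @export
subjects_fixture_path <- function() {
  system.file("extdata", "subjects_table.tsv", package = "restconn",
              mustWork = TRUE)
}

#' Paths to the packaged significant-edge tables
#' @param condition `"abstinence"` or `"satiety"`.
#' @return file path to the corresponding ROI-level edge TSV.
#' @export
edges_fixture_path <- function(condition = c("abstinence", "satiety")) {
  condition <- match.arg(condition)
  fn <- sprintf("roi_edges_%s.tsv", condition)
  system.file("extdata", fn, package = "restconn", mustWork = TRUE)
}

#' Build a validated run configuration
#'
#' Defaults mirror the standard analysis: band 0.01-0.08 Hz, 8 mm FWHM
#' smoothing, FDR q = 0.01 for one-sample maps, uncorrected p = 0.005 and
#' 20-voxel extent for paired-test clusters, FDR q = 0.01 at network level
#' and q = 0.001 at ROI level.
#'
#' @param n_subjects,n_timepoints cohort size of the simulated run.
#' @param grid_dims voxel grid dimensions.
#' @param seed master seed; per-stage seeds derive from it.
#' @param n_components,n_runs ICA settings.
#' @param smooth_fwhm_mm spatial smoothing FWHM (NULL to skip).
#' @param bandpass voxelwise band in Hz (NULL to skip; the GCA path works
#'   on unfiltered series regardless, see the methods vignette).
#' @param q_one_sample FDR level of one-sample network maps.
#' @param p_paired_uncorrected,min_extent,connectivity paired-test
#'   cluster settings.
#' @param q_network,q_roi FDR levels of the two causal analyses.
#' @param max_order BIC search bound.
#' @param match_threshold template-matching acceptance threshold.
#' @return a `run_config` list.
#' @export
run_config <- function(n_subjects = 21, n_timepoints = 150,
                       grid_dims = c(24, 28, 24), seed = 1,
                       n_components = 8, n_runs = 20,
                       smooth_fwhm_mm = 8, bandpass = NULL,
                       q_one_sample = 0.01, p_paired_uncorrected = 0.005,
                       min_extent = 20, connectivity = 26,
                       q_network = 0.01, q_roi = 0.001, max_order = 6,
                       match_threshold = 0.3) {
  cfg <- as.list(environment())
  stopifnot(n_subjects >= 2, n_timepoints >= 20, length(grid_dims) == 3,
            n_components >= 2, n_runs >= 1,
            q_one_sample > 0, q_one_sample < 1,
            p_paired_uncorrected > 0, p_paired_uncorrected < 1,
            min_extent >= 1, connectivity %in% c(6, 18, 26),
            q_network > 0, q_network < 1, q_roi > 0, q_roi < 1,
            max_order >= 1)
  structure(cfg, class = "run_config")
}

## order sessions as the group concatenation expects: abstinence block first
ordered_sessions <- function(cohort) {
  keys <- names(cohort$sessions)
  cond <- sub("^.*\\.", "", keys)
  cohort$sessions[order(match(cond, c("abstinence", "satiety")), keys)]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full simulated two-condition analysis
#'
#' Orchestrates every stage in fixed order: simulate the cohort,
#' preprocess, group ICA with ICASSO and back-reconstruction, template
#' matching, z-scored one-sample t maps per condition with FDR, paired t
#' maps with cluster extraction per network, ROI definition from paired
#' peaks, and Granger causality at network and ROI level with out-in
#' degree tables. Identical config and seed yield identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, every table is written as
#'   TSV/JSON together with a provenance record.
#' @return list with all stage outputs (`cohort_summary`, `ica`,
#'   `matching`, `one_sample`, `paired`, `clusters`, `rois`,
#'   `network_graphs`, `roi_graphs`, `degree_tables`, `provenance`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  grid <- volume_grid(config$grid_dims)
  truth <- default_truth(seed = config$seed, grid = grid)
  cohort <- stage("simulate", make_cohort(truth, config$n_subjects,
                                          config$n_timepoints))
  summary_tab <- cohort_summary(cohort$subjects)

  sessions <- ordered_sessions(cohort)
  sessions <- stage("prep", lapply(sessions, function(s) {
    prep_session(s, discard_n = 0, detrend = TRUE,
                 bandpass = config$bandpass,
                 smooth_fwhm_mm = config$smooth_fwhm_mm)
  }))

  ica <- stage("gica", group_ica(sessions, n_components = config$n_components,
                                 n_runs = config$n_runs, seed = config$seed))
  matching <- stage("match", match_components(ica$group$maps, truth$sources,
                                              config$match_threshold))

  cond_of <- vapply(sessions, `[[`, "", "condition")
  nets <- matching$network[!is.na(matching$component)]
  one_sample <- list(); paired <- list(); clusters <- list(); rois <- list()
  for (net in nets) {
    comp <- matching$component[matching$network == net]
    maps_by_cond <- lapply(c(abstinence = "abstinence", satiety = "satiety"),
      function(cc) {
        t(vapply(ica$subject_maps[cond_of == cc],
                 function(m) m[, comp], numeric(n_voxels(grid))))
      })
    ## z-scored maps feed the group-pattern (one-sample) inference; the
    ## paired contrast runs in native map scale, where amplitude
    ## differences between conditions remain visible (see vignette)
    one_sample[[net]] <- lapply(maps_by_cond, function(M) {
      sm <- one_sample_ttest(t(apply(M, 1, zscore_map)), grid)
      sm$fdr <- fdr_threshold(sm$p, config$q_one_sample)
      sm
    })
    pt <- paired_ttest(maps_by_cond$abstinence, maps_by_cond$satiety,
                       grid = grid)
    paired[[net]] <- pt
    cl <- extract_clusters(pt, config$p_paired_uncorrected,
                           config$min_extent, config$connectivity)
    clusters[[net]] <- cl
    if (length(cl)) {
      roi <- roi_from_cluster(cl[[1]], pt, grid, name = paste0(net, "_peak"))
      if (!is.null(roi)) rois[[net]] <- roi
    }
  }

  ## network-level GCA on back-reconstructed time courses (z-normalized)
  net_comp <- matching$component[match(nets, matching$network)]
  network_graphs <- list(); roi_graphs <- list(); degree_tables <- list()
  for (cc in c("abstinence", "satiety")) {
    segs <- lapply(ica$subject_timecourses[cond_of == cc], function(tc) {
      m <- tc[, net_comp, drop = FALSE]
      colnames(m) <- nets
      standardize(m, "zscore")
    })
    ss <- concatenate_segments(segs, condition = cc)
    edges <- stage("gca_network",
                   pairwise_granger(ss, order = "bic",
                                    max_order = config$max_order))
    network_graphs[[cc]] <- build_causal_graph(edges, config$q_network,
                                               nodes = nets, condition = cc)
    degree_tables[[paste0("network_", cc)]] <-
      out_in_degree(network_graphs[[cc]])
    if (length(rois) >= 2) {
      segs_roi <- lapply(names(cohort$sessions)[cond_of == cc], function(key) {
        sapply(rois, function(r) roi_timeseries(cohort$sessions[[key]], r))
      })
      ssr <- concatenate_segments(segs_roi, condition = cc)
      edges_r <- stage("gca_roi",
                       pairwise_granger(ssr, order = "bic",
                                        max_order = config$max_order))
      roi_graphs[[cc]] <- build_causal_graph(edges_r, config$q_roi,
                                             nodes = names(rois),
                                             condition = cc)
      degree_tables[[paste0("roi_", cc)]] <- out_in_degree(roi_graphs[[cc]])
    }
  }

  provenance <- list(
    config = unclass(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("restconn")),
    stages = c("simulate", "prep", "gica", "netstat", "gcause")
  )
  result <- list(cohort_summary = summary_tab, matching = matching,
                 ica = ica, one_sample = one_sample, paired = paired,
                 clusters = clusters, rois = rois,
                 network_graphs = network_graphs, roi_graphs = roi_graphs,
                 degree_tables = degree_tables, provenance = provenance)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir, grid)
  result
}

write_pipeline_outputs <- function(result, out_dir, grid) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(result$cohort_summary, file.path(out_dir, "cohort_summary.tsv"))
  write_tsv(result$matching, file.path(out_dir, "template_matching.tsv"))
  cl_rows <- do.call(rbind, lapply(names(result$clusters), function(net) {
    tab <- cluster_table(result$clusters[[net]])
    if (nrow(tab)) cbind(network = net, tab) else NULL
  }))
  if (is.null(cl_rows)) {
    cl_rows <- cbind(network = character(), cluster_table(list()))
  }
  write_tsv(cl_rows, file.path(out_dir, "paired_clusters.tsv"))
  for (cc in names(result$network_graphs)) {
    g <- result$network_graphs[[cc]]
    write_tsv(g$edges, file.path(out_dir, sprintf("network_edges_%s.tsv", cc)))
  }
  deg <- do.call(rbind, lapply(names(result$degree_tables), function(nm) {
    cbind(analysis = nm, result$degree_tables[[nm]])
  }))
  write_tsv(deg, file.path(out_dir, "degree_tables.tsv"))
  jsonlite::write_json(result$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
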