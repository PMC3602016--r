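#' Normalize a spatial map to z-scores
#'
#' Subtracts the spatial mean and divides by the spatial standard deviation
#' (n - 1 denominator) over the supplied voxels.
#'
#' @param map numeric vector of per-voxel values.
#' @return z-scored vector (mean 0, sd 1).
#' @export
zscore_map <- function(map) {
  s <- stats::sd(map)
  if (!is.finite(s) || s == 0) stop("z-score undefined for a constant map")
  (map - mean(map)) / s
}

new_stat_map <- function(t, p, df, test, n_degenerate, grid = NULL) {
  structure(list(t = t, p = p, df = df, test = test,
                 n_degenerate = n_degenerate, grid = grid),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s t-test, df = %d, %d voxels (%d degenerate)\n",
              x$test, x$df, length(x$t), x$n_degenerate))
  invisible(x)
}

## column-wise one-sample t against zero; zero-variance columns get an
## infinity sentinel (p = 0) or t = 0, p = 1 when the mean is also zero.
col_t_test <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  sd <- sqrt(colSums(sweep(M, 2, mu, `-`)^2) / (n - 1))
  t <- rep(0, ncol(M))
  p <- rep(1, ncol(M))
  ## zero variance up to floating-point noise counts as degenerate
  ok <- sd > 1e-12 * pmax(abs(mu), 1)
  t[ok] <- mu[ok] / (sd[ok] / sqrt(n))
  p[ok] <- 2 * stats::pt(-abs(t[ok]), df = n - 1)
  degen <- !ok & mu != 0
  t[degen] <- sign(mu[degen]) * Inf
  p[degen] <- 0
  list(t = t, p = p, df = n - 1L, n_degenerate = sum(degen))
}

#' Voxelwise one-sample t-test across subjects
#'
#' Random-effects group inference: per voxel, t = mean / (sd / sqrt(n))
#' with df = n - 1 and two-sided p-values. Voxels with zero variance but a
#' nonzero mean receive a signed infinity sentinel with p = 0; their count
#' is recorded in `n_degenerate`.
#'
#' @param maps n x V matrix of subject spatial maps (rows = subjects).
#' @param grid optional [volume_grid()] carried for cluster extraction.
#' @return a `stat_map`.
#' @export
one_sample_ttest <- function(maps, grid = NULL) {
  if (nrow(maps) < 2) stop("need at least 2 subjects")
  r <- col_t_test(maps)
  new_stat_map(r$t, r$p, r$df, "one_sample", r$n_degenerate, grid)
}

#' Voxelwise paired t-test between two conditions
#'
#' One-sample t-test on subject-aligned paired differences `a - b`;
#' positive t favours the first condition (A > B).
#'
#' @param maps_a,maps_b n x V matrices, subject-aligned by row.
#' @param subjects_a,subjects_b optional subject id vectors; when given
#'   they must match element-wise.
#' @param grid optional [volume_grid()].
#' @return a `stat_map` with `test = "paired"`.
#' @export
paired_ttest <- function(maps_a, maps_b, subjects_a = NULL, subjects_b = NULL,
                         grid = NULL) {
  if (!all(dim(maps_a) == dim(maps_b))) stop("conditions must have equal n and V")
  if (!is.null(subjects_a) && !identical(subjects_a, subjects_b)) {
    stop("misaligned subject ids between conditions")
  }
  if (nrow(maps_a) < 2) stop("need at least 2 subjects")
  r <- col_t_test(maps_a - maps_b)
  new_stat_map(r$t, r$p, r$df, "paired", r$n_degenerate, grid)
}

#' Benjamini-Hochberg false-discovery-rate threshold
#'
#' Step-up procedure: with sorted p-values, find the largest k with
#' `p_(k) <= k * q / m` and reject every p at or below that critical value.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param q target false discovery rate (0 < q < 1).
#' @return list with `reject` (logical, same order as input) and
#'   `critical_p` (0 when nothing is rejected).
#' @export
fdr_threshold <- function(p_values, q) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (!(q > 0 && q < 1)) stop("q must lie in (0, 1)")
  m <- length(p_values)
  ps <- sort(p_values)
  ok <- which(ps <= seq_len(m) * q / m)
  crit <- if (length(ok)) ps[max(ok)] else 0
  list(reject = p_values <= crit & length(ok) > 0, critical_p = crit)
}

neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  dist <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = dist == 1,
                 "18" = dist >= 1 & rowSums(off != 0) <= 2,
                 "26" = dist >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  off[keep, , drop = FALSE]
}

## label connected components of a logical 3D mask by breadth-first search
label_components <- function(mask3d, connectivity = 26) {
  d <- dim(mask3d)
  off <- neighbour_offsets(connectivity)
  labels <- array(0L, d)
  lin <- which(mask3d)
  if (!length(lin)) return(labels)
  nxt <- 0L
  for (v in lin) {
    if (labels[v] != 0L) next
    nxt <- nxt + 1L
    queue <- v
    labels[v] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      k0 <- (cur - 1L) %/% (d[1] * d[2])
      rem <- (cur - 1L) %% (d[1] * d[2])
      j0 <- rem %/% d[1]
      i0 <- rem %% d[1]
      ni <- i0 + 1L + off[, 1]; nj <- j0 + 1L + off[, 2]; nk <- k0 + 1L + off[, 3]
      inb <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
      cand <- (ni[inb] - 1L) + (nj[inb] - 1L) * d[1] + (nk[inb] - 1L) * d[1] * d[2] + 1L
      cand <- cand[mask3d[cand] & labels[cand] == 0L]
      if (length(cand)) {
        labels[cand] <- nxt
        queue <- c(queue, cand)
      }
    }
  }
  labels
}

#' Extract suprathreshold clusters from a statistical map
#'
#' Thresholds the map at an uncorrected p-value, separates the positive
#' (A > B) and negative (B > A) directions, labels connected components
#' under the chosen voxel connectivity, drops clusters below the minimum
#' extent, and reports each cluster's size, peak |t| voxel and its world-mm
#' coordinates. Clusters are ordered by direction then descending peak |t|.
#'
#' @param stat a `stat_map` carrying a grid (or pass `grid`).
#' @param p_thresh uncorrected voxelwise p threshold (default 0.005).
#' @param min_extent minimum cluster size in voxels (default 20).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param grid a [volume_grid()] overriding `stat$grid`.
#' @return list of clusters; each has `member_voxels` (linear indices),
#'   `size_voxels`, `peak_voxel`, `peak_t`, `peak_mm`, `direction`.
#' @export
extract_clusters <- function(stat, p_thresh = 0.005, min_extent = 20,
                             connectivity = 26, grid = NULL) {
  grid <- if (is.null(grid)) stat$grid else grid
  if (is.null(grid)) stop("a volume_grid is required for cluster extraction")
  if (!(p_thresh > 0 && p_thresh < 1)) stop("invalid p threshold")
  out <- list()
  for (dir in c("A>B", "B>A")) {
    sel <- if (dir == "A>B") stat$t > 0 else stat$t < 0
    mask <- array(sel & stat$p < p_thresh, grid$dims)
    labels <- label_components(mask, connectivity)
    if (!any(labels > 0)) next
    for (lb in seq_len(max(labels))) {
      members <- which(labels == lb)
      if (length(members) < min_extent) next
      peak <- members[which.max(abs(stat$t[members]))]
      ijk <- arrayInd(peak, grid$dims)[1, ]
      out[[length(out) + 1]] <- list(
        member_voxels = members,
        size_voxels = length(members),
        peak_voxel = peak,
        peak_t = stat$t[peak],
        peak_mm = voxel_to_mm(grid, ijk),
        direction = dir
      )
    }
  }
  ord <- order(vapply(out, `[[`, "", "direction"),
               -abs(vapply(out, `[[`, 0, "peak_t")))
  out[ord]
}

#' Tabulate extracted clusters
#' @param clusters result of [extract_clusters()].
#' @return data.frame with one row per cluster.
#' @export
cluster_table <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(direction = character(), size_voxels = integer(),
                      peak_t = numeric(), peak_x_mm = numeric(),
                      peak_y_mm = numeric(), peak_z_mm = numeric()))
  }
  data.frame(
    direction = vapply(clusters, `[[`, "", "direction"),
    size_voxels = vapply(clusters, `[[`, 0L, "size_voxels"),
    peak_t = vapply(clusters, `[[`, 0, "peak_t"),
    peak_x_mm = vapply(clusters, function(c) c$peak_mm[1], 0),
    peak_y_mm = vapply(clusters, function(c) c$peak_mm[2], 0),
    peak_z_mm = vapply(clusters, function(c) c$peak_mm[3], 0)
  )
}

#' Define a 27-voxel region of interest around a peak
#'
#' The ROI is the full 3 x 3 x 3 voxel block centred on the peak voxel
#' (the peak and its 26 neighbours); the block must fit inside the grid.
#'
#' @param center_voxel integer triple of 1-based voxel indices.
#' @param grid a [volume_grid()].
#' @param name ROI label.
#' @return an `roi`: list with `name`, `center_voxel` and 27
#'   `member_voxels` linear indices.
#' @export
define_roi <- function(center_voxel, grid, name = "roi") {
  center_voxel <- as.integer(center_voxel)
  if (any(center_voxel <= 1) || any(center_voxel >= grid$dims)) {
    stop("ROI block extends beyond the grid boundary")
  }
  neigh <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ijk <- sweep(neigh, 2, center_voxel, `+`)
  members <- apply(ijk, 1, function(v) voxel_index(grid, v))
  structure(list(name = name, center_voxel = center_voxel,
                 member_voxels = sort(members)),
            class = "roi")
}

#' Define an ROI from a cluster, respecting grid boundaries
#'
#' Takes the cluster's member voxels in decreasing |t| order and returns
#' the ROI centred on the first one whose full 3 x 3 x 3 block fits inside
#' the grid (the cluster peak itself when it is interior).
#'
#' @param cluster one element of [extract_clusters()].
#' @param stat the `stat_map` the cluster came from.
#' @param grid a [volume_grid()].
#' @param name ROI label.
#' @return an `roi`, or NULL when no member voxel can host a full block.
#' @export
roi_from_cluster <- function(cluster, stat, grid, name = "roi") {
  members <- cluster$member_voxels[order(-abs(stat$t[cluster$member_voxels]))]
  for (v in members) {
    ijk <- arrayInd(v, grid$dims)[1, ]
    if (all(ijk > 1) && all(ijk < grid$dims)) {
      return(define_roi(ijk, grid, name))
    }
  }
  NULL
}

#' Mean ROI time series of a session
#'
#' Unweighted mean over the ROI's 27 voxels at each time point, then
#' shifted to zero mean (so series concatenate across subjects without
#' level jumps).
#'
#' @param session an `fmri_session`.
#' @param roi an [define_roi()] result on the same grid.
#' @return numeric zero-mean time series of length T.
#' @export
roi_timeseries <- function(session, roi) {
  if (any(roi$member_voxels > ncol(session$data)) ||
      any(roi$center_voxel > session$grid$dims)) {
    stop("ROI does not fit the session grid")
  }
  v <- rowMeans(session$data[, roi$member_voxels, drop = FALSE])
  v - mean(v)
}
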