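#' Estimate the number of latent components by MDL
#'
#' Minimum-description-length model-order selection on the eigenvalue
#' spectrum of the sample covariance (Wax-Kailath form): for each candidate
#' k the code length is the negative log ratio of the geometric to the
#' arithmetic mean of the trailing eigenvalues times `N * (V - k)`, plus the
#' parameter penalty `0.5 * k * (2V - k) * log(N)`. Returns the minimizing k.
#'
#' @param data N x V matrix (observations by variables), or NULL when
#'   `eigenvalues` is supplied directly.
#' @param eigenvalues optional descending eigenvalue vector with `n_obs`.
#' @param n_obs number of observations (required with `eigenvalues`).
#' @return the estimated component count (integer, 0 <= k < V).
#' @export
estimate_component_count <- function(data = NULL, eigenvalues = NULL,
                                     n_obs = NULL) {
  if (is.null(eigenvalues)) {
    stopifnot(is.matrix(data), ncol(data) >= 2)
    if (nrow(data) <= ncol(data)) {
      stop("need more observations than variables")
    }
    n_obs <- nrow(data)
    eigenvalues <- eigen(stats::cov(data), symmetric = TRUE,
                         only.values = TRUE)$values
  }
  V <- length(eigenvalues)
  N <- n_obs
  tol <- max(eigenvalues) * 1e-10
  if (any(eigenvalues < tol)) {
    stop(sprintf("rank-deficient covariance: eigenvalue %d is numerically zero",
                 which(eigenvalues < tol)[1]))
  }
  mdl <- vapply(0:(V - 1), function(k) {
    tail_l <- eigenvalues[(k + 1):V]
    g <- mean(log(tail_l))          # log geometric mean
    a <- log(mean(tail_l))          # log arithmetic mean
    -N * (V - k) * (g - a) + 0.5 * k * (2 * V - k) * log(N)
  }, numeric(1))
  as.integer(which.min(mdl) - 1L)
}

## Per-session temporal PCA: orthonormal basis of the top d left singular
## vectors of the voxel-centred data (T x V), via the small T x T Gram matrix.
session_pca <- function(Y, d) {
  Yc <- sweep(Y, 2, colMeans(Y), `-`)
  G <- tcrossprod(Yc)               # T x T
  F <- eigen(G, symmetric = TRUE)$vectors[, seq_len(d), drop = FALSE]
  list(F = F, reduced = crossprod(F, Yc))
}

#' Stagewise PCA reduction of temporally concatenated sessions
#'
#' Three-stage reduction for group ICA over many sessions: (1) each
#' session's time dimension is reduced to `d1`; (2) fixed-size blocks of
#' sessions are row-concatenated and reduced to `d2`; (3) all blocks are
#' concatenated and reduced to `d3`. All projection matrices are retained
#' for back-reconstruction. Sessions must be supplied in concatenation
#' order (abstinence block first, then satiety).
#'
#' @param sessions ordered list of `fmri_session`s (or plain T x V matrices).
#' @param stage_dims integer triple `(d1, d2, d3)` with `d1 >= d2 >= d3 >= 2`.
#' @param block_size sessions per stage-2 block (default 7).
#' @return list with `reduced` (d3 x V group matrix) and `projections`
#'   (per-session composite T x d3 matrices plus the raw stage matrices).
#' @export
reduce_stagewise_pca <- function(sessions, stage_dims = c(40, 30, 20),
                                 block_size = 7) {
  d1 <- stage_dims[1]; d2 <- stage_dims[2]; d3 <- stage_dims[3]
  if (!(d1 >= d2 && d2 >= d3 && d3 >= 2)) {
    stop("stage dims must satisfy d1 >= d2 >= d3 >= 2")
  }
  mats <- lapply(sessions, function(s) if (inherits(s, "fmri_session")) s$data else s)
  n <- length(mats)
  if (any(vapply(mats, nrow, 1L) < d1)) stop("d1 must not exceed per-session T")
  s1 <- lapply(mats, session_pca, d = d1)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / block_size))
  s2 <- lapply(blocks, function(ix) {
    B <- do.call(rbind, lapply(s1[ix], `[[`, "reduced"))
    dd2 <- min(d2, nrow(B))
    G <- eigen(tcrossprod(B), symmetric = TRUE)$vectors[, seq_len(dd2), drop = FALSE]
    list(G = G, reduced = crossprod(G, B), sessions = ix)
  })
  C <- do.call(rbind, lapply(s2, `[[`, "reduced"))
  dd3 <- min(d3, nrow(C))
  H <- eigen(tcrossprod(C), symmetric = TRUE)$vectors[, seq_len(dd3), drop = FALSE]
  reduced <- crossprod(H, C)
  ## composite per-session projection: T x d3
  comp <- vector("list", n)
  offset <- 0
  for (b in seq_along(s2)) {
    ix <- s2[[b]]$sessions
    db <- ncol(s2[[b]]$G)
    Hb <- H[(offset + 1):(offset + db), , drop = FALSE]
    for (w in seq_along(ix)) {
      rows <- ((w - 1) * d1 + 1):(w * d1)
      comp[[ix[w]]] <- s1[[ix[w]]]$F %*% s2[[b]]$G[rows, , drop = FALSE] %*% Hb
    }
    offset <- offset + db
  }
  names(comp) <- names(sessions)
  list(reduced = reduced,
       projections = list(composite = comp,
                          stage1 = lapply(s1, `[[`, "F"),
                          stage2 = lapply(s2, function(z) z[c("G", "sessions")]),
                          stage3 = H,
                          stage_dims = c(d1, d2, dd3),
                          block_size = block_size))
}

#' Infomax independent component analysis
#'
#' Natural-gradient Infomax with a logistic nonlinearity on internally
#' whitened data. The learning rate anneals by 0.9 whenever the weight
#' update grows, and the run restarts at half the rate on numerical
#' blow-up. Component sign is fixed so every spatial map has nonnegative
#' skewness, and maps are scaled to unit variance.
#'
#' @param reduced k x V matrix (reduced observations in rows, voxel samples
#'   in columns).
#' @param seed integer seed for the random initial unmixing matrix.
#' @param lrate initial learning rate (default 0.01).
#' @param max_iter maximum passes over the data (default 512).
#' @param tol convergence tolerance on the relative weight change.
#' @param block_size samples per natural-gradient block update.
#' @return A `component_set`: `maps` (V x k, unit variance, sign-fixed),
#'   `unmixing` (k x k acting on the centred reduced data), `mixing` (its
#'   inverse), `converged`, `iterations`, `kurtosis` (per-component excess
#'   kurtosis) and `identifiable` (FALSE when every component looks
#'   Gaussian, in which case ICA is only determined up to rotation).
#' @export
infomax_ica <- function(reduced, seed = 1, lrate = 0.01, max_iter = 512,
                        tol = 1e-7, block_size = 256) {
  k <- nrow(reduced)
  V <- ncol(reduced)
  if (k < 2) stop("need at least 2 components")
  centre <- rowMeans(reduced)
  X <- reduced - centre
  ## whiten
  C <- tcrossprod(X) / (V - 1)
  ec <- eigen(C, symmetric = TRUE)
  if (min(ec$values) < max(ec$values) * 1e-12) {
    stop("reduced data are rank deficient; lower the component count")
  }
  K <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  Z <- K %*% X
  run <- function(lr0) {
    W <- with_seed(seed, qr.Q(qr(matrix(rnorm(k * k), k, k))))
    lr <- lr0
    dW_prev <- NULL
    I_k <- diag(k)
    for (it in seq_len(max_iter)) {
      perm <- with_seed(seed + it, sample.int(V))
      Wold <- W
      for (start in seq(1, V, by = block_size)) {
        idx <- perm[start:min(start + block_size - 1, V)]
        U <- W %*% Z[, idx, drop = FALSE]
        Yl <- 1 / (1 + exp(-U))
        G <- tcrossprod(1 - 2 * Yl, U) / length(idx)
        W <- W + lr * (I_k + G) %*% W
        if (!all(is.finite(W)) || max(abs(W)) > 1e8) return(NULL)
      }
      dW <- W - Wold
      ## anneal only when successive updates oscillate (obtuse angle)
      if (!is.null(dW_prev) && sum(dW * dW_prev) < 0) lr <- lr * 0.9
      dW_prev <- dW
      change <- sum(dW^2) / sum(Wold^2)
      if (change < tol) {
        return(list(W = W, converged = TRUE, iterations = it))
      }
    }
    list(W = W, converged = FALSE, iterations = max_iter)
  }
  res <- NULL
  lr_try <- lrate
  for (attempt in 1:8) {
    res <- run(lr_try)
    if (!is.null(res)) break
    lr_try <- lr_try / 2
  }
  if (is.null(res)) stop("Infomax diverged at every attempted learning rate")
  if (!res$converged) {
    warning(sprintf("Infomax did not reach tol %.1e within %d iterations",
                    tol, max_iter))
  }
  S <- res$W %*% Z                          # k x V source (spatial) maps
  ## sign convention: nonnegative skewness
  sk <- apply(S, 1, function(v) mean((v - mean(v))^3) / stats::sd(v)^3)
  flip <- ifelse(sk < 0, -1, 1)
  S <- flip * S
  scl <- apply(S, 1, stats::sd)
  S <- S / scl
  Wt <- diag(flip / scl) %*% res$W %*% K    # total unmixing on centred reduced
  kurt <- apply(S, 1, function(v) mean((v - mean(v))^4) / stats::var(v)^2 - 3)
  structure(list(
    maps = t(S),
    unmixing = Wt,
    mixing = solve(Wt),
    n_components = k,
    centre = centre,
    converged = res$converged,
    iterations = res$iterations,
    kurtosis = kurt,
    identifiable = any(abs(kurt) > 0.2),
    seed = seed
  ), class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components over %d voxels (%s, %d iterations)\n",
              x$n_components, nrow(x$maps),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Select stable components across repeated ICA runs
#'
#' Pools the components of all runs, clusters them by average-linkage
#' agglomeration of the dissimilarity `1 - |spatial correlation|`, and
#' returns each cluster's centrotype (the member with the largest summed
#' intra-cluster similarity). The stability index of a cluster is its mean
#' intra-cluster similarity minus its mean similarity to the nearest other
#' cluster, clipped to [0, 1].
#'
#' @param runs list of `component_set`s from different seeds (>= 2), all
#'   with the same component count.
#' @param n_components number of clusters to form.
#' @return A `component_set` of centrotypes with `stability` (per
#'   component), `cluster_sizes` and the originating `run`/`component`
#'   bookkeeping.
#' @export
icasso_select <- function(runs, n_components) {
  if (length(runs) < 2) stop("need at least 2 runs")
  kk <- vapply(runs, function(r) r$n_components, 1L)
  if (any(kk != n_components)) {
    stop("all runs must have n_components components")
  }
  allmaps <- do.call(cbind, lapply(runs, `[[`, "maps"))
  m <- ncol(allmaps)
  sim <- abs(stats::cor(allmaps))
  cl <- stats::cutree(stats::hclust(stats::as.dist(1 - sim), method = "average"),
                      k = n_components)
  run_of <- rep(seq_along(runs), each = n_components)
  comp_of <- rep(seq_len(n_components), times = length(runs))
  centro <- integer(n_components)
  stability <- numeric(n_components)
  for (c_i in seq_len(n_components)) {
    members <- which(cl == c_i)
    if (length(members) == 1) {
      centro[c_i] <- members
    } else {
      intra <- rowSums(sim[members, members, drop = FALSE])
      centro[c_i] <- members[which.max(intra)]
    }
    within <- if (length(members) == 1) 1 else {
      Sm <- sim[members, members, drop = FALSE]
      mean(Sm[upper.tri(Sm)])
    }
    other_means <- vapply(setdiff(seq_len(n_components), c_i), function(o) {
      mean(sim[members, cl == o, drop = FALSE])
    }, numeric(1))
    nearest <- if (length(other_means)) max(other_means) else 0
    stability[c_i] <- min(1, max(0, within - nearest))
  }
  ## order clusters by descending stability for a deterministic layout
  sizes <- as.integer(table(factor(cl, levels = seq_len(n_components))))
  ord <- order(-stability, centro)
  centro <- centro[ord]; stability <- stability[ord]; sizes <- sizes[ord]
  maps <- allmaps[, centro, drop = FALSE]
  unmixing <- do.call(rbind, lapply(centro, function(ix) {
    runs[[run_of[ix]]]$unmixing[comp_of[ix], , drop = FALSE]
  }))
  mixing <- tryCatch(solve(unmixing), error = function(e) MASS::ginv(unmixing))
  structure(list(
    maps = maps,
    unmixing = unmixing,
    mixing = mixing,
    n_components = n_components,
    centre = runs[[1]]$centre,
    converged = all(vapply(runs, `[[`, TRUE, "converged")),
    iterations = NA_integer_,
    stability = stability,
    cluster_sizes = sizes,
    centrotype_run = run_of[centro],
    centrotype_component = comp_of[centro],
    seed = NA_integer_
  ), class = "component_set")
}

#' Back-reconstruct per-session maps and time courses
#'
#' GICA-style back-reconstruction: each session's component time courses
#' are obtained by pushing the group mixing matrix back through that
#' session's stored stage projections, and its spatial maps by regressing
#' the session's (voxel-centred) data on those time courses. By default a
#' dual-regression refinement follows: the returned time courses are
#' re-estimated by regressing the session data on the subject maps, which
#' pools information over all of a component's voxels instead of only the
#' retained PCA subspace.
#'
#' @param group a `component_set` from [infomax_ica()] or [icasso_select()].
#' @param reduction the `projections` element of [reduce_stagewise_pca()].
#' @param sessions the original session list used for the reduction.
#' @param tc_sessions optional parallel session list used for the
#'   dual-regression time-course stage. Spatial smoothing helps the
#'   voxelwise map statistics but blurs overlapping or boundary-truncated
#'   sources into each other, degrading extracted time courses; passing
#'   the unsmoothed sessions here re-estimates each session's time courses
#'   by regressing those data on the session's spatial maps.
#' @return list with `timecourses` (per session, T x k) and `maps`
#'   (per session, V x k).
#' @export
back_reconstruct <- function(group, reduction, sessions, tc_sessions = NULL) {
  comp <- reduction$composite
  if (length(comp) != length(sessions)) {
    stop("projection/session mismatch: different session counts")
  }
  if (!is.null(tc_sessions) && length(tc_sessions) != length(sessions)) {
    stop("tc_sessions must parallel sessions")
  }
  A <- group$mixing                        # d3 x k
  out_tc <- vector("list", length(sessions))
  out_maps <- vector("list", length(sessions))
  unit_sd <- function(M) sweep(M, 2, apply(M, 2, stats::sd), `/`)
  for (i in seq_along(sessions)) {
    Y <- if (inherits(sessions[[i]], "fmri_session")) sessions[[i]]$data else sessions[[i]]
    Yc <- sweep(Y, 2, colMeans(Y), `-`)
    TC <- unit_sd(comp[[i]] %*% A)         # T x k, unit-variance convention:
    M <- qr.coef(qr(TC), Yc)               # map intensity carries the
    if (!is.null(tc_sessions)) {           # session's component amplitude
      Y2 <- if (inherits(tc_sessions[[i]], "fmri_session")) tc_sessions[[i]]$data else tc_sessions[[i]]
      Y2c <- sweep(Y2, 2, colMeans(Y2), `-`)
      TC <- unit_sd(Y2c %*% t(M) %*% solve(tcrossprod(M)))
      colnames(TC) <- colnames(A)
    }
    out_tc[[i]] <- TC
    out_maps[[i]] <- t(M)
  }
  names(out_tc) <- names(sessions)
  names(out_maps) <- names(sessions)
  list(timecourses = out_tc, maps = out_maps)
}

#' Match components to network templates
#'
#' Greedy best-first assignment: repeatedly take the highest remaining
#' spatial correlation between an unassigned component and an unassigned
#' template. Assignments whose score falls below the threshold are reported
#' unmatched. Ties break toward the lower component index.
#'
#' @param maps V x k matrix of component spatial maps.
#' @param templates a `spatial_source_set`.
#' @param threshold minimum correlation to accept a match (default 0.3).
#' @return data.frame with `network`, `component` (NA when unmatched) and
#'   `score`.
#' @export
match_components <- function(maps, templates, threshold = 0.3) {
  if (ncol(maps) < length(templates$names)) {
    stop("need at least as many components as templates")
  }
  cc <- stats::cor(templates$maps, maps)    # templates x components
  nets <- templates$names
  assigned <- data.frame(network = nets, component = NA_integer_,
                         score = NA_real_)
  free_t <- seq_along(nets)
  free_c <- seq_len(ncol(maps))
  while (length(free_t) && length(free_c)) {
    sub <- cc[free_t, free_c, drop = FALSE]
    best <- max(sub)
    if (best < threshold) break
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 2], hit[, 1]), , drop = FALSE][1, ]  # lower comp index wins
    t_i <- free_t[hit[1]]; c_i <- free_c[hit[2]]
    assigned$component[t_i] <- c_i
    assigned$score[t_i] <- cc[t_i, c_i]
    free_t <- setdiff(free_t, t_i)
    free_c <- setdiff(free_c, c_i)
  }
  assigned
}

#' Group ICA with ICASSO stability selection
#'
#' Full group decomposition: stagewise PCA over the ordered sessions,
#' `n_runs` Infomax runs from different random initialisations (seeds
#' `seed + run index`), ICASSO centrotype selection, and GICA
#' back-reconstruction of per-session maps and time courses.
#'
#' @param sessions ordered list of `fmri_session`s (abstinence block first).
#' @param n_components number of components (or `"mdl"` to estimate by the
#'   median per-session MDL over a voxel-subsampled covariance; supply
#'   sessions whose temporal covariance is full rank — i.e. estimate before
#'   detrending, which removes two degrees of freedom).
#' @param n_runs Infomax restarts pooled by ICASSO (default 20).
#' @param seed master seed.
#' @param stage_dims PCA stage dimensions; third entry is forced to the
#'   component count. Defaults to `c(40, 30, n_components)`.
#' @param block_size stage-2 block size (default 7 sessions).
#' @param tc_sessions optional unsmoothed session list for the time-course
#'   stage of back-reconstruction (see [back_reconstruct()]).
#' @param ... further arguments passed to [infomax_ica()].
#' @return A `group_ica_result`: `group` component set (with stability),
#'   `subject_maps`, `subject_timecourses`, `reduction`, `n_components`.
#' @export
group_ica <- function(sessions, n_components = 20, n_runs = 20, seed = 1,
                      stage_dims = NULL, block_size = 7, tc_sessions = NULL,
                      ...) {
  if (identical(n_components, "mdl")) {
    ks <- vapply(sessions, function(s) {
      Y <- if (inherits(s, "fmri_session")) s$data else s
      sub <- Y[, seq(1, ncol(Y), by = 3), drop = FALSE]  # soften iid violation
      estimate_component_count(t(sub))
    }, 1L)
    n_components <- max(2L, as.integer(stats::median(ks)))
  }
  if (is.null(stage_dims)) stage_dims <- c(40, 30, n_components)
  stage_dims[3] <- n_components
  stage_dims[2] <- max(stage_dims[2], n_components)
  stage_dims[1] <- max(stage_dims[1], stage_dims[2])
  red <- reduce_stagewise_pca(sessions, stage_dims, block_size)
  runs <- lapply(seq_len(n_runs), function(r) {
    infomax_ica(red$reduced, seed = seed + r, ...)
  })
  group <- if (n_runs > 1) icasso_select(runs, n_components) else runs[[1]]
  br <- back_reconstruct(group, red$projections, sessions, tc_sessions)
  structure(list(group = group,
                 subject_maps = br$maps,
                 subject_timecourses = br$timecourses,
                 reduction = red$projections,
                 n_components = n_components,
                 n_runs = n_runs, seed = seed),
            class = "group_ica_result")
}

#' @export
print.group_ica_result <- function(x, ...) {
  cat(sprintf("<group_ica_result> %d components, %d sessions, %d ICASSO runs\n",
              x$n_components, length(x$subject_maps), x$n_runs))
  if (!is.null(x$group$stability)) {
    cat("  stability:", paste(sprintf("%.2f", x$group$stability), collapse = " "), "\n")
  }
  invisible(x)
}
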