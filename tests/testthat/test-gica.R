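test_that("MDL picks the planted dimension on a constructed spectrum", {
  ## 5 strong components over a flat noise floor, eigen-gap 10x
  eigs <- c(50, 40, 30, 25, 20, rep(2, 45))
  expect_equal(estimate_component_count(eigenvalues = eigs, n_obs = 5000), 5)
  ## exactly equal eigenvalues: likelihood term vanishes, penalty wins at 0
  expect_equal(estimate_component_count(eigenvalues = rep(3, 30), n_obs = 5000), 0)
  ## from data: planted low-rank structure plus noise
  set.seed(4)
  N <- 2000; V <- 30
  S <- matrix(rnorm(N * 5), N, 5) %*% matrix(rnorm(5 * V), 5, V) * 2
  X <- S + matrix(rnorm(N * V), N, V)
  expect_equal(estimate_component_count(X), 5)
  ## duplicated variable -> singular covariance
  expect_error(estimate_component_count(cbind(X, X[, 1])), "rank-deficient")
  expect_error(estimate_component_count(matrix(rnorm(20), 4, 5)),
               "more observations")
})

test_that("stagewise PCA collapses to plain PCA and captures exact rank", {
  set.seed(7)
  Y <- matrix(rnorm(60 * 200), 60, 200)
  one <- reduce_stagewise_pca(list(Y), stage_dims = c(5, 5, 5))
  ## single session, equal dims: composite projection spans the top-5 PCA
  ## subspace (projection matrices agree)
  Yc <- sweep(Y, 2, colMeans(Y), `-`)
  sv <- svd(Yc, nu = 5)
  C <- one$projections$composite[[1]]
  P_direct <- tcrossprod(sv$u)
  P_staged <- C %*% solve(crossprod(C), t(C))
  expect_lt(max(abs(P_direct - P_staged)), 1e-8)
  ## round-trip on the retained subspace reproduces it
  expect_lt(max(abs(P_staged %*% sv$u - sv$u)), 1e-8)

  ## data of exact rank r: residual of the retained space is ~0
  r <- 4
  L <- matrix(rnorm(50 * r), 50, r) %*% matrix(rnorm(r * 300), r, 300)
  sessions <- list(L[1:25, ], L[26:50, ])
  red <- reduce_stagewise_pca(sessions, stage_dims = c(r, r, r), block_size = 1)
  for (i in 1:2) {
    Yc_i <- sweep(sessions[[i]], 2, colMeans(sessions[[i]]), `-`)
    Pi <- red$projections$composite[[i]]
    resid <- Yc_i - Pi %*% qr.coef(qr(Pi), Yc_i)
    expect_lt(max(abs(resid)), 1e-8)
  }
  expect_error(reduce_stagewise_pca(list(Y), stage_dims = c(5, 10, 3)),
               "d1 >= d2 >= d3")
})

test_that("group reduction to k components has k rows and V columns", {
  set.seed(8)
  sessions <- lapply(1:6, function(i) matrix(rnorm(40 * 500), 40, 500))
  red <- reduce_stagewise_pca(sessions, stage_dims = c(20, 15, 10), block_size = 3)
  expect_equal(dim(red$reduced), c(10, 500))
  expect_length(red$projections$composite, 6)
  expect_equal(dim(red$projections$composite[[4]]), c(40, 10))
})

test_that("Infomax separates a Laplacian toy into the true sources", {
  toy <- laplacian_toy(n = 5000, seed = 3)
  cs <- infomax_ica(toy$X, seed = 11)
  expect_true(cs$converged)
  expect_gte(match_two(t(cs$maps), toy$S), 0.99)
  ## unmixing x whitened-mixing ~ signed permutation (Amari-style check)
  P <- abs(cs$unmixing %*% toy$A)
  P <- P / apply(P, 1, max)
  off <- sum(P) - sum(apply(P, 1, max))
  expect_lt(off / 2, 0.05)
})

test_that("already-unmixed input converges to a signed permutation", {
  toy <- laplacian_toy(n = 5000, seed = 5, mixing = diag(2))
  cs <- infomax_ica(toy$X, seed = 2)
  P <- abs(cs$unmixing %*% diag(apply(toy$X, 1, sd)))
  P <- P / apply(P, 1, max)
  expect_lt(max(P[P < 1]), 0.05)
})

test_that("Gaussian sources are flagged non-identifiable", {
  set.seed(6)
  X <- matrix(rnorm(2 * 6000), 2, 6000)
  cs <- infomax_ica(X, seed = 4)
  expect_false(cs$identifiable)
  toy <- laplacian_toy(n = 4000, seed = 8)
  expect_true(infomax_ica(toy$X, seed = 4)$identifiable)
})

test_that("ICASSO clusters identical and sign-flipped runs correctly", {
  toy <- laplacian_toy(n = 3000, seed = 9)
  base <- infomax_ica(toy$X, seed = 21)
  runs <- replicate(20, base, simplify = FALSE)
  sel <- icasso_select(runs, 2)
  ## within-cluster similarity is exactly 1; the index is reduced only by
  ## the (small) similarity between the two distinct sources
  expect_equal(sel$stability, c(1, 1), tolerance = 0.05)
  expect_equal(sel$cluster_sizes, c(20L, 20L))
  expect_equal(abs(cor(sel$maps[, 1], base$maps[, 1])) > 0.999 ||
                 abs(cor(sel$maps[, 1], base$maps[, 2])) > 0.999, TRUE)

  flipped <- base; flipped$maps <- -base$maps; flipped$unmixing <- -base$unmixing
  sel2 <- icasso_select(list(base, flipped), 2)
  expect_equal(sel2$cluster_sizes, c(2L, 2L))  # sign-invariant metric pairs them
  expect_error(icasso_select(list(base), 2), "at least 2")
})

test_that("ICASSO centrotypes over restarts recover the toy sources", {
  toy <- laplacian_toy(n = 4000, seed = 13)
  runs <- lapply(1:20, function(r) infomax_ica(toy$X, seed = 100 + r))
  sel <- icasso_select(runs, 2)
  expect_gte(match_two(t(sel$maps), toy$S), 0.99)
  expect_gte(min(sel$stability), 0.9)
})

test_that("icasso selection is deterministic for a fixed seed list", {
  toy <- laplacian_toy(n = 2000, seed = 1)
  sel1 <- icasso_select(lapply(1:5, function(r) infomax_ica(toy$X, seed = r)), 2)
  sel2 <- icasso_select(lapply(1:5, function(r) infomax_ica(toy$X, seed = r)), 2)
  expect_identical(sel1$maps, sel2$maps)
})

test_that("MDL-driven group ICA estimates the planted source count", {
  grid <- tiny_grid()
  tm <- tiny_templates(grid)
  truth <- default_truth(seed = 5, grid = grid, sources = tm)
  cohort <- make_cohort(truth, n_subjects = 3, n_timepoints = 80)
  ica <- suppressWarnings(group_ica(cohort$sessions, n_components = "mdl",
                                    n_runs = 2, seed = 5))
  expect_equal(ica$n_components, 2L)
})

test_that("single-session back-reconstruction reproduces the group result", {
  grid <- tiny_grid()
  tm <- tiny_templates(grid)
  set.seed(3)
  tc <- matrix(rnorm(120 * 2), 120, 2, dimnames = list(NULL, tm$names))
  ses <- synthesize_session(tm, tc, noise_sd = 0.2, seed = 5)
  red <- reduce_stagewise_pca(list(s1 = ses), stage_dims = c(2, 2, 2))
  grp <- infomax_ica(red$reduced, seed = 1)
  br <- back_reconstruct(grp, red$projections, list(s1 = ses))
  for (c_i in 1:2) {
    expect_gte(abs(cor(br$maps[[1]][, c_i], grp$maps[, c_i])), 0.999)
  }
  expect_error(back_reconstruct(grp, red$projections, list(ses, ses)),
               "mismatch")
})

test_that("template matching assigns greedily with threshold and tie-breaks", {
  grid <- tiny_grid()
  tm <- tiny_templates(grid)
  maps <- cbind(tm$maps[, "netB"], rnorm(n_voxels(grid)), tm$maps[, "netA"])
  m <- match_components(maps, tm)
  expect_equal(m$component[m$network == "netA"], 3L)
  expect_equal(m$component[m$network == "netB"], 1L)
  expect_equal(m$score[m$network == "netA"], 1)

  ## a pure-noise map stays unmatched at threshold 0.3
  set.seed(10)
  noise_maps <- matrix(rnorm(2 * n_voxels(grid)), ncol = 2)
  m2 <- match_components(noise_maps, tm, threshold = 0.3)
  expect_true(all(is.na(m2$component)))

  ## exact tie: the lower component index wins
  maps3 <- cbind(tm$maps[, "netA"], tm$maps[, "netA"])
  m3 <- match_components(maps3, make_network_templates(grid, data.frame(
    network = "netA", x_mm = -9, y_mm = -9, z_mm = -9, fwhm_mm = 9, amplitude = 2)))
  expect_equal(m3$component, 1L)
})
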