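test_that("z-scoring a map is an exact affine normalization and idempotent", {
  set.seed(1)
  m <- rnorm(500, mean = 5, sd = 2)
  z <- zscore_map(m)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_equal(zscore_map(z), z, tolerance = 1e-10)
  expect_error(zscore_map(rep(2, 10)), "constant")
})

test_that("one-sample t-map matches the closed form and flags degeneracies", {
  maps <- rbind(c(1, 0, 5), c(2, 0, 5), c(3, 0, 5))
  sm <- one_sample_ttest(maps)
  expect_equal(sm$t[1], 2 * sqrt(3), tolerance = 1e-6)  # mean 2, sd 1, n 3
  expect_equal(sm$df, 2L)
  expect_equal(sm$t[2], 0)
  expect_equal(sm$p[2], 1)
  ## zero-variance nonzero-mean voxel: infinity sentinel with p = 0
  expect_equal(sm$t[3], Inf)
  expect_equal(sm$p[3], 0)
  expect_equal(sm$n_degenerate, 1L)
  ## t/p consistency against the Student reference
  set.seed(2)
  M <- matrix(rnorm(20 * 50), 20, 50)
  sm2 <- one_sample_ttest(M)
  expect_equal(sm2$p, 2 * pt(-abs(sm2$t), df = 19), tolerance = 1e-12)
  ## agrees with stats::t.test per voxel
  tt <- t.test(M[, 7])
  expect_equal(sm2$t[7], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(sm2$p[7], tt$p.value, tolerance = 1e-10)
})

test_that("paired t-map is the one-sample test on differences", {
  set.seed(3)
  A <- matrix(rnorm(12 * 40), 12, 40)
  expect_true(all(paired_ttest(A, A)$t == 0))
  B <- A; B[, 5] <- A[, 5] - 1   # constant difference: degenerate sentinel
  sm <- paired_ttest(A, B)
  expect_equal(sm$t[5], Inf)
  expect_equal(sm$n_degenerate, 1L)
  expect_error(paired_ttest(A, B, subjects_a = letters[1:12],
                            subjects_b = rev(letters[1:12])), "misaligned")
  ## equals one_sample on A - B elsewhere
  sm2 <- one_sample_ttest(A - B)
  expect_equal(sm$t, sm2$t)
})

test_that("BH step-up matches hand-computed cases and p.adjust", {
  r <- fdr_threshold(c(0.001, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  expect_equal(r$critical_p, 0.04)
  expect_false(any(fdr_threshold(c(0.9, 0.8), 0.05)$reject))
  expect_true(fdr_threshold(0.049, 0.05)$reject)
  expect_error(fdr_threshold(numeric(0), 0.05), "empty")
  expect_error(fdr_threshold(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
  ## equivalence with the BH adjustment for random p-lists
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    for (q in c(0.01, 0.05, 0.1)) {
      expect_equal(fdr_threshold(p, q)$reject, p.adjust(p, "BH") <= q)
    }
  }
})

test_that("BH rejections are monotone in q", {
  set.seed(5)
  for (i in 1:10) {
    p <- runif(40)^2
    r1 <- fdr_threshold(p, 0.01)$reject
    r5 <- fdr_threshold(p, 0.05)$reject
    expect_true(all(r5[r1]))   # q = 0.01 set is a subset of q = 0.05 set
  }
})

test_that("voxelwise type-I error is nominal on null data", {
  set.seed(6)
  n_vox <- 20000
  M <- matrix(rnorm(10 * n_vox), 10, n_vox)
  sm <- one_sample_ttest(M)
  frac <- mean(sm$p < 0.05)
  ci <- qbinom(c(0.0005, 0.9995), n_vox, 0.05) / n_vox
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("cluster extraction matches a union-find oracle on random masks", {
  grid <- tiny_grid(c(12, 12, 12))
  set.seed(7)
  for (rep in 1:12) {
    conn <- sample(c(6, 18, 26), 1)
    t_vals <- rnorm(n_voxels(grid))
    p_vals <- 2 * pnorm(-abs(t_vals) * 2)   # some suprathreshold voxels
    sm <- structure(list(t = t_vals, p = p_vals, df = 9L, test = "one_sample",
                         n_degenerate = 0L, grid = grid), class = "stat_map")
    cl <- extract_clusters(sm, p_thresh = 0.05, min_extent = 1,
                           connectivity = conn)
    mask_pos <- array(t_vals > 0 & p_vals < 0.05, grid$dims)
    mask_neg <- array(t_vals < 0 & p_vals < 0.05, grid$dims)
    oracle <- c(flood_fill_oracle(mask_pos, conn), flood_fill_oracle(mask_neg, conn))
    expect_equal(length(cl), length(oracle))
    got <- lapply(cl, function(c) sort(c$member_voxels))
    want <- lapply(oracle, function(v) sort(unname(v)))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
    ## peak attains the max |t| in its member set
    for (c_i in cl) {
      expect_equal(abs(c_i$peak_t), max(abs(t_vals[c_i$member_voxels])))
      expect_true(c_i$peak_voxel %in% c_i$member_voxels)
    }
  }
})

test_that("min extent, connectivity and ordering behave as specified", {
  grid <- tiny_grid(c(12, 12, 12))
  t_vals <- rep(0, n_voxels(grid))
  ## one 30-voxel block and one 5-voxel block
  big <- as.vector(outer(outer(2:6, (2:7 - 1) * 12, `+`), (2:2 - 1) * 144, `+`))
  small <- as.vector(outer(outer(9:11, (9 - 1) * 12, `+`), (c(9, 10) - 1) * 144, `+`))[1:5]
  t_vals[big] <- 5; t_vals[small] <- 5
  p_vals <- ifelse(t_vals != 0, 1e-4, 0.5)
  sm <- structure(list(t = t_vals, p = p_vals, df = 9L, test = "one_sample",
                       n_degenerate = 0L, grid = grid), class = "stat_map")
  cl <- extract_clusters(sm, 0.005, min_extent = 20)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size_voxels, 30)

  ## corner-touching voxels: one cluster at 26, two at 6
  t2 <- rep(0, n_voxels(grid))
  v1 <- voxel_index(grid, c(5, 5, 5)); v2 <- voxel_index(grid, c(6, 6, 6))
  t2[c(v1, v2)] <- 4
  p2 <- ifelse(t2 != 0, 1e-4, 0.5)
  sm2 <- structure(list(t = t2, p = p2, df = 9L, test = "one_sample",
                        n_degenerate = 0L, grid = grid), class = "stat_map")
  expect_length(extract_clusters(sm2, 0.005, 1, connectivity = 26), 1)
  expect_length(extract_clusters(sm2, 0.005, 1, connectivity = 6), 2)

  ## single suprathreshold voxel at min_extent 1
  t3 <- rep(0, n_voxels(grid)); t3[v1] <- 6
  p3 <- ifelse(t3 != 0, 1e-5, 0.5)
  sm3 <- structure(list(t = t3, p = p3, df = 9L, test = "one_sample",
                        n_degenerate = 0L, grid = grid), class = "stat_map")
  cl3 <- extract_clusters(sm3, 0.005, 1)
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$peak_voxel, v1)
  expect_equal(cl3[[1]]$peak_mm, voxel_to_mm(grid, c(5, 5, 5)))

  ## deterministic ordering: direction then descending peak |t|
  t4 <- t3; t4[v2] <- -8
  p4 <- ifelse(t4 != 0, 1e-5, 0.5)
  sm4 <- structure(list(t = t4, p = p4, df = 9L, test = "paired",
                        n_degenerate = 0L, grid = grid), class = "stat_map")
  cl4 <- extract_clusters(sm4, 0.005, 1)
  expect_equal(vapply(cl4, `[[`, "", "direction"), c("A>B", "B>A"))
})

test_that("ROIs are exactly the 27-voxel block and respect boundaries", {
  grid <- tiny_grid(c(12, 12, 12))
  roi <- define_roi(c(10, 10, 10), grid, "test")
  expect_length(roi$member_voxels, 27)
  ijk <- arrayInd(roi$member_voxels, grid$dims)
  expect_true(all(ijk >= 9 & ijk <= 11))
  expect_error(define_roi(c(1, 5, 5), grid), "boundary")
  expect_error(define_roi(c(5, 12, 5), grid), "boundary")
})

test_that("ROI time series is the zero-mean voxel average", {
  grid <- tiny_grid(c(6, 6, 6))
  roi <- define_roi(c(3, 3, 3), grid)
  v <- sin(seq_len(80) / 5) + 2
  data <- matrix(rnorm(80 * 216), 80, 216)
  data[, roi$member_voxels] <- v   # all ROI voxels share the series
  ses <- fmri_session("s", "abstinence", grid, 2, data)
  ts <- roi_timeseries(ses, roi)
  expect_equal(ts, v - mean(v), tolerance = 1e-12)
  expect_equal(mean(ts), 0, tolerance = 1e-12)
})
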