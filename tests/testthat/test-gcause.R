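sim_var2 <- function(T, A1, A2 = NULL, seed = 1, sd = 1) {
  k <- nrow(A1)
  lags <- if (is.null(A2)) 1 else 2
  co <- array(0, c(lags, k, k))
  co[1, , ] <- A1
  if (!is.null(A2)) co[2, , ] <- A2
  simulate_var_timecourses(T, causal_spec(co, sd), seed = seed)
}

test_that("segments keep their boundaries and count usable rows", {
  s1 <- matrix(rnorm(150 * 2), 150, 2, dimnames = list(NULL, c("a", "b")))
  s2 <- matrix(rnorm(150 * 2), 150, 2, dimnames = list(NULL, c("a", "b")))
  ss <- concatenate_segments(list(s1, s2))
  expect_equal(restconn:::usable_rows(ss, 2), 2 * 148)
  bad <- s2; colnames(bad) <- c("b", "a")
  expect_error(concatenate_segments(list(s1, bad)), "same nodes")
})

test_that("segmented fitting equals block-OLS and differs from naive concatenation", {
  set.seed(11)
  A <- matrix(c(0.5, 0.3, 0, 0.4), 2, 2, byrow = TRUE)
  s1 <- sim_var2(100, A, seed = 1)
  s2 <- sim_var2(100, A, seed = 2)
  ss <- concatenate_segments(list(s1, s2))
  vm <- fit_var(ss, 1)
  ## oracle: explicit block OLS pooling the two segments' normal equations
  X <- rbind(s1[1:99, ], s2[1:99, ])
  Y <- rbind(s1[2:100, ], s2[2:100, ])
  B_oracle <- solve(crossprod(X), crossprod(X, Y))
  expect_equal(vm$coeffs[1, , ], t(B_oracle), tolerance = 1e-10,
               ignore_attr = TRUE)
  ## naive concatenation crossing the seam gives different estimates
  cat_naive <- rbind(s1, s2)
  B_naive <- solve(crossprod(cat_naive[1:199, ]),
                   crossprod(cat_naive[1:199, ], cat_naive[2:200, ]))
  expect_gt(max(abs(B_naive - B_oracle)), 1e-8)
  expect_equal(vm$n_obs, 198)
})

test_that("noiseless and noisy VAR coefficients are recovered", {
  ## noiseless x(t) = 0.5 x(t-1): exact recovery, zero residual
  x <- matrix(0.5^(0:60) * 10, ncol = 1, dimnames = list(NULL, "x"))
  ss <- concatenate_segments(list(x))
  vm <- fit_var(ss, 1)
  expect_equal(unname(vm$coeffs[1, 1, 1]), 0.5, tolerance = 1e-10)
  expect_lt(vm$rss, 1e-15)

  ## bivariate driving: OLS consistency at T = 2000
  A <- matrix(c(0.3, 0, 0.8, 0.3), 2, 2, byrow = TRUE)  # x2 <- 0.8 x1
  xx <- sim_var2(2000, A, seed = 4)
  vm2 <- fit_var(concatenate_segments(list(xx)), 1)
  expect_gte(vm2$coeffs[1, "x2", "x1"], 0.75)
  expect_lte(vm2$coeffs[1, "x2", "x1"], 0.85)

  ## duplicated node series: collinear design
  dup <- cbind(xx, xx[, 1]); colnames(dup) <- c("x1", "x2", "x3")
  expect_error(fit_var(concatenate_segments(list(dup)), 1), "collinear")
})

test_that("planted VAR coefficients are recovered within 2 SE at cohort scale", {
  truth <- default_truth(seed = 30)
  spec <- truth$causal_by_condition$abstinence
  segs <- lapply(1:21, function(s) simulate_var_timecourses(150, spec, seed = 300 + s))
  ss <- concatenate_segments(lapply(segs, standardize, mode = "zero_mean"))
  vm <- fit_var(ss, 2)
  ## standard error of a VAR coefficient ~ sd(e)/sd(x)/sqrt(n); use 2 SE bound
  n <- vm$n_obs
  se_bound <- 2 * 1.5 / sqrt(n)
  expect_lt(abs(vm$coeffs[1, "pDMN", "SN"] - 0.4), se_bound + 0.02)
  expect_lt(abs(vm$coeffs[1, "aDMN", "aDMN"] - 0.3), se_bound + 0.02)
  expect_lt(abs(vm$coeffs[2, "ECN", "ECN"] - 0.2), se_bound + 0.02)
})

test_that("BIC selects the true order and collapses to 1 under the null", {
  ## strong lag-2 structure, T = 500 (documented coefficients)
  A1 <- matrix(c(0.25, 0, 0.2, 0.25), 2, 2, byrow = TRUE)
  A2 <- matrix(c(0.4, 0, 0.3, 0.4), 2, 2, byrow = TRUE)
  hits <- sum(vapply(1:20, function(s) {
    x <- sim_var2(500, A1, A2, seed = s)
    select_order_bic(concatenate_segments(list(x)), max_order = 5) == 2L
  }, TRUE))
  expect_gte(hits, 18)

  ## white noise: penalty dominates, smallest candidate wins
  nulls <- vapply(1:20, function(s) {
    x <- sim_var2(300, matrix(0, 2, 2), seed = 100 + s)
    select_order_bic(concatenate_segments(list(x)), max_order = 4)
  }, 1L)
  expect_gte(mean(nulls == 1L), 0.8)

  x <- sim_var2(40, matrix(0, 2, 2), seed = 1)
  expect_error(select_order_bic(concatenate_segments(list(x)), max_order = 10),
               "too large")
})

test_that("Granger F agrees with lmtest on a single segment", {
  skip_if_not_installed("lmtest")
  A <- matrix(c(0.3, 0, 0.5, 0.3), 2, 2, byrow = TRUE)
  x <- sim_var2(400, A, seed = 7)
  x <- scale(x, scale = FALSE)
  ss <- concatenate_segments(list(x))
  for (p in 1:2) {
    edge <- granger_f(ss, "x1", "x2", order = p)
    ## lmtest fits with intercept; on centred data the F statistics agree
    ref <- lmtest::grangertest(x[, 1], x[, 2], order = p)
    expect_equal(edge$f, ref$F[2], tolerance = 0.02)
  }
})

test_that("directed power and null behaviour of the pair test", {
  A <- matrix(c(0.3, 0, 0.8, 0.3), 2, 2, byrow = TRUE)
  x <- sim_var2(2000, A, seed = 9)
  ss <- concatenate_segments(list(scale(x, scale = FALSE)))
  fwd <- granger_f(ss, "x1", "x2", 1)
  rev <- granger_f(ss, "x2", "x1", 1)
  expect_lt(fwd$p_value, 1e-6)
  expect_gt(rev$p_value, 1e-4)   # reverse direction behaves as a null
  expect_error(granger_f(ss, "x1", "x1", 1), "must differ")

  ## deterministic dependence: degenerate residual branch is flagged
  z <- rnorm(200)
  det <- cbind(x1 = z[2:200], x2 = z[1:199])
  det_ss <- concatenate_segments(list(det))
  ## x1 lags reproduce x2 exactly: zero full-model residual
  expect_error(granger_f(det_ss, "x1", "x2", 1), "numerically zero")
})

test_that("pairwise evaluation covers k(k-1) ordered pairs deterministically", {
  set.seed(12)
  x4 <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, letters[1:4]))
  e4 <- pairwise_granger(concatenate_segments(list(x4)), order = 1)
  expect_equal(nrow(e4), 12)
  expect_equal(e4$source[1:3], c("a", "a", "a"))   # source-major order
  x8 <- matrix(rnorm(300 * 8), 300, 8, dimnames = list(NULL, letters[1:8]))
  expect_equal(nrow(pairwise_granger(concatenate_segments(list(x8)), order = 1)), 56)
})

test_that("graph thresholding keeps BH-significant edges only", {
  edges <- data.frame(source = c("a", "a", "b"), target = c("b", "c", "c"),
                      f = c(1, 2, 50), p_value = c(0.5, 0.5, 1e-9))
  g <- build_causal_graph(edges, q = 0.01, nodes = c("a", "b", "c"))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$source, "b")
  g_none <- build_causal_graph(transform(edges, p_value = 0.5), q = 0.01)
  expect_equal(nrow(g_none$edges), 0)
  expect_error(build_causal_graph(edges[0, ], 0.01), "empty")
})

test_that("out-in degrees reproduce the packaged ROI tables and sum to zero", {
  gA <- read_edge_table(edges_fixture_path("abstinence"), nodes = roi_node_names)
  gS <- read_edge_table(edges_fixture_path("satiety"), nodes = roi_node_names)
  dA <- out_in_degree(gA)
  dS <- out_in_degree(gS)
  expect_equal(dA$out_in, c(2, -3, 2, -2, 1, 0, 2, -2))
  expect_equal(dS$out_in, c(-1, 0, 3, -1, 0, -1, 0, 0))
  expect_equal(sum(dA$out_in), 0)
  expect_equal(sum(dS$out_in), 0)

  empty <- structure(list(nodes = c("a", "b"),
                          edges = data.frame(source = character(),
                                             target = character())),
                     class = "causal_graph")
  expect_true(all(out_in_degree(empty)$out_in == 0))
  single <- structure(list(nodes = c("a", "b", "c"),
                           edges = data.frame(source = "a", target = "b")),
                      class = "causal_graph")
  expect_equal(out_in_degree(single)$out_in, c(1, -1, 0))
})

test_that("FDR-controlled pipeline keeps family error under q on null cohorts", {
  false_any <- vapply(1:40, function(s) {
    segs <- lapply(1:4, function(i)
      sim_var2(120, matrix(0, 3, 3), seed = s * 10 + i))
    ss <- concatenate_segments(lapply(segs, standardize, mode = "zero_mean"))
    edges <- pairwise_granger(ss, order = 1)
    nrow(build_causal_graph(edges, q = 0.05)$edges) > 0
  }, TRUE)
  ## BH at q = 0.05 over 6 tests: any-rejection rate stays well under 0.25
  expect_lte(mean(false_any), 0.25)
})
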