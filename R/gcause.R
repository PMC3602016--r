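#' Bundle per-subject multivariate series into segments
#'
#' Concatenation across subjects is handled by keeping each subject-session
#' as a separate segment: lagged design matrices are built within segments
#' only, so no regression row ever crosses a segment boundary.
#'
#' @param segments list of T_r x k matrices with identical column names
#'   (node names) in identical order.
#' @param condition optional condition label.
#' @param node_names node names (defaults to the first segment's colnames).
#' @return a `segmented_series`.
#' @export
concatenate_segments <- function(segments, condition = NA_character_,
                                 node_names = NULL) {
  if (!length(segments)) stop("no segments supplied")
  segments <- lapply(segments, as.matrix)
  if (is.null(node_names)) node_names <- colnames(segments[[1]])
  if (is.null(node_names)) node_names <- paste0("x", seq_len(ncol(segments[[1]])))
  for (s in segments) {
    nm <- colnames(s)
    if (ncol(s) != length(node_names) ||
        (!is.null(nm) && !identical(nm, node_names))) {
      stop("all segments must share the same nodes in the same order")
    }
  }
  structure(list(node_names = node_names, segments = segments,
                 condition = condition),
            class = "segmented_series")
}

#' @export
print.segmented_series <- function(x, ...) {
  cat(sprintf("<segmented_series> %d nodes x %d segments (T = %s)%s\n",
              length(x$node_names), length(x$segments),
              paste(range(vapply(x$segments, nrow, 1L)), collapse = "-"),
              if (is.na(x$condition)) "" else paste0(", ", x$condition)))
  invisible(x)
}

## usable regression rows at order p: sum over segments of (T_r - p)
usable_rows <- function(series, p) {
  sum(vapply(series$segments, nrow, 1L) - p)
}

## Pooled lagged design over segments. Response rows start at `start`
## (>= p + 1) within each segment so different orders can share rows.
## Columns are ordered lag-major: lag 1 nodes, lag 2 nodes, ...
lag_design <- function(series, p, nodes = NULL, start = p + 1) {
  if (is.null(nodes)) nodes <- series$node_names
  Y <- NULL; X <- NULL
  for (seg in series$segments) {
    T <- nrow(seg)
    if (start > T) stop("segment too short for requested order")
    rows <- start:T
    Y <- rbind(Y, seg[rows, , drop = FALSE])
    X <- rbind(X, do.call(cbind, lapply(seq_len(p), function(j) {
      block <- seg[rows - j, nodes, drop = FALSE]
      colnames(block) <- paste0(nodes, ".l", j)
      block
    })))
  }
  list(Y = Y, X = X, n = nrow(Y))
}

#' Select the VAR model order by BIC
#'
#' Fits the full multivariate VAR for each candidate order on a common set
#' of regression rows (those available at `max_order`, so criteria are
#' comparable) and returns the order minimizing
#' `n * log det(Sigma_resid) + k^2 p * log(n)`.
#'
#' @param series a `segmented_series`.
#' @param max_order largest candidate order (>= 1; every segment must have
#'   at least `5 * max_order` rows).
#' @return the selected order (integer in 1..max_order).
#' @export
select_order_bic <- function(series, max_order = 6) {
  if (max_order < 1) stop("max_order must be >= 1")
  Tmin <- min(vapply(series$segments, nrow, 1L))
  if (max_order > Tmin / 5) {
    stop(sprintf("max_order %d too large for segments of length %d (need T >= 5p)",
                 max_order, Tmin))
  }
  k <- length(series$node_names)
  bic <- vapply(seq_len(max_order), function(p) {
    d <- lag_design(series, p, start = max_order + 1)
    E <- qr.resid(qr(d$X), d$Y)
    S <- crossprod(E) / d$n
    ld <- determinant(S, logarithm = TRUE)
    as.numeric(d$n * ld$modulus + (k^2 * p) * log(d$n))
  }, numeric(1))
  which.min(bic)
}

#' Fit a vector autoregression on segmented series
#'
#' Per-equation ordinary least squares pooled over within-segment rows,
#' without an intercept (inputs are expected zero-mean per segment).
#'
#' @param series a `segmented_series`.
#' @param order VAR order p (>= 1).
#' @return a `var_model`: `order`, `coeffs` array `[lag, target, source]`,
#'   `residuals` (pooled n_obs x k), `rss` per equation, `n_obs`.
#' @export
fit_var <- function(series, order) {
  if (order < 1) stop("order must be >= 1")
  k <- length(series$node_names)
  d <- lag_design(series, order)
  qx <- qr(d$X)
  if (qx$rank < ncol(d$X)) {
    aliased <- colnames(d$X)[qx$pivot[(qx$rank + 1):ncol(d$X)]]
    stop("collinear regressors: ", paste(aliased, collapse = ", "))
  }
  B <- qr.coef(qx, d$Y)                       # (k*p) x k
  E <- qr.resid(qx, d$Y)
  coeffs <- array(0, c(order, k, k),
                  dimnames = list(NULL, series$node_names, series$node_names))
  for (j in seq_len(order)) {
    rows <- ((j - 1) * k + 1):(j * k)
    coeffs[j, , ] <- t(B[rows, , drop = FALSE])  # [target, source]
  }
  structure(list(order = order, coeffs = coeffs, residuals = E,
                 rss = colSums(E^2), n_obs = d$n,
                 node_names = series$node_names),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> order %d, %d nodes, n_obs %d\n",
              x$order, length(x$node_names), x$n_obs))
  invisible(x)
}

#' Granger causality F-test for one directed pair
#'
#' Tests whether the source node's past improves prediction of the target
#' beyond the target's own past. By default the test is bivariate (the
#' model contains only the pair); `conditional = TRUE` conditions on all
#' remaining nodes' lags instead. F = ((RSS_restricted - RSS_full) / p) /
#' (RSS_full / (n - k_full)) with a F(p, n - k_full) reference.
#'
#' @param series a `segmented_series`.
#' @param source,target node names (distinct).
#' @param order VAR order p.
#' @param conditional include all other nodes' lags in both models.
#' @return a `causal_edge` data.frame row: `source`, `target`, `f`, `p_value`,
#'   `df1`, `df2`.
#' @export
granger_f <- function(series, source, target, order, conditional = FALSE) {
  if (identical(source, target)) stop("source and target must differ")
  stopifnot(source %in% series$node_names, target %in% series$node_names)
  others <- if (conditional) setdiff(series$node_names, c(source, target)) else character()
  full_nodes <- c(target, source, others)
  restr_nodes <- c(target, others)
  df <- lag_design(series, order, nodes = full_nodes)
  y <- df$Y[, target]
  keep_restr <- as.vector(outer(match(restr_nodes, full_nodes),
                                (seq_len(order) - 1) * length(full_nodes), `+`))
  rss_full <- sum(qr.resid(qr(df$X), y)^2)
  rss_restr <- sum(qr.resid(qr(df$X[, keep_restr, drop = FALSE]), y)^2)
  k_full <- ncol(df$X)
  n <- df$n
  if (rss_full <= .Machine$double.eps * n) {
    stop(sprintf("undefined F for %s -> %s: full-model residual is numerically zero",
                 source, target))
  }
  f <- ((rss_restr - rss_full) / order) / (rss_full / (n - k_full))
  f <- max(f, 0)
  p_value <- stats::pf(f, order, n - k_full, lower.tail = FALSE)
  structure(data.frame(source = source, target = target, f = f,
                       p_value = p_value, df1 = order, df2 = n - k_full,
                       stringsAsFactors = FALSE),
            class = c("causal_edge", "data.frame"))
}

#' Granger F-tests for every ordered node pair
#'
#' Evaluates [granger_f()] for all k(k-1) directed pairs in deterministic
#' source-major order.
#'
#' @inheritParams granger_f
#' @param order VAR order p (or `"bic"` to select via [select_order_bic()]).
#' @param max_order BIC search bound when `order = "bic"`.
#' @return data.frame of edges (`source`, `target`, `f`, `p_value`, ...),
#'   with the used order in attribute `"order"`.
#' @export
pairwise_granger <- function(series, order = "bic", conditional = FALSE,
                             max_order = 6) {
  if (length(series$node_names) < 2) stop("need at least 2 nodes")
  if (identical(order, "bic")) order <- select_order_bic(series, max_order)
  nodes <- series$node_names
  rows <- list()
  for (src in nodes) {
    for (tgt in nodes) {
      if (src == tgt) next
      edge <- tryCatch(granger_f(series, src, tgt, order, conditional),
                       error = function(e) {
                         stop(sprintf("pair %s -> %s: %s", src, tgt,
                                      conditionMessage(e)), call. = FALSE)
                       })
      rows[[length(rows) + 1]] <- edge
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "order") <- order
  out
}

#' Threshold edges into a directed causal graph
#'
#' Benjamini-Hochberg FDR across all evaluated directed edges of one
#' condition; edges surviving at level `q` form the graph.
#'
#' @param edges data.frame from [pairwise_granger()].
#' @param q FDR level.
#' @param nodes node universe (defaults to nodes present in `edges`).
#' @param condition optional label.
#' @return a `causal_graph`: `nodes`, `edges` (significant only), `q`,
#'   `condition`.
#' @export
build_causal_graph <- function(edges, q, nodes = NULL, condition = NA_character_) {
  if (!nrow(edges)) stop("empty edge list")
  if (is.null(nodes)) nodes <- unique(c(edges$source, edges$target))
  fdr <- fdr_threshold(edges$p_value, q)
  structure(list(nodes = nodes,
                 edges = edges[fdr$reject, , drop = FALSE],
                 critical_p = fdr$critical_p,
                 q = q, condition = condition),
            class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("<causal_graph> %d nodes, %d significant edges at FDR q = %g%s\n",
              length(x$nodes), nrow(x$edges), x$q,
              if (is.na(x$condition)) "" else paste0(" (", x$condition, ")")))
  if (nrow(x$edges)) {
    cat(paste(sprintf("  %s -> %s (F = %.2f)", x$edges$source, x$edges$target,
                      x$edges$f), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Out-, in- and out-in degrees of a causal graph
#'
#' Out-degree counts significant causal out-flows from a node, in-degree
#' counts in-flows, and out-in degree is their difference: positive values
#' mark causal sources, negative values causal targets. Out-in degrees sum
#' to zero over the graph.
#'
#' @param graph a `causal_graph` (or a list with `nodes` and `edges`).
#' @return data.frame with `node`, `out_degree`, `in_degree`, `out_in`.
#' @export
out_in_degree <- function(graph) {
  nodes <- graph$nodes
  out <- vapply(nodes, function(n) sum(graph$edges$source == n), 0L)
  inn <- vapply(nodes, function(n) sum(graph$edges$target == n), 0L)
  data.frame(node = nodes, out_degree = out, in_degree = inn,
             out_in = out - inn, row.names = NULL)
}

#' Read a directed edge table
#'
#' Reads a tab-separated table with columns `from`, `to` and optionally
#' `f_score`, as used for packaged significant-edge fixtures.
#'
#' @param path TSV path.
#' @param nodes node universe (defaults to nodes present in the table).
#' @return a `causal_graph` whose edges are all rows of the table.
#' @export
read_edge_table <- function(path, nodes = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to") %in% names(tab)))
  edges <- data.frame(source = tab$from, target = tab$to,
                      f = if ("f_score" %in% names(tab)) tab$f_score else NA_real_,
                      p_value = NA_real_, stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- unique(c(edges$source, edges$target))
  structure(list(nodes = nodes, edges = edges, critical_p = NA_real_,
                 q = NA_real_, condition = NA_character_),
            class = "causal_graph")
}
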