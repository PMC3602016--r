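## Shared builders for small deterministic fixtures; everything is generated
## in code at test time.

tiny_grid <- function(dims = c(12, 12, 12)) volume_grid(dims, c(3, 3, 3))

## blob centres sit on voxel centres of the 3 mm lattice
tiny_templates <- function(grid = tiny_grid()) {
  make_network_templates(grid, data.frame(
    network = c("netA", "netB"),
    x_mm = c(-7.5, 7.5), y_mm = c(-7.5, 7.5), z_mm = c(-7.5, 7.5),
    fwhm_mm = 9, amplitude = c(2, 3)
  ))
}

## brute-force 26-neighbourhood local-maximum scan (independent oracle)
local_maxima_26 <- function(map, dims) {
  arr <- array(map, dims)
  hits <- 0
  for (i in 2:(dims[1] - 1)) for (j in 2:(dims[2] - 1)) for (k in 2:(dims[3] - 1)) {
    nb <- arr[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)]
    if (arr[i, j, k] > 0 && arr[i, j, k] == max(nb) && sum(nb == max(nb)) == 1) {
      hits <- hits + 1
    }
  }
  hits
}

## independent connected-components oracle: union-find over the mask
flood_fill_oracle <- function(mask3d, connectivity = 26) {
  d <- dim(mask3d)
  idx <- which(mask3d)
  parent <- seq_along(idx)
  pos <- match(seq_len(prod(d)), idx)   # voxel -> mask rank
  find <- function(a) { while (parent[a] != a) a <- parent[a] <- parent[parent[a]]; a }
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[rowSums(abs(off)) > 0, ]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, ]
  if (connectivity == 18) off <- off[rowSums(abs(off)) <= 2, ]
  for (r in seq_along(idx)) {
    v <- idx[r]
    k0 <- (v - 1) %/% (d[1] * d[2]); rem <- (v - 1) %% (d[1] * d[2])
    j0 <- rem %/% d[1]; i0 <- rem %% d[1]
    for (o in seq_len(nrow(off))) {
      ni <- i0 + 1 + off$di[o]; nj <- j0 + 1 + off$dj[o]; nk <- k0 + 1 + off$dk[o]
      if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2] || nk < 1 || nk > d[3]) next
      w <- (ni - 1) + (nj - 1) * d[1] + (nk - 1) * d[1] * d[2] + 1
      if (!is.na(pos[w]) && mask3d[w]) {
        ra <- find(r); rb <- find(pos[w])
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  comp <- vapply(seq_along(idx), find, 1L)
  split(idx, comp)
}

## two-source toy with Laplacian (super-Gaussian) sources and known mixing
laplacian_toy <- function(n = 5000, seed = 1, mixing = matrix(c(1, 0.6, 0.4, 1), 2, 2)) {
  set.seed(seed)
  S <- matrix(rexp(2 * n) * sample(c(-1, 1), 2 * n, replace = TRUE), 2, n)
  list(S = S, A = mixing, X = mixing %*% S)
}

## best |correlation| assignment of recovered to true sources (2x2)
match_two <- function(rec, true) {
  cc <- abs(cor(t(rec), t(true)))
  direct <- min(cc[1, 1], cc[2, 2])
  crossed <- min(cc[1, 2], cc[2, 1])
  max(direct, crossed)
}

roi_node_names <- c("dACC", "SMA", "rACC", "dlPFC", "Precuneus",
                    "Parahippocampus", "Insula", "vmPFC")
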