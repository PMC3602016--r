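#' Define a regular axis-aligned voxel grid
#'
#' A `volume_grid` describes the sampling lattice of a volume: the number of
#' voxels per axis, the voxel size in millimetres and the world-space
#' position of the first voxel. Voxel indices are 1-based; the world
#' coordinate of voxel `(i, j, k)` is `origin_mm + (c(i, j, k) - 1) *
#' voxel_size_mm`.
#'
#' @param dims integer triple, voxels per axis (all >= 1).
#' @param voxel_size_mm positive real triple, voxel edge lengths in mm.
#' @param origin_mm real triple, world mm coordinate of voxel (1,1,1).
#'   Defaults to centring the grid on the world origin.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(dims, voxel_size_mm = c(3, 3, 3), origin_mm = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, length(voxel_size_mm) == 3)
  if (any(dims < 1)) stop("all grid dims must be >= 1")
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be > 0")
  if (is.null(origin_mm)) origin_mm <- -(dims - 1) / 2 * voxel_size_mm
  stopifnot(length(origin_mm) == 3)
  structure(
    list(dims = dims, voxel_size_mm = as.numeric(voxel_size_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "volume_grid"
  )
}

#' Number of voxels in a grid
#' @param grid a [volume_grid()].
#' @return integer voxel count.
#' @export
n_voxels <- function(grid) prod(grid$dims)

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels at %g x %g x %g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' Integer voxel coordinates of every voxel
#'
#' Rows are ordered to match R's column-major flattening of a 3D array with
#' dimensions `grid$dims` (first axis fastest), so row `v` corresponds to
#' linear voxel index `v`.
#'
#' @param grid a [volume_grid()].
#' @return V x 3 integer matrix of 1-based voxel indices.
#' @export
voxel_coords <- function(grid) {
  d <- grid$dims
  cbind(
    i = rep.int(seq_len(d[1]), d[2] * d[3]),
    j = rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
    k = rep(seq_len(d[3]), each = d[1] * d[2])
  )
}

#' Convert voxel indices to world millimetres
#' @param grid a [volume_grid()].
#' @param vox integer triple or matrix with 3 columns (1-based voxel indices).
#' @return numeric triple or matrix of world mm coordinates.
#' @export
voxel_to_mm <- function(grid, vox) {
  if (is.null(dim(vox))) {
    grid$origin_mm + (as.numeric(vox) - 1) * grid$voxel_size_mm
  } else {
    sweep(sweep(vox - 1, 2, grid$voxel_size_mm, `*`), 2, grid$origin_mm, `+`)
  }
}

#' Convert world millimetres to the nearest voxel index
#' @param grid a [volume_grid()].
#' @param mm numeric triple of world coordinates.
#' @return integer triple of 1-based voxel indices.
#' @export
mm_to_voxel <- function(grid, mm) {
  v <- round((as.numeric(mm) - grid$origin_mm) / grid$voxel_size_mm) + 1
  as.integer(v)
}

#' Linear voxel index from an (i, j, k) triple
#' @param grid a [volume_grid()].
#' @param ijk integer triple of 1-based voxel indices.
#' @return 1-based linear index into the flattened volume.
#' @export
voxel_index <- function(grid, ijk) {
  d <- grid$dims
  if (any(ijk < 1) || any(ijk > d)) stop("voxel outside grid")
  as.integer(ijk[1] + (ijk[2] - 1) * d[1] + (ijk[3] - 1) * d[1] * d[2])
}

in_grid <- function(grid, ijk) all(ijk >= 1) && all(ijk <= grid$dims)

mm_in_grid <- function(grid, mm) {
  lo <- grid$origin_mm - grid$voxel_size_mm / 2
  hi <- grid$origin_mm + (grid$dims - 0.5) * grid$voxel_size_mm
  all(mm >= lo) && all(mm <= hi)
}

## Evaluate and restore the RNG state around a seeded computation, so that
## seeded helpers do not disturb the caller's random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
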