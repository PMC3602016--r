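#' Discard initial volumes of a session
#'
#' Early volumes of an fMRI run are conventionally dropped to allow the
#' longitudinal magnetisation to reach equilibrium.
#'
#' @param session an `fmri_session`.
#' @param n number of leading time points to remove (`n < T`).
#' @return the session with the first `n` volumes removed.
#' @export
discard_initial_volumes <- function(session, n) {
  T <- nrow(session$data)
  if (n >= T) stop(sprintf("cannot discard %d of %d volumes", n, T))
  if (n == 0) return(session)
  session$data <- session$data[-seq_len(n), , drop = FALSE]
  session
}

#' Remove a linear trend from time series
#'
#' Ordinary least-squares residual of each series regressed on an intercept
#' and the time index; the output is orthogonal to both regressors, so a
#' constant series maps to zeros.
#'
#' @param x numeric vector (length >= 3) or T x V matrix (columns detrended
#'   independently).
#' @return object of the same shape.
#' @export
remove_linear_trend <- function(x) {
  vec <- is.null(dim(x))
  Y <- if (vec) matrix(x, ncol = 1) else x
  T <- nrow(Y)
  if (T < 3) stop("need at least 3 time points to remove a linear trend")
  X <- cbind(1, seq_len(T))
  R <- qr.resid(qr(X), Y)
  if (vec) as.numeric(R) else R
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (zero phase, no temporal shift). The band must lie strictly inside
#' (0, Nyquist) where Nyquist = 1 / (2 * tr_s).
#'
#' @param x numeric vector or T x V matrix of time series.
#' @param low_hz,high_hz passband edges in Hz (default 0.01-0.08, the
#'   conventional resting-state band).
#' @param tr_s sampling interval in seconds.
#' @param order filter order (default 4).
#' @return filtered object of the same shape.
#' @export
bandpass_filter <- function(x, low_hz = 0.01, high_hz = 0.08, tr_s = 2,
                            order = 4) {
  nyq <- 1 / (2 * tr_s)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop(sprintf("band (%g, %g) must satisfy 0 < low < high < Nyquist = %g Hz",
                 low_hz, high_hz, nyq))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  f1 <- function(v) as.numeric(signal::filtfilt(bf, v))
  if (is.null(dim(x))) f1(x) else apply(x, 2, f1)
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

## n x n matrix applying 1D Gaussian convolution with mirror-reflect
## boundaries (reflection about the edge samples); the kernel is normalized,
## so each row sums to 1 and total mass is preserved.
conv_matrix_reflect <- function(n, sigma_vox) {
  kern <- gaussian_kernel_1d(sigma_vox)
  r <- (length(kern) - 1) / 2
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in -r:r) {
      j <- i + o
      if (j < 1) j <- 2 - j
      if (j > n) j <- 2 * n - j
      j <- min(max(j, 1), n)
      K[i, j] <- K[i, j] + kern[o + r + 1]
    }
  }
  ## renormalize the boundary columns so total mass is conserved exactly
  K / rep(colSums(K), each = n)
}

## Smooth a stack of volumes at once: data is T x V, each row one volume.
## Separable convolution implemented as three kernel-matrix products.
smooth_volumes <- function(data, fwhm_mm, grid) {
  fwhm_mm <- rep_len(fwhm_mm, 3)
  if (any(fwhm_mm <= 0)) stop("fwhm must be > 0")
  d <- grid$dims
  Tn <- nrow(data)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size_mm
  K1 <- conv_matrix_reflect(d[1], sigma_vox[1])
  K2 <- conv_matrix_reflect(d[2], sigma_vox[2])
  K3 <- conv_matrix_reflect(d[3], sigma_vox[3])
  A <- array(t(data), c(d, Tn))
  A <- array(K1 %*% matrix(A, d[1]), c(d, Tn))                  # axis 1
  A <- aperm(A, c(2, 1, 3, 4))
  A <- array(K2 %*% matrix(A, d[2]), c(d[2], d[1], d[3], Tn))   # axis 2
  A <- aperm(A, c(3, 2, 1, 4))
  A <- array(K3 %*% matrix(A, d[3]), c(d[3], d[1], d[2], Tn))   # axis 3
  A <- aperm(A, c(2, 3, 1, 4))
  t(matrix(A, prod(d), Tn))
}

#' Spatially smooth a volume with a separable Gaussian kernel
#'
#' The kernel standard deviation per axis is `fwhm_mm / (2 sqrt(2 ln 2))`
#' converted to voxel units. Boundaries are handled by mirror reflection so
#' total mass is preserved on small grids.
#'
#' @param volume numeric 3D array, or flat vector of length `n_voxels(grid)`.
#' @param fwhm_mm full width at half maximum in mm, scalar or triple.
#' @param grid a [volume_grid()] (required when `volume` is a flat vector;
#'   otherwise voxel size defaults to 3 mm isotropic unless given).
#' @return smoothed object of the same shape as the input.
#' @export
spatial_smooth <- function(volume, fwhm_mm, grid = NULL) {
  fwhm_mm <- rep_len(fwhm_mm, 3)
  if (any(fwhm_mm <= 0)) stop("fwhm must be > 0")
  flat <- is.null(dim(volume))
  if (flat) {
    if (is.null(grid)) stop("grid required for a flat voxel vector")
    vol <- array(volume, grid$dims)
  } else {
    vol <- volume
  }
  g <- if (is.null(grid)) volume_grid(dim(vol), c(3, 3, 3)) else grid
  sm <- smooth_volumes(matrix(as.numeric(vol), nrow = 1), fwhm_mm, g)
  if (flat) as.numeric(sm) else array(sm, dim(vol))
}

#' Centre or z-score a time series
#'
#' `zero_mean` subtracts the sample mean; `zscore` additionally divides by
#' the sample standard deviation (n - 1 denominator).
#'
#' @param x numeric vector (length >= 2) or T x V matrix (by column).
#' @param mode `"zero_mean"` or `"zscore"`.
#' @return standardized object of the same shape.
#' @export
standardize <- function(x, mode = c("zero_mean", "zscore")) {
  mode <- match.arg(mode)
  vec <- is.null(dim(x))
  Y <- if (vec) matrix(x, ncol = 1) else x
  if (nrow(Y) < 2) stop("need at least 2 samples")
  Y <- sweep(Y, 2, colMeans(Y), `-`)
  if (mode == "zscore") {
    s <- sqrt(colSums(Y^2) / (nrow(Y) - 1))
    if (any(s == 0)) stop("zscore undefined for a constant series")
    Y <- sweep(Y, 2, s, `/`)
  }
  if (vec) as.numeric(Y) else Y
}

#' Apply the standard preprocessing chain to a session
#'
#' Fixed order: discard initial volumes, remove linear trends per voxel,
#' band-pass filter (optional), spatially smooth each volume (optional).
#' The applied steps are recorded in the session's `prep_steps` attribute.
#'
#' @param session an `fmri_session`.
#' @param discard_n leading volumes to drop (default 0).
#' @param detrend remove per-voxel linear trends (default TRUE).
#' @param bandpass NULL to skip, or `c(low_hz, high_hz)`.
#' @param smooth_fwhm_mm NULL to skip, or FWHM in mm (scalar or triple).
#' @return the preprocessed session, with provenance recorded.
#' @export
prep_session <- function(session, discard_n = 0, detrend = TRUE,
                         bandpass = NULL, smooth_fwhm_mm = NULL) {
  steps <- list(order = c("discard", "detrend", "bandpass", "smooth"),
                discard_n = discard_n, detrend = detrend,
                bandpass = bandpass, smooth_fwhm_mm = smooth_fwhm_mm)
  if (discard_n > 0) session <- discard_initial_volumes(session, discard_n)
  if (detrend) session$data <- remove_linear_trend(session$data)
  if (!is.null(bandpass)) {
    session$data <- bandpass_filter(session$data, bandpass[1], bandpass[2],
                                    tr_s = session$tr_s)
  }
  if (!is.null(smooth_fwhm_mm)) {
    session$data <- smooth_volumes(session$data, smooth_fwhm_mm, session$grid)
  }
  attr(session, "prep_steps") <- steps
  session
}
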