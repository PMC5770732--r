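#' Separable Gaussian smoothing of a 3D volume
#'
#' Smooths with per-axis sigma (in voxels) of
#' `fwhm_mm / (2 * sqrt(2 * log(2)) * voxel_size_mm)`, applied as three 1D
#' convolutions with reflective boundary handling, which conserves total
#' intensity on small grids.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm full width at half maximum of the kernel, mm (>= 0; 0 is a
#'   no-op).
#' @param voxel_size_mm numeric 3-vector, mm.
#' @return smoothed array, same shape.
#' @export
gaussian_smooth <- function(volume, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(volume)
  d <- dim(volume)
  stopifnot(length(d) == 3L)
  sig <- fwhm_to_sigma(fwhm_mm, voxel_size_mm)
  out <- volume
  for (axis in 1:3) {
    s <- sig[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    kern <- stats::dnorm(-r:r, sd = s)
    kern <- kern / sum(kern)
    out <- convolve_axis_reflect(out, kern, axis)
  }
  out
}

# 1D convolution along one axis of a 3D array, reflective padding.
convolve_axis_reflect <- function(arr, kern, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  a <- aperm(arr, perm)
  da <- dim(a)
  n <- da[1]
  m <- matrix(a, n, prod(da[2:3]))
  r <- (length(kern) - 1L) %/% 2L
  ref <- function(i) {             # symmetric reflection (edge repeated)
    i <- ifelse(i < 1L, 1L - i, i)
    i <- ifelse(i > n, 2L * n + 1L - i, i)
    pmin(pmax(i, 1L), n)
  }
  pad <- m[ref(c((1L - r):0L, 1:n, (n + 1L):(n + r))), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kern))
    out <- out + kern[j] * pad[j:(j + n - 1L), , drop = FALSE]
  aperm(array(out, da), order(perm))
}

#' Detrend and standardize voxel time series
#'
#' Each in-mask voxel time series is linearly detrended and scaled to zero
#' mean, unit variance. Voxels whose series has zero variance are dropped
#' from the mask with a warning.
#'
#' @param run a [bold_run()].
#' @param detrend remove a linear trend first (default `TRUE`).
#' @return the run with standardized in-mask data (out-of-mask voxels zeroed).
#' @export
standardize_timecourses <- function(run, detrend = TRUE) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  nt <- d[4]
  m <- matrix(run$data, prod(d[1:3]), nt)
  idx <- which(run$mask)
  x <- m[idx, , drop = FALSE]
  if (detrend) {
    tt <- seq_len(nt) - (nt + 1) / 2
    beta <- (x %*% tt) / sum(tt^2)
    x <- x - beta %*% tt
  }
  mu <- rowMeans(x)
  x <- x - mu
  sds <- sqrt(rowSums(x^2) / (nt - 1))
  bad <- sds == 0
  if (any(bad)) {
    warning(sprintf("%d zero-variance in-mask voxel(s) dropped from mask",
                    sum(bad)))
    run$mask[idx[bad]] <- FALSE
    idx <- idx[!bad]; x <- x[!bad, , drop = FALSE]; sds <- sds[!bad]
  }
  m[] <- 0
  m[idx, ] <- x / sds
  run$data <- array(m, d)
  run
}

# Extract the in-mask time x voxels matrix from a run.
run_matrix <- function(run) {
  d <- dim(run$data)
  m <- matrix(run$data, prod(d[1:3]), d[4])
  t(m[which(run$mask), , drop = FALSE])
}
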