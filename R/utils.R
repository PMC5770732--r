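#' @keywords internal
"_PACKAGE"

# Derive a child seed from a master seed; kept below 2^31 so it is always a
# valid R integer.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1000003 + offset) %% 2147483629L)
}

# z-score a vector; error on zero variance unless allow_zero.
zscore <- function(x, allow_zero = FALSE) {
  s <- stats::sd(x)
  if (s == 0) {
    if (allow_zero) return(x * 0)
    stop("zscore: zero variance")
  }
  (x - mean(x)) / s
}

# FWHM (mm) -> Gaussian sigma in voxel units, per axis.
fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm) {
  fwhm_mm / (2 * sqrt(2 * log(2)) * voxel_size_mm)
}

# Label face-adjacent (6-neighbour) connected components of a 3D logical
# array. Returns an integer array of the same shape: 0 outside, 1..n_clusters
# inside. Iterative flood fill with an explicit stack.
label_clusters_3d <- function(mask) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  labels <- array(0L, dims)
  idx <- which(mask)
  if (length(idx) == 0L) return(labels)
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  nxy <- nx * ny
  cur <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    labels[start] <- cur
    while (length(stack) > 0L) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      v0 <- v - 1L
      x <- v0 %% nx
      y <- (v0 %/% nx) %% ny
      z <- v0 %/% nxy
      nb <- integer(0)
      if (x > 0L)      nb <- c(nb, v - 1L)
      if (x < nx - 1L) nb <- c(nb, v + 1L)
      if (y > 0L)      nb <- c(nb, v - nx)
      if (y < ny - 1L) nb <- c(nb, v + nx)
      if (z > 0L)      nb <- c(nb, v - nxy)
      if (z < nz - 1L) nb <- c(nb, v + nxy)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      if (length(nb) > 0L) {
        labels[nb] <- cur
        stack <- c(stack, nb)
      }
    }
  }
  labels
}

# Sizes of labelled clusters (named integer vector, possibly empty).
cluster_sizes <- function(labels) {
  lab <- labels[labels > 0L]
  if (length(lab) == 0L) return(integer(0))
  tabulate(lab)
}
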