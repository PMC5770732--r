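#' Voxelwise t-statistic map
#'
#' @param values t values over in-mask voxels (vector of length `sum(mask)`)
#'   or a full 3D array.
#' @param df degrees of freedom.
#' @param mask 3D logical analysis mask.
#' @return object of class `stat_map`: `values` (3D array, 0 outside mask),
#'   `df`, `mask`, plus `clusters` / thresholds once [apply_threshold()] has
#'   run.
#' @export
stat_map <- function(values, df, mask) {
  stopifnot(length(dim(mask)) == 3L)
  if (is.array(values) && length(dim(values)) == 3L) {
    arr <- values
  } else {
    if (length(values) != sum(mask))
      stop("values length must equal mask voxel count")
    arr <- array(0, dim(mask))
    arr[which(mask)] <- values
  }
  structure(list(values = arr, df = df, mask = mask == TRUE,
                 clusters = NULL, voxel_p_threshold = NULL,
                 extent_threshold_k = NULL), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map %s | df %s | %d mask voxels%s>\n",
              paste(dim(x$values), collapse = "x"), format(x$df),
              sum(x$mask),
              if (!is.null(x$clusters))
                sprintf(" | %d clusters", nrow(x$clusters)) else ""))
  invisible(x)
}

#' Covariate-adjusted voxelwise group comparison
#'
#' Ordinary least squares at every in-mask voxel with intercept, group
#' indicator and covariates (age, sex by default); the returned t is the
#' group-contrast statistic with `df = n - rank(design)`. Positive t means
#' group A exceeds group B.
#'
#' @param maps subjects x in-mask-voxels matrix (one map per subject).
#' @param design data.frame with a `group` column (two levels; the first
#'   level is the positive direction) and any covariate columns (e.g. `age`,
#'   `sex`).
#' @param mask 3D logical mask matching the map columns.
#' @return a [stat_map()] of group-contrast t values.
#' @export
fit_group_glm <- function(maps, design, mask) {
  stopifnot(nrow(maps) == nrow(design))
  g <- design$group
  glev <- if (is.factor(g)) levels(g) else sort(unique(as.character(g)))
  if (length(glev) != 2L) stop("design$group must have exactly two levels")
  gind <- as.numeric(as.character(g) == glev[1])
  covs <- design[, setdiff(names(design), "group"), drop = FALSE]
  X <- cbind(intercept = 1, group = gind)
  if (ncol(covs) > 0)
    X <- cbind(X, vapply(covs, as.numeric, numeric(nrow(design))))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  n <- nrow(X)
  df <- n - qrX$rank
  beta <- qr.coef(qrX, maps)                      # p x voxels
  res <- maps - X %*% beta
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(sigma2 * XtXinv[2, 2], .Machine$double.eps))
  tval <- beta[2, ] / se
  stat_map(tval, df = df, mask = mask)
}

#' Monte-Carlo cluster-extent threshold
#'
#' Estimates the minimum cluster size controlling the family-wise error of
#' suprathreshold clusters. Each simulation draws an independent Gaussian
#' noise volume, smooths it with the given FWHM, re-standardizes over the
#' mask (so the voxel threshold keeps its nominal level after smoothing),
#' applies the two-sided voxel threshold, and records the largest
#' face-connected suprathreshold cluster. The returned extent `k` is the
#' smallest size whose null exceedance probability is at most
#' `corrected_alpha`.
#'
#' @param mask 3D logical analysis mask.
#' @param voxel_p two-sided per-voxel type-I error (0 < p < 1).
#' @param fwhm_mm smoothing kernel FWHM, mm (0 for none).
#' @param voxel_size_mm voxel sizes, mm.
#' @param n_sims simulations (>= 100).
#' @param corrected_alpha target family-wise error (default 0.05).
#' @param seed integer seed.
#' @return integer extent `k`; attribute `max_sizes` holds the simulated
#'   maximum-cluster-size distribution.
#' @export
mc_cluster_extent <- function(mask, voxel_p, fwhm_mm, voxel_size_mm,
                              n_sims = 1000L, corrected_alpha = 0.05,
                              seed = 1L) {
  if (sum(mask) == 0L) stop("empty mask")
  if (voxel_p <= 0 || voxel_p >= 1) stop("voxel_p must be in (0, 1)")
  if (n_sims < 100L) stop("n_sims must be >= 100")
  if (corrected_alpha >= 1) return(structure(1L, max_sizes = NULL))
  dims <- dim(mask)
  idx <- which(mask)
  zthr <- stats::qnorm(1 - voxel_p / 2)
  set.seed(seed)
  max_sizes <- integer(n_sims)
  for (s in seq_len(n_sims)) {
    vol <- array(stats::rnorm(prod(dims)), dims)
    if (fwhm_mm > 0) vol <- gaussian_smooth(vol, fwhm_mm, voxel_size_mm)
    v <- vol[idx]
    v <- (v - mean(v)) / stats::sd(v)
    supra <- array(FALSE, dims)
    supra[idx[abs(v) > zthr]] <- TRUE
    sz <- cluster_sizes(label_clusters_3d(supra))
    max_sizes[s] <- if (length(sz)) max(sz) else 0L
  }
  # smallest k with P(max cluster >= k) <= alpha
  kmax <- max(max_sizes)
  k <- 1L
  while (k <= kmax && mean(max_sizes >= k) > corrected_alpha) k <- k + 1L
  structure(as.integer(k), max_sizes = max_sizes)
}

#' Apply voxel and cluster-extent thresholds to a t-map
#'
#' Zeroes voxels whose two-sided p is at or above `voxel_p`, removes
#' face-connected components smaller than `extent_k`, and tabulates the
#' surviving clusters (size, peak voxel index, signed peak t). Positive and
#' negative suprathreshold voxels form separate clusters.
#'
#' @param statmap a [stat_map()] with finite `df`.
#' @param voxel_p two-sided voxel-level p threshold.
#' @param extent_k minimum cluster extent in voxels.
#' @return the `stat_map` with sub-threshold voxels zeroed and a `clusters`
#'   data.frame (`size`, `peak_index`, `peak_t`).
#' @export
apply_threshold <- function(statmap, voxel_p, extent_k) {
  stopifnot(inherits(statmap, "stat_map"))
  tthr <- stats::qt(1 - voxel_p / 2, df = statmap$df)
  vals <- statmap$values
  keep <- array(FALSE, dim(vals))
  keep[statmap$mask] <- abs(vals[statmap$mask]) >= tthr
  clusters <- data.frame(size = integer(0), peak_index = integer(0),
                         peak_t = numeric(0))
  surviving <- array(FALSE, dim(vals))
  for (sgn in c(1, -1)) {
    side <- keep & (sign(vals) == sgn)
    labs <- label_clusters_3d(side)
    sz <- cluster_sizes(labs)
    for (ci in which(sz >= extent_k)) {
      vox <- which(labs == ci)
      pk <- vox[which.max(abs(vals[vox]))]
      clusters <- rbind(clusters, data.frame(
        size = sz[ci], peak_index = pk, peak_t = vals[pk]))
      surviving[vox] <- TRUE
    }
  }
  out <- statmap
  out$values[!surviving] <- 0
  if (nrow(clusters))
    clusters <- clusters[order(-clusters$size), , drop = FALSE]
  out$clusters <- clusters
  out$voxel_p_threshold <- voxel_p
  out$extent_threshold_k <- as.integer(extent_k)
  out
}

#' Resting-state network mask from a one-sample t-map
#'
#' Voxels whose one-sample p (positive tail) is below `mask_p`; restricting
#' group comparisons to such a mask confines them to where the network is
#' expressed.
#'
#' @param onesample_statmap a [stat_map()] from [cluster_onesample_map()].
#' @param mask_p one-sided p threshold (1 keeps the full analysis mask).
#' @return 3D logical mask; empty masks are returned with a warning and
#'   attribute `empty = TRUE`.
#' @export
make_rsn_mask <- function(onesample_statmap, mask_p = 0.001) {
  sm <- onesample_statmap
  stopifnot(inherits(sm, "stat_map"), sm$df >= 1)
  if (mask_p >= 1) return(sm$mask)
  tthr <- stats::qt(1 - mask_p, df = sm$df)
  out <- sm$mask & (sm$values > tthr)
  if (!any(out)) {
    warning("RSN mask is empty at this threshold")
    attr(out, "empty") <- TRUE
  }
  out
}

#' Severity-connectivity Pearson correlation
#'
#' Pearson r between per-subject connectivity scores and severity scores,
#' with the two-sided p from the t transform `r * sqrt((n-2)/(1-r^2))`.
#'
#' @param subject_scores numeric vector (e.g. mean component z within a
#'   significant cluster, per subject).
#' @param severities paired severity scores.
#' @return list with `r`, `p`, `n`, `t`, `df`.
#' @export
severity_correlation <- function(subject_scores, severities) {
  ok <- is.finite(subject_scores) & is.finite(severities)
  x <- subject_scores[ok]; y <- severities[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n, t = sign(r) * Inf,
                               df = n - 2L))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df = n - 2), n = n, t = tval,
       df = n - 2L)
}

#' Per-subject cluster score
#'
#' Scalar connectivity summary of a subject's component map within a
#' surviving cluster: the mean z over the cluster's voxels (default) or the
#' value at the cluster peak.
#'
#' @param member_maps subjects x in-mask-voxels matrix.
#' @param statmap thresholded [stat_map()] (provides mask geometry).
#' @param cluster_row one row of `statmap$clusters`.
#' @param method `"mean"` or `"peak"`.
#' @return numeric vector, one score per subject.
#' @export
cluster_scores <- function(member_maps, statmap, cluster_row,
                           method = c("mean", "peak")) {
  method <- match.arg(method)
  maskidx <- which(statmap$mask)
  if (method == "peak") {
    col <- match(cluster_row$peak_index, maskidx)
    return(member_maps[, col])
  }
  labs <- label_clusters_3d(statmap$values != 0)
  vox <- which(labs == labs[cluster_row$peak_index])
  cols <- match(vox, maskidx)
  rowMeans(member_maps[, cols, drop = FALSE])
}
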