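#' Subject-level spatial ICA
#'
#' Decomposes one standardized run into `n_components` spatially independent
#' sources: the time-by-voxel matrix is modelled as mixing (t x N) times
#' sources (N x voxels). The estimator is fixed-point negentropy-maximizing
#' ICA with a logcosh contrast, PCA whitening and symmetric decorrelation,
#' restarted from `n_restarts` random rotations with the best objective kept.
#' Each spatial map is z-scored over the mask and sign-fixed so its skewness
#' is non-negative (blob-positive convention); time courses are flipped to
#' match.
#'
#' @param run a standardized [bold_run()].
#' @param n_components model order N (<= rank of the data).
#' @param seed integer seed (restart initialisations).
#' @param n_restarts random restarts (>= 1; default 3).
#' @param maxit,tol fixed-point iteration controls.
#' @return object of class `component_set`: `subject_id`, `model_order`,
#'   `spatial_maps` (N x in-mask voxels, z-scored), `time_courses` (t x N),
#'   `converged` (per restart), `objective`, `mask`.
#' @export
decompose_subject <- function(run, n_components, seed = 1L, n_restarts = 3L,
                              maxit = 200L, tol = 1e-6) {
  stopifnot(inherits(run, "bold_run"))
  X <- run_matrix(run)                      # t x voxels
  nt <- nrow(X); nv <- ncol(X)
  if (n_components > min(nt - 1L, nv))
    stop("n_components exceeds the rank of the data")
  Xc <- X - rowMeans(X)                     # centre over voxels
  sv <- svd(Xc, nu = n_components, nv = n_components)
  if (sv$d[n_components] < 1e-12 * sv$d[1])
    stop("data rank below n_components")
  Z <- t(sv$v) * sqrt(nv)                   # N x voxels, whitened
  best <- NULL
  converged <- logical(n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, r))
    W0 <- matrix(stats::rnorm(n_components^2), n_components)
    fit <- fastica_fixed_point(Z, W0, maxit, tol)
    converged[r] <- fit$converged
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  if (!any(converged))
    warning(sprintf("ICA did not converge in any of %d restarts for %s",
                    n_restarts, run$subject_id))
  S <- best$W %*% Z                          # N x voxels
  A <- sv$u %*% (diag(sv$d[seq_len(n_components)], n_components) %*%
                   t(best$W)) / sqrt(nv)     # t x N mixing
  # z-score maps, fix sign by skewness
  for (k in seq_len(n_components)) {
    s <- zscore(S[k, ])
    skw <- mean(s^3)
    if (skw < 0) { s <- -s; A[, k] <- -A[, k] }
    S[k, ] <- s
  }
  structure(list(subject_id = run$subject_id, model_order = n_components,
                 spatial_maps = S, time_courses = A, converged = converged,
                 objective = best$objective, mask = run$mask),
            class = "component_set")
}

# Symmetric fixed-point ICA on whitened data Z (N x samples), logcosh
# contrast g = tanh. Returns the unmixing rotation, convergence flag, and the
# negentropy-proxy objective used to rank restarts.
fastica_fixed_point <- function(Z, W0, maxit = 200L, tol = 1e-6) {
  nsmp <- ncol(Z)
  W <- sym_orth(W0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- tcrossprod(G, Z) / nsmp - rowMeans(1 - G^2) * W
    W1 <- sym_orth(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  # negentropy proxy: squared gap of E[logcosh] to its Gaussian expectation
  eg <- rowMeans(log(cosh(W %*% Z)))
  objective <- sum((eg - 0.3745672)^2)
  list(W = W, converged = converged, objective = objective)
}

# Symmetric decorrelation: W <- (W W')^{-1/2} W.
sym_orth <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                     nrow(W)) %*% t(e$vectors) %*% W
}
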