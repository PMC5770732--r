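#' Least-squares vector autoregression
#'
#' Fits `x_t = c + A_1 x_{t-1} + ... + A_p x_{t-p} + e_t` by equation-wise
#' ordinary least squares with intercept.
#'
#' @param timecourses series x timepoints matrix (or a vector for a single
#'   series).
#' @param order lag order p (>= 1).
#' @return list: `coefficients` (array series x series x lag), `intercept`,
#'   `residuals` (series x (T - p)), `sigma` (residual covariance, ML
#'   denominator), `order`.
#' @export
fit_var <- function(timecourses, order = 1L) {
  x <- as.matrix(timecourses)
  if (ncol(x) == 1L) x <- t(x)
  k <- nrow(x); tt <- ncol(x); p <- as.integer(order)
  if (p < 1L) stop("order must be >= 1")
  if (tt <= p * k + 1L) stop("too few timepoints for this order; lower the order")
  n <- tt - p
  Y <- t(x[, (p + 1):tt, drop = FALSE])                       # n x k
  Xl <- matrix(1, n, 1 + k * p)
  for (l in seq_len(p))
    Xl[, 1 + (l - 1) * k + seq_len(k)] <- t(x[, (p + 1 - l):(tt - l),
                                              drop = FALSE])
  qrX <- qr(Xl)
  if (qrX$rank < ncol(Xl))
    stop("singular regressor matrix; lower the order")
  B <- qr.coef(qrX, Y)                                        # (1+kp) x k
  res <- t(Y - Xl %*% B)                                      # k x n
  coef <- array(0, c(k, k, p))
  for (l in seq_len(p))
    coef[, , l] <- t(B[1 + (l - 1) * k + seq_len(k), , drop = FALSE])
  list(coefficients = coef, intercept = B[1, ], residuals = res,
       sigma = tcrossprod(res) / n, order = p)
}

# Residual variance of y regressed on lagged predictors. pred: list of
# series (vectors) whose `order` lags enter the model alongside y's own.
# With adjust = TRUE the sum of squares is divided by the residual degrees
# of freedom, which removes the O(order/T) upward bias of the raw
# log-variance-ratio GCI under the null (the full model spends more
# parameters than the reduced one); adjust = FALSE keeps the maximum-
# likelihood denominator, under which the full model never fits worse.
lag_regression_rv <- function(y, predictors, order, adjust = TRUE) {
  tt <- length(y)
  n <- tt - order
  if (n <= 1 + length(predictors) * order + 1)
    stop("series too short for this order")
  X <- cbind(rep(1, n))
  for (s in predictors)
    for (l in seq_len(order)) X <- cbind(X, s[(order + 1 - l):(tt - l)])
  yy <- y[(order + 1):tt]
  fit <- stats::lm.fit(X, yy)
  denom <- if (adjust) n - ncol(X) else n
  rv <- sum(fit$residuals^2) / denom
  if (rv <= .Machine$double.eps) stop("zero residual variance: y is perfectly predictable")
  rv
}

#' Pairwise Granger causality index
#'
#' `GCI(x -> y) = ln(sigma2_reduced / sigma2_full)`, where the reduced model
#' regresses y on its own `order` lags and the full model adds x's lags.
#' Residual variances use their residual degrees of freedom by default
#' (`small_sample = TRUE`), which centres the index at zero for independent
#' series; the maximum-likelihood denominators (`small_sample = FALSE`)
#' guarantee a non-negative raw index by the least-squares projection
#' property but are biased upward by about `order / T` under the null.
#' Finite-sample estimates can be slightly negative; they are clipped at 0
#' unless `clip = FALSE` (calibration use).
#'
#' @param x candidate cause (numeric vector).
#' @param y effect series, same length.
#' @param order lag order (default 1).
#' @param clip clip negative estimates at zero (default `TRUE`).
#' @param small_sample use df-corrected residual variances (default `TRUE`).
#' @return scalar GCI.
#' @export
gci_pairwise <- function(x, y, order = 1L, clip = TRUE, small_sample = TRUE) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(y) <= 3 * order + 3) stop("series too short for this order")
  rv_red <- lag_regression_rv(y, list(y), order, adjust = small_sample)
  rv_full <- lag_regression_rv(y, list(y, x), order, adjust = small_sample)
  g <- log(rv_red / rv_full)
  if (clip) max(0, g) else g
}

#' Relay-mediated Granger causality index
#'
#' Quantifies the influence of `x` on `y` routed through `relay`:
#' `max(0, GCI(x -> y) - GCI(x -> y | relay))`, where the conditional term
#' (Geweke-style) augments both the reduced and full models with the relay's
#' lags. Large when the influence flows through the relay; near zero when
#' the path is direct or the relay is independent.
#'
#' @param x source series.
#' @param y target series.
#' @param relay relay series (distinct from both).
#' @param order lag order (default 1).
#' @return list with `mediated`, `pairwise`, `conditional`.
#' @export
gci_mediated <- function(x, y, relay, order = 1L) {
  if (identical(x, relay) || identical(y, relay) || identical(x, y))
    stop("x, y and relay must be three distinct series")
  g_pair <- gci_pairwise(x, y, order)
  rv_red <- lag_regression_rv(y, list(y, relay), order)
  rv_full <- lag_regression_rv(y, list(y, relay, x), order)
  g_cond <- max(0, log(rv_red / rv_full))
  list(mediated = max(0, g_pair - g_cond), pairwise = g_pair,
       conditional = g_cond)
}

#' Select a VAR order by BIC
#'
#' @param timecourses series x timepoints matrix.
#' @param max_order largest order tried (default 5).
#' @return integer order minimising the Bayesian information criterion.
#' @export
select_var_order <- function(timecourses, max_order = 5L) {
  x <- as.matrix(timecourses)
  if (ncol(x) == 1L) x <- t(x)
  k <- nrow(x); tt <- ncol(x)
  bic <- rep(Inf, max_order)
  for (p in seq_len(max_order)) {
    if (tt <= p * k + 1L) break
    f <- fit_var(x, p)
    n <- tt - p
    bic[p] <- n * determinant(f$sigma, logarithm = TRUE)$modulus +
      log(n) * (k^2 * p + k)
  }
  which.min(bic)
}

#' Per-subject GCI table
#'
#' Computes the pairwise GCI for every ordered pair of the supplied component
#' time courses, and the mediated GCI for every (source, target) pair routed
#' through each series named in `relays`. Time courses are standardized
#' before fitting.
#'
#' @param timecourses named list (or t x k matrix with column names) of one
#'   subject's component time courses.
#' @param order lag order.
#' @param relays character vector of relay names (default none).
#' @param subject_id id recorded in the table.
#' @return data.frame (`subject_id`, `source`, `target`, `relay` (NA for
#'   pairwise), `order`, `gci`).
#' @export
gci_table <- function(timecourses, order = 1L, relays = character(0),
                      subject_id = NA_character_) {
  if (is.matrix(timecourses))
    timecourses <- stats::setNames(
      lapply(seq_len(ncol(timecourses)), function(j) timecourses[, j]),
      colnames(timecourses))
  nms <- names(timecourses)
  tc <- lapply(timecourses, zscore)
  rows <- list()
  for (a in nms) for (b in nms) {
    if (a == b) next
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subject_id, source = a, target = b, relay = NA_character_,
      order = order, gci = gci_pairwise(tc[[a]], tc[[b]], order))
  }
  for (r in relays) for (a in nms) for (b in nms) {
    if (a == b || a == r || b == r) next
    med <- gci_mediated(tc[[a]], tc[[b]], tc[[r]], order)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subject_id, source = a, target = b, relay = r,
      order = order, gci = med$mediated)
  }
  do.call(rbind, rows)
}

#' Within-group test that a GCI is nonzero
#'
#' One-sample t-test of per-subject GCIs against zero.
#'
#' @param group_gcis numeric vector, one GCI per subject (>= 2).
#' @return list with `mean`, `sd`, `t`, `p` (two-sided), `n`.
#' @export
test_gci_nonzero <- function(group_gcis) {
  n <- length(group_gcis)
  if (n < 2L) stop("need >= 2 subjects")
  s <- stats::sd(group_gcis)
  if (s == 0) stop("zero variance across subjects")
  m <- mean(group_gcis)
  tval <- m / (s / sqrt(n))
  list(mean = m, sd = s, t = tval,
       p = 2 * stats::pt(-abs(tval), df = n - 1), n = n)
}

#' Between-group comparison of GCIs
#'
#' Pooled-variance two-sample t-test per connection; t > 0 when group A's
#' mean exceeds group B's.
#'
#' @param gcis_A,gcis_B numeric vectors of per-subject GCIs (>= 2 each).
#' @return list with `t`, `p`, `df`, `mean_A`, `mean_B`, `sd_A`, `sd_B`.
#' @export
compare_gci_groups <- function(gcis_A, gcis_B) {
  nA <- length(gcis_A); nB <- length(gcis_B)
  if (nA < 2L || nB < 2L) stop("need >= 2 subjects per group")
  sp2 <- ((nA - 1) * stats::var(gcis_A) + (nB - 1) * stats::var(gcis_B)) /
    (nA + nB - 2)
  if (sp2 == 0) stop("zero pooled variance")
  tval <- (mean(gcis_A) - mean(gcis_B)) / sqrt(sp2 * (1 / nA + 1 / nB))
  list(t = tval, p = 2 * stats::pt(-abs(tval), df = nA + nB - 2),
       df = nA + nB - 2, mean_A = mean(gcis_A), mean_B = mean(gcis_B),
       sd_A = stats::sd(gcis_A), sd_B = stats::sd(gcis_B))
}

#' Group GCI comparison report
#'
#' Mirrors the per-connection summary table: per-group mean +/- sd with the
#' within-group nonzero p, and the between-group t and p.
#'
#' @param gci_tables data.frame rbind of per-subject [gci_table()]s.
#' @param groups named character vector mapping subject_id to group label
#'   (two levels; first sorted level is "A").
#' @return data.frame, one row per connection.
#' @export
gci_group_report <- function(gci_tables, groups) {
  key <- with(gci_tables, paste(source, target, ifelse(is.na(relay), "", relay)))
  out <- list()
  glev <- sort(unique(groups))
  for (k in unique(key)) {
    sub <- gci_tables[key == k, ]
    gA <- sub$gci[groups[sub$subject_id] == glev[1]]
    gB <- sub$gci[groups[sub$subject_id] == glev[2]]
    tA <- tryCatch(test_gci_nonzero(gA), error = function(e) NULL)
    tB <- tryCatch(test_gci_nonzero(gB), error = function(e) NULL)
    cmp <- tryCatch(compare_gci_groups(gA, gB), error = function(e) NULL)
    out[[length(out) + 1L]] <- data.frame(
      source = sub$source[1], target = sub$target[1], relay = sub$relay[1],
      mean_A = mean(gA), sd_A = stats::sd(gA),
      p_A = if (is.null(tA)) NA_real_ else tA$p,
      mean_B = mean(gB), sd_B = stats::sd(gB),
      p_B = if (is.null(tB)) NA_real_ else tB$p,
      t = if (is.null(cmp)) NA_real_ else cmp$t,
      p = if (is.null(cmp)) NA_real_ else cmp$p)
  }
  do.call(rbind, out)
}
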