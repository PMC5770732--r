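#' Assemble a feature table from connectivity measures
#'
#' Concatenates per-subject functional-connectivity features (e.g. mean
#' component z within each group-difference cluster) with effective
#' connectivity features (per-subject GCIs), and standardizes every column
#' over subjects. Constant columns are dropped with a warning.
#'
#' @param component_scores data.frame: `subject_id` plus one numeric column
#'   per FC feature (columns are prefixed `FC:` unless already prefixed).
#' @param gci_table data.frame from [gci_table()] rows for all subjects.
#' @param groups named vector mapping subject_id to group label.
#' @param standardize z-score columns over subjects (default `TRUE`; LOOCV
#'   re-standardizes inside folds regardless).
#' @return object of class `feature_table`: `subjects`, `groups`, `features`
#'   (subjects x d matrix), `feature_names`.
#' @export
build_features <- function(component_scores, gci_table, groups,
                           standardize = TRUE) {
  ids <- component_scores$subject_id
  missing_gci <- setdiff(ids, unique(gci_table$subject_id))
  if (length(missing_gci))
    stop(sprintf("subject(s) missing from GCI table: %s",
                 paste(missing_gci, collapse = ", ")))
  missing_fc <- setdiff(unique(gci_table$subject_id), ids)
  if (length(missing_fc))
    stop(sprintf("subject(s) missing from component scores: %s",
                 paste(missing_fc, collapse = ", ")))
  fc <- as.matrix(component_scores[, setdiff(names(component_scores),
                                             "subject_id"), drop = FALSE])
  fcn <- colnames(fc)
  colnames(fc) <- ifelse(grepl("^FC:", fcn), fcn, paste0("FC:", fcn))
  conn <- with(gci_table, ifelse(is.na(relay),
                                 paste0("GC:", source, "->", target),
                                 paste0("GC:", source, "->", target,
                                        "|", relay)))
  ec <- matrix(NA_real_, length(ids), length(unique(conn)),
               dimnames = list(ids, unique(conn)))
  for (r in seq_len(nrow(gci_table)))
    ec[gci_table$subject_id[r], conn[r]] <- gci_table$gci[r]
  if (anyNA(ec)) stop("GCI table has missing connections for some subjects")
  X <- cbind(fc, ec)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant feature(s): %s", sum(sds == 0),
                    paste(colnames(X)[sds == 0], collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (standardize) X <- scale(X)
  structure(list(subjects = ids, groups = groups[ids],
                 features = unclass(X)[, , drop = FALSE],
                 feature_names = colnames(X)), class = "feature_table")
}

#' Per-fold t-test feature selection
#'
#' Two-sample t-test per feature column on the training rows only; features
#' with p below `alpha` (uncorrected) are kept. If none pass, the single
#' smallest-p feature is kept so no fold is left featureless.
#'
#' @param X training feature matrix (rows: subjects).
#' @param y training group labels (two levels).
#' @param alpha selection level (default 0.05).
#' @return integer indices of selected columns.
#' @export
select_features_ttest <- function(X, y, alpha = 0.05) {
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L) stop("training set must contain both groups")
  a <- X[y == lev[1], , drop = FALSE]
  b <- X[y == lev[2], , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  tval <- (colMeans(a) - colMeans(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(tval), df = na + nb - 2)
  sel <- which(p < alpha)
  if (length(sel) == 0L) sel <- which.min(p)
  sel
}

#' Maximum-uncertainty linear discriminant analysis
#'
#' Classical LDA with maximum-uncertainty covariance regularization: the
#' pooled within-class covariance is eigendecomposed and every eigenvalue
#' below the mean eigenvalue is raised to the mean, stabilizing the inverse
#' when features outnumber samples. The weight vector is
#' `w = S*^{-1} (mu1 - mu2)` and the bias places the decision boundary at
#' the midpoint of the projected class means; predict class 1 when
#' `w . x + b > 0`.
#'
#' @param X training matrix (n x d).
#' @param y labels (two levels; the first sorted level is class 1).
#' @return object of class `mlda`: `w`, `b`, `classes`, `regularized`
#'   (number of raised eigenvalues).
#' @export
train_mlda <- function(X, y) {
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("exactly two classes required")
  X1 <- X[y == lev[1], , drop = FALSE]
  X2 <- X[y == lev[2], , drop = FALSE]
  if (nrow(X1) < 2L || nrow(X2) < 2L)
    stop("each class needs >= 2 training rows (covariance undefined)")
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  n1 <- nrow(X1); n2 <- nrow(X2)
  Sp <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) /
    (n1 + n2 - 2)
  e <- eigen(Sp, symmetric = TRUE)
  lbar <- mean(e$values)
  lam <- pmax(e$values, lbar)
  nreg <- sum(e$values < lbar * (1 - 1e-9))  # ignore floating-point ties
  w <- e$vectors %*% ((t(e$vectors) %*% (mu1 - mu2)) / lam)
  w <- drop(w)
  b <- -sum(w * (mu1 + mu2) / 2)
  structure(list(w = w, b = b, classes = lev, regularized = nreg),
            class = "mlda")
}

#' @export
predict.mlda <- function(object, newdata, ...) {
  sc <- as.matrix(newdata) %*% object$w + object$b
  ifelse(drop(sc) > 0, object$classes[1], object$classes[2])
}

#' Gaussian-kernel support vector machine
#'
#' Soft-margin SVM with kernel `exp(-||u - v||^2 / (2 * width^2))`. The
#' `width` is the Gaussian sigma; it maps to the radial-kernel gamma as
#' `gamma = 1 / (2 * width^2)`.
#'
#' @param X training matrix.
#' @param y labels (two levels).
#' @param width Gaussian kernel width sigma (default 0.5).
#' @param cost soft-margin constant C (default 1).
#' @return object of class `ksvm_model` wrapping the fitted SVM.
#' @export
train_ksvm <- function(X, y, width = 0.5, cost = 1) {
  yf <- factor(as.character(y))
  if (nlevels(yf) != 2L) stop("exactly two classes required")
  fit <- e1071::svm(x = as.matrix(X), y = yf, kernel = "radial",
                    gamma = 1 / (2 * width^2), cost = cost, scale = FALSE)
  structure(list(fit = fit, classes = levels(yf), width = width),
            class = "ksvm_model")
}

#' @export
predict.ksvm_model <- function(object, newdata, ...) {
  as.character(predict(object$fit, as.matrix(newdata)))
}

#' Leave-one-out cross-validation with nested feature selection
#'
#' One fold per subject. Inside every fold, feature standardization
#' parameters and the t-test feature selection are computed on the n - 1
#' training rows only, then applied to the held-out row, so no information
#' leaks from the test subject. Metrics take the patient-analog group (the
#' `positive` label) as the positive class.
#'
#' @param table a [build_features()] table (or any list with `features`,
#'   `groups`, `subjects`).
#' @param classifier `"mlda"` or `"ksvm"`.
#' @param alpha feature-selection level per fold (default 0.05).
#' @param positive label of the positive class (default the first sorted
#'   group level).
#' @param width,cost kernel SVM parameters (used when `classifier = "ksvm"`).
#' @return object of class `classification_result`: `predicted`, `truth`,
#'   `accuracy`, `sensitivity`, `specificity`, `mean_weights`,
#'   `selected_counts`, `folds`.
#' @export
loocv <- function(table, classifier = c("mlda", "ksvm"), alpha = 0.05,
                  positive = NULL, width = 0.5, cost = 1) {
  classifier <- match.arg(classifier)
  X <- table$features
  y <- as.character(table$groups)
  n <- nrow(X)
  if (n < 4L || min(table(y)) < 2L)
    stop("LOOCV needs >= 4 subjects and both classes >= 2")
  lev <- sort(unique(y))
  if (is.null(positive)) positive <- lev[1]
  d <- ncol(X)
  pred <- character(n)
  sel_count <- integer(d)
  wsum <- numeric(d)
  wn <- integer(d)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    mu <- colMeans(X[tr, , drop = FALSE])
    sds <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    usable <- which(sds > 0)
    Xtr <- sweep(sweep(X[tr, usable, drop = FALSE], 2, mu[usable]), 2,
                 sds[usable], "/")
    Xte <- (X[i, usable] - mu[usable]) / sds[usable]
    sel <- select_features_ttest(Xtr, y[tr], alpha)
    cols <- usable[sel]
    fit <- tryCatch(
      if (classifier == "mlda")
        train_mlda(Xtr[, sel, drop = FALSE], y[tr])
      else
        train_ksvm(Xtr[, sel, drop = FALSE], y[tr], width, cost),
      error = function(e)
        stop(sprintf("classifier failed in fold %d (%s): %s", i,
                     table$subjects[i], conditionMessage(e))))
    pred[i] <- predict(fit, matrix(Xte[sel], 1))
    sel_count[cols] <- sel_count[cols] + 1L
    fold_w <- NULL
    if (classifier == "mlda") {
      # orient weights so positive values favour the positive class
      wv <- if (fit$classes[1] == positive) fit$w else -fit$w
      wsum[cols] <- wsum[cols] + wv
      wn[cols] <- wn[cols] + 1L
      fold_w <- stats::setNames(wv, table$feature_names[cols])
    }
    folds[[i]] <- list(held_out = table$subjects[i], selected = cols,
                       predicted = pred[i], weights = fold_w)
  }
  tp <- sum(pred == positive & y == positive)
  tn <- sum(pred != positive & y != positive)
  npos <- sum(y == positive); nneg <- n - npos
  mean_w <- ifelse(wn > 0, wsum / pmax(wn, 1L), 0)
  names(mean_w) <- table$feature_names
  names(sel_count) <- table$feature_names
  structure(list(predicted = stats::setNames(pred, table$subjects),
                 truth = stats::setNames(y, table$subjects),
                 positive = positive,
                 accuracy = (tp + tn) / n, sensitivity = tp / npos,
                 specificity = tn / nneg, mean_weights = mean_w,
                 selected_counts = sel_count, folds = folds,
                 classifier = classifier), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<%s LOOCV | accuracy %.1f%% | sensitivity %.1f%% | specificity %.1f%%>\n",
              toupper(x$classifier), 100 * x$accuracy, 100 * x$sensitivity,
              100 * x$specificity))
  invisible(x)
}

#' Pooled accuracy from sensitivity and specificity
#'
#' `accuracy = (sensitivity * n_pos + specificity * n_neg) / (n_pos + n_neg)`
#' — the arithmetic identity every `classification_result` satisfies.
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @param n_pos,n_neg class sizes.
#' @return pooled accuracy.
#' @export
pooled_accuracy <- function(sensitivity, specificity, n_pos, n_neg) {
  (sensitivity * n_pos + specificity * n_neg) / (n_pos + n_neg)
}

#' Average MLDA feature weights over LOOCV folds
#'
#' Per feature, the mean of its discriminant coefficient over the folds in
#' which it was selected (folds where it was not selected do not enter that
#' feature's mean); never-selected features report weight 0 and frequency 0.
#'
#' @param per_fold_weights list, one named numeric vector per fold (weights
#'   of the selected features).
#' @param n_features total feature count.
#' @param feature_names feature names (length `n_features`).
#' @return data.frame `feature`, `mean_weight`, `selection_frequency`.
#' @export
average_feature_weights <- function(per_fold_weights, n_features,
                                    feature_names = NULL) {
  if (length(per_fold_weights) < 1L) stop("need >= 1 successful fold")
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(n_features))
  wsum <- numeric(n_features); cnt <- integer(n_features)
  names(wsum) <- names(cnt) <- feature_names
  for (w in per_fold_weights) {
    wsum[names(w)] <- wsum[names(w)] + w
    cnt[names(w)] <- cnt[names(w)] + 1L
  }
  data.frame(feature = feature_names,
             mean_weight = ifelse(cnt > 0, wsum / pmax(cnt, 1L), 0),
             selection_frequency = cnt / length(per_fold_weights),
             row.names = NULL)
}
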