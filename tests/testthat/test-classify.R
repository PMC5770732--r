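make_gci_rows <- function(ids, edges, values) {
  do.call(rbind, lapply(seq_along(ids), function(i)
    data.frame(subject_id = ids[i], source = edges$source,
               target = edges$target, relay = NA_character_, order = 1,
               gci = values[i, ])))
}

test_that("feature tables concatenate FC and GC with provenance names", {
  ids <- sprintf("s%d", 1:6)
  fc <- data.frame(subject_id = ids, amygdala = rnorm(6), insula = rnorm(6))
  edges <- data.frame(source = c("MFG", "MFG", "MTG"),
                      target = c("AMY", "PUT", "AMY"))
  set.seed(1)
  gci <- make_gci_rows(ids, edges, matrix(abs(rnorm(18)), 6))
  ft <- build_features(fc, gci, setNames(rep(c("A", "B"), 3), ids))
  expect_equal(ncol(ft$features), 5L)
  expect_setequal(ft$feature_names,
                  c("FC:amygdala", "FC:insula", "GC:MFG->AMY",
                    "GC:MFG->PUT", "GC:MTG->AMY"))
  expect_lt(max(abs(colMeans(ft$features))), 1e-10)
  # constant feature dropped with a warning
  fc2 <- fc; fc2$insula <- 1
  expect_warning(ft2 <- build_features(fc2, gci,
                                       setNames(rep(c("A", "B"), 3), ids)),
                 "constant")
  expect_equal(ncol(ft2$features), 4L)
  # missing subject is named
  expect_error(build_features(fc[-2, ], gci,
                              setNames(rep(c("A", "B"), 3), ids)), "s2")
})

test_that("t-test selection keeps real effects and guards empty folds", {
  set.seed(2)
  X <- matrix(rnorm(20 * 10), 20)
  y <- rep(c("A", "B"), each = 10)
  X[y == "A", 3] <- X[y == "A", 3] + 3
  sel <- select_features_ttest(X, y, 0.05)
  expect_true(3 %in% sel)
  # null columns select at the binomial rate
  set.seed(3)
  Xn <- matrix(rnorm(38 * 1000), 38)
  yn <- rep(c("A", "B"), each = 19)
  expect_equal(length(select_features_ttest(Xn, yn, 0.05)), 50,
               tolerance = 15 / 50)
  # degenerate fold: nothing significant -> exactly one kept
  set.seed(4)
  X1 <- matrix(rnorm(8 * 3), 8) * 1e-6 +
    matrix(rep(c(0, 0, 0), each = 8), 8)
  y1 <- rep(c("A", "B"), 4)
  expect_length(select_features_ttest(matrix(rnorm(8 * 2, sd = 1e-9), 8),
                                      y1, 1e-12), 1L)
  expect_error(select_features_ttest(X1, rep("A", 8), 0.05), "both groups")
})

test_that("MLDA equals classical LDA on an equal-spectrum covariance", {
  set.seed(5)
  n <- 40; d <- 4
  mu <- c(2, 0, 0, 0)
  X <- rbind(matrix(rnorm(n / 2 * d), ncol = d),
             sweep(matrix(rnorm(n / 2 * d), ncol = d), 2, -mu))
  y <- rep(c("A", "B"), each = n / 2)
  # force an exactly equal spectrum: whiten the pooled covariance to c*I
  X1 <- X[y == "A", ]; X2 <- X[y == "B", ]
  Sp <- (cov(X1) * (n / 2 - 1) + cov(X2) * (n / 2 - 1)) / (n - 2)
  W <- solve(chol(Sp))
  Xw <- X %*% W * 0.7          # pooled covariance is now 0.49 * I
  fit <- train_mlda(Xw, y)
  expect_equal(fit$regularized, 0L)  # no eigenvalue below the mean
  m1 <- colMeans(Xw[y == "A", ]); m2 <- colMeans(Xw[y == "B", ])
  w_lda <- solve(0.49 * diag(d), m1 - m2)
  expect_equal(fit$w, w_lda, tolerance = 1e-8)
  # and w is proportional to the mean difference under isotropic covariance
  cosang <- sum(fit$w * (m1 - m2)) /
    sqrt(sum(fit$w^2) * sum((m1 - m2)^2))
  expect_equal(cosang, 1.0, tolerance = 1e-10)
})

test_that("MLDA stays finite and deterministic when features outnumber
           samples, and agrees in direction with a pseudo-inverse oracle", {
  set.seed(6)
  n <- 20; d <- 50
  X <- matrix(rnorm(n * d), n)
  y <- rep(c("A", "B"), each = n / 2)
  X[y == "A", 1] <- X[y == "A", 1] + 2
  f1 <- train_mlda(X, y)
  f2 <- train_mlda(X, y)
  expect_true(all(is.finite(f1$w)))
  expect_identical(f1$w, f2$w)
  expect_gt(f1$regularized, 0L)
  acc <- mean(predict(f1, X) == y)
  expect_gt(acc, 0.5)
  # pseudo-inverse LDA oracle: both separate the training classes
  mu_d <- colMeans(X[y == "A", ]) - colMeans(X[y == "B", ])
  Sp <- (cov(X[y == "A", ]) + cov(X[y == "B", ])) / 2
  w_pinv <- drop(MASS::ginv(Sp) %*% mu_d)
  expect_gt(cor(f1$w, w_pinv), 0)
  proj_pinv <- X %*% w_pinv
  expect_gt(abs(mean(proj_pinv[y == "A"]) - mean(proj_pinv[y == "B"])), 0)
  expect_error(train_mlda(X[c(1, 11, 12), ], y[c(1, 11, 12)]), ">= 2")
})

test_that("kernel SVM separates XOR and approaches linear at huge width", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c("A", "A", "B", "B")
  fit <- train_ksvm(X, y, width = 0.5, cost = 100)
  expect_equal(predict(fit, X), y)
  set.seed(7)
  Xl <- matrix(rnorm(60 * 2), ncol = 2)
  yl <- ifelse(Xl[, 1] + Xl[, 2] > 0, "A", "B")
  # sigma -> infinity flattens the kernel; compensate with a larger cost so
  # the decision function keeps its scale
  fw <- train_ksvm(Xl, yl, width = 100, cost = 2e4)
  lin <- e1071::svm(Xl, factor(yl), kernel = "linear", cost = 1,
                    scale = FALSE)
  grid <- as.matrix(expand.grid(seq(-2, 2, 0.25), seq(-2, 2, 0.25)))
  agree <- mean(predict(fw, grid) == as.character(predict(lin, grid)))
  expect_gte(agree, 0.95)
  # separable clusters are fit perfectly
  Xs <- rbind(matrix(rnorm(20, 3), ncol = 2), matrix(rnorm(20, -3), ncol = 2))
  ys <- rep(c("A", "B"), each = 10)
  expect_equal(mean(predict(train_ksvm(Xs, ys, 0.5, 10), Xs) == ys), 1.0)
})

test_that("LOOCV is deterministic and its metrics satisfy the identity", {
  set.seed(8)
  ft <- null_feature_table(n = 16, d = 10, seed = 42)
  ft$features[ft$groups == "A", 1] <- ft$features[ft$groups == "A", 1] + 3
  r1 <- loocv(ft, "mlda", positive = "A")
  r2 <- loocv(ft, "mlda", positive = "A")
  expect_identical(r1$predicted, r2$predicted)
  npos <- sum(ft$groups == "A"); nneg <- sum(ft$groups == "B")
  expect_equal(r1$accuracy * 16,
               r1$sensitivity * npos + r1$specificity * nneg)
  expect_gt(r1$accuracy, 0.8)
  rs <- loocv(ft, "ksvm", positive = "A", width = 0.5)
  expect_equal(rs$accuracy * 16,
               rs$sensitivity * npos + rs$specificity * nneg)
})

test_that("LOOCV accuracy grows with the planted effect size", {
  accs <- vapply(c(0, 1, 2.5), function(gap) {
    mean(vapply(1:10, function(rep) {
      ft <- null_feature_table(n = 20, d = 15, seed = 900 + rep)
      ft$features[ft$groups == "A", 1:3] <-
        ft$features[ft$groups == "A", 1:3] + gap
      loocv(ft, "mlda", positive = "A")$accuracy
    }, 0))
  }, 0)
  expect_lte(accs[1], accs[2] + 0.1)
  expect_lte(accs[2], accs[3] + 0.1)
  expect_gt(accs[3], 0.9)
})

test_that("fold-averaged weights follow the stated conventions", {
  w <- average_feature_weights(list(c(f1 = 0.3, f2 = 1), c(f1 = 0.3)),
                               n_features = 3,
                               feature_names = c("f1", "f2", "f3"))
  expect_equal(w$mean_weight[w$feature == "f1"], 0.3)
  expect_equal(w$mean_weight[w$feature == "f2"], 1)   # only selected folds
  expect_equal(w$mean_weight[w$feature == "f3"], 0)   # never selected
  expect_equal(w$selection_frequency, c(1, 0.5, 0))
  expect_error(average_feature_weights(list(), 3), "fold")
})

test_that("pooled accuracy identity reproduces the 20-per-class arithmetic", {
  expect_equal(pooled_accuracy(0.90, 0.85, 20, 20), 0.875)
  expect_equal(pooled_accuracy(0.90, 0.85, 20, 20) * 40, 18 + 17)
})
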