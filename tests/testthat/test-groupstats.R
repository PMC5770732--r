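test_that("the group GLM reduces to the two-sample t-test", {
  set.seed(1)
  n <- 20; nv <- 30
  maps <- matrix(rnorm(n * nv), n)
  maps[1:10, 5] <- maps[1:10, 5] + 2
  g <- rep(c("A", "B"), each = 10)
  mask <- array(TRUE, c(5, 6, 1))
  sm <- fit_group_glm(maps, data.frame(group = g), mask)
  tt <- t.test(maps[1:10, 5], maps[11:20, 5], var.equal = TRUE)
  expect_equal(sm$values[which(mask)[5]], unname(tt$statistic),
               tolerance = 1e-8)
  expect_equal(sm$df, 18L)
})

test_that("covariate adjustment leaves the group contrast calibrated", {
  set.seed(2)
  n <- 24; nv <- 1000
  age <- rnorm(n, 32, 8); sex <- rbinom(n, 1, 0.5)
  g <- rep(c("A", "B"), each = n / 2)
  noise <- matrix(rnorm(n * nv), n)
  maps_plain <- noise
  maps_age <- noise + outer(age - mean(age), rep(0.5, nv))  # age effect only
  mask <- array(TRUE, c(10, 10, 10))
  des <- data.frame(group = g, age = age, sex = sex)
  t_plain <- fit_group_glm(maps_plain, des, mask)$values[mask]
  t_age <- fit_group_glm(maps_age, des, mask)$values[mask]
  expect_equal(t_age, t_plain, tolerance = 1e-8)  # adjustment removes it all
  # null calibration: ~5% of voxels significant at p<0.05
  p <- 2 * pt(-abs(t_plain), df = n - 4)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("rank-deficient designs are rejected naming the column", {
  maps <- matrix(rnorm(12 * 4), 12)
  g <- rep(c("A", "B"), each = 6)
  des <- data.frame(group = g, age = rep(1, 12))  # collinear with intercept
  expect_error(fit_group_glm(maps, des, array(TRUE, c(2, 2, 1))),
               "collinear")
})

test_that("Monte-Carlo extent matches a brute-force oracle on a tiny grid", {
  mask <- array(TRUE, c(5, 5, 5))
  k <- mc_cluster_extent(mask, voxel_p = 0.5, fwhm_mm = 0,
                         voxel_size_mm = c(1, 1, 1), n_sims = 100,
                         corrected_alpha = 0.05, seed = 31)
  k_oracle <- oracle_mc_extent(mask, 0.5, 100, 0.05, seed = 31)
  expect_equal(as.integer(k), k_oracle)
})

test_that("no correction means extent one; extent grows with smoothness", {
  mask <- array(TRUE, c(8, 8, 4))
  expect_equal(as.integer(mc_cluster_extent(mask, 0.05, 0, c(3, 3, 3),
                                            n_sims = 100,
                                            corrected_alpha = 1,
                                            seed = 1)), 1L)
  k4 <- mc_cluster_extent(mask, 0.05, 4, c(3, 3, 3), n_sims = 500,
                          corrected_alpha = 0.05, seed = 7)
  k8 <- mc_cluster_extent(mask, 0.05, 8, c(3, 3, 3), n_sims = 500,
                          corrected_alpha = 0.05, seed = 7)
  expect_lte(as.integer(k4), as.integer(k8))
})

test_that("extent thresholding keeps only large-enough blobs", {
  mask <- array(TRUE, c(10, 10, 5))
  vals <- array(0, c(10, 10, 5))
  vals[1:5, 1:4, 1:2] <- 6          # 40-voxel blob
  vals[8:9, 8:9, 4:5] <- -6         # 8-voxel blob (negative side)
  sm <- stat_map(vals[mask], df = 20, mask = mask)
  thr30 <- apply_threshold(sm, 0.01, 30)
  expect_equal(nrow(thr30$clusters), 1L)
  expect_equal(thr30$clusters$size, 40L)
  expect_equal(thr30$clusters$peak_t, 6)
  thr41 <- apply_threshold(sm, 0.01, 41)
  expect_equal(nrow(thr41$clusters), 0L)
  expect_true(all(thr41$values == 0))
  # all-zero map has no clusters
  sm0 <- stat_map(array(0, c(10, 10, 5))[mask], df = 20, mask = mask)
  expect_equal(nrow(apply_threshold(sm0, 0.01, 1)$clusters), 0L)
})

test_that("raising the extent threshold never adds clusters", {
  set.seed(4)
  mask <- array(TRUE, c(8, 8, 6))
  vals <- gaussian_smooth(array(rnorm(8 * 8 * 6), c(8, 8, 6)), 6, c(3, 3, 3))
  vals <- (vals - mean(vals)) / sd(vals) * 3
  sm <- stat_map(vals[mask], df = 30, mask = mask)
  prev <- Inf
  for (k in c(1, 3, 5, 10)) {
    nc <- nrow(apply_threshold(sm, 0.1, k)$clusters)
    expect_lte(nc, prev)
    prev <- nc
  }
})

test_that("RSN masks take the positive tail and flag empty results", {
  mask <- array(TRUE, c(6, 6, 3))
  vals <- array(0, c(6, 6, 3)); vals[2:4, 2:4, 1:2] <- 8
  sm <- stat_map(vals[mask], df = 10, mask = mask)
  expect_identical(make_rsn_mask(sm, mask_p = 1), mask)
  rsn <- make_rsn_mask(sm, 0.001)
  expect_equal(sum(rsn), 18L)
  smneg <- stat_map(-vals[mask], df = 10, mask = mask)
  expect_warning(empty <- make_rsn_mask(smneg, 0.001), "empty")
  expect_true(attr(empty, "empty"))
  expect_equal(sum(empty), 0L)
})

test_that("RSN mask overlaps the planted blob", {
  co <- small_cohort()
  runs <- standardized_runs()
  sets <- lapply(1:10, function(i) decompose_subject(runs[[i]], 6,
                                                     seed = 80 + i))
  cl <- match_components(sets, 0.5)[[1]]
  sm <- cluster_onesample_map(cl, runs[[1]]$mask)
  rsn <- make_rsn_mask(sm, 0.001)
  truth <- co$truth$source_maps
  ktruth <- which.max(abs(cor(cl$representative_map, t(truth))))
  blob <- truth[ktruth, ] > 0.05 * max(truth[ktruth, ])  # smoothed support
  dice <- 2 * sum(rsn[blob]) / (sum(rsn) + sum(blob))
  expect_gte(dice, 0.7)
})

test_that("severity correlation matches its closed form", {
  x <- 1:10
  expect_equal(severity_correlation(x, 2 * x + 1)$r, 1.0)
  # r = 0.8, n = 20 -> t = 5.657, p < 0.001
  t80 <- 0.8 * sqrt(18 / (1 - 0.64))
  expect_equal(t80, 5.6569, tolerance = 1e-4)
  set.seed(6)
  repeat {  # build a sample with r very close to 0.8, then check p math
    a <- rnorm(20); b <- 0.8 * scale(a) + sqrt(1 - 0.64) * scale(rnorm(20))
    if (abs(cor(a, b) - 0.8) < 0.1) break
  }
  res <- severity_correlation(a, as.vector(b))
  expect_equal(res$p, 2 * pt(-abs(res$t), 18), tolerance = 1e-12)
  expect_error(severity_correlation(rep(1, 5), 1:5), "variance")
  expect_error(severity_correlation(1:2, 2:3), ">= 3")
})

test_that("null severity correlations have uniform p-values", {
  set.seed(7)
  ps <- replicate(1000, severity_correlation(rnorm(20), rnorm(20))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  rs <- replicate(200, severity_correlation(rnorm(20), rnorm(20))$r)
  expect_lt(abs(mean(rs)), 0.05)
})
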