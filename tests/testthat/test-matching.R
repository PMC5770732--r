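# Construct a component_set directly from a matrix of maps.
as_component_set <- function(maps, subject_id, mask, order = nrow(maps)) {
  maps <- t(apply(maps, 1, function(x) (x - mean(x)) / sd(x)))
  structure(list(subject_id = subject_id, model_order = order,
                 spatial_maps = maps,
                 time_courses = matrix(0, 10, nrow(maps)),
                 converged = TRUE, objective = 0, mask = mask),
            class = "component_set")
}

sep_maps <- function(k, nv, seed) {
  set.seed(seed)
  m <- matrix(0, k, nv)
  for (i in seq_len(k)) {
    block <- ((i - 1) * floor(nv / k) + 1):(i * floor(nv / k))
    m[i, block] <- 1 + rnorm(length(block), sd = 0.1)
  }
  m + matrix(rnorm(k * nv, sd = 0.02), k)
}

test_that("identical component sets cluster as the identity pairing", {
  mask <- array(TRUE, c(4, 4, 4))
  m <- sep_maps(3, 64, seed = 1)
  s1 <- as_component_set(m, "a", mask)
  s2 <- as_component_set(m, "b", mask)
  cl <- match_components(list(s1, s2))
  expect_length(cl, 3L)
  for (x in cl) {
    expect_equal(nrow(x$members), 2L)
    expect_equal(x$members$component_index[1], x$members$component_index[2])
    expect_equal(x$mean_similarity, 1.0, tolerance = 1e-10)
  }
})

test_that("matching is invariant to permutation and sign flips", {
  mask <- array(TRUE, c(4, 4, 4))
  m <- sep_maps(4, 64, seed = 2)
  perm <- c(3, 1, 4, 2); flip <- c(-1, 1, -1, 1)
  s1 <- as_component_set(m, "a", mask)
  s2 <- as_component_set(m[perm, ] * flip, "b", mask)
  cl <- match_components(list(s1, s2))
  expect_length(cl, 4L)
  for (x in cl) {
    i1 <- x$members$component_index[x$members$subject_id == "a"]
    i2 <- x$members$component_index[x$members$subject_id == "b"]
    expect_equal(perm[i2], i1)       # partner is the permuted original
    aligned <- x$member_maps
    expect_gt(cor(aligned[1, ], aligned[2, ]), 0.99)  # signs corrected
  }
})

test_that("greedy matching equals the exhaustive best assignment", {
  mask <- array(TRUE, c(4, 4, 4))
  for (seed in 1:4) {
    k <- sample(2:4, 1)
    m <- sep_maps(k, 64, seed = seed)
    sets <- lapply(1:3, function(s) {
      set.seed(seed * 10 + s)
      perm <- sample(k)
      as_component_set(m[perm, ] + matrix(rnorm(k * 64, sd = 0.05), k),
                       letters[s], mask)
    })
    cl <- match_components(sets, match_threshold = 0.3)
    got <- lapply(cl, `[[`, "member_rows")
    got <- got[order(vapply(got, min, 0L))]
    want <- brute_force_match(lapply(sets, `[[`, "spatial_maps"))
    expect_equal(got, want)
  }
})

test_that("planted networks cluster fully across subjects; noise does not", {
  runs <- standardized_runs()[1:8]
  sets <- lapply(seq_along(runs), function(i)
    decompose_subject(runs[[i]], 8, seed = 50 + i))
  cl <- match_components(sets, match_threshold = 0.5)
  full <- Filter(function(x) nrow(x$members) == 8L, cl)
  expect_gte(length(full), 6L)
  truth <- small_cohort()$truth$source_maps
  best <- vapply(full[1:6], function(x)
    max(abs(cor(x$representative_map, t(truth)))), 0)
  expect_true(all(best > 0.8))
})

test_that("cronbach alpha: identical items give 1; Spearman-Brown holds", {
  set.seed(3)
  x <- rnorm(200)
  expect_equal(cronbach_alpha(rbind(x, x, x)), 1.0, tolerance = 1e-12)
  # two standardized items: alpha must equal 2r/(1+r) for the sample r
  y <- rnorm(200)
  xs <- (x - mean(x)) / sd(x); ys <- (y - mean(y)) / sd(y)
  ys2 <- 0.5 * xs + sqrt(0.75) * ys
  ys2 <- (ys2 - mean(ys2)) / sd(ys2)
  r <- cor(xs, ys2)
  expect_equal(cronbach_alpha(rbind(xs, ys2)), 2 * r / (1 + r),
               tolerance = 1e-10)
})

test_that("cronbach alpha of independent items is near zero; errors fire", {
  set.seed(4)
  a <- cronbach_alpha(matrix(rnorm(2 * 10000), 2))
  expect_lt(abs(a), 0.05)
  expect_error(cronbach_alpha(matrix(1, 1, 10)), "items")
  expect_error(cronbach_alpha(rbind(c(1, 1), c(-1, -1))), "variance")
})

test_that("one-sample cluster maps match hand-computed t values", {
  mask <- array(TRUE, c(3, 1, 1))
  M <- rbind(c(1, 1, 1), c(2, 2, -1), c(3, 3, 0))  # per-voxel members
  sm <- cluster_onesample_map(M, mask)
  expect_equal(sm$df, 2L)
  expect_equal(sm$values[1, 1, 1], 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(sm$values[3, 1, 1], 0)               # symmetric about 0
  Mc <- rbind(c(2, 0), c(2, 0))                     # zero variance, mean 2
  sm2 <- cluster_onesample_map(Mc, array(TRUE, c(2, 1, 1)))
  expect_identical(sm2$values[1, 1, 1], Inf)
  expect_error(cluster_onesample_map(M[1, , drop = FALSE], mask), ">= 2")
})

test_that("hierarchical matching spans orders and enforces min_orders", {
  mask <- array(TRUE, c(4, 4, 4))
  m <- sep_maps(3, 64, seed = 6)
  mk_level <- function(order) {
    sets <- lapply(c("a", "b"), function(s)
      as_component_set(m + matrix(rnorm(3 * 64, sd = 0.03), 3), s, mask,
                       order = order))
    match_components(sets)
  }
  fl <- list(`6` = mk_level(6), `8` = mk_level(8), `10` = mk_level(10))
  groups <- hierarchical_match(fl)
  expect_length(groups, 3L)
  for (g in groups) expect_equal(attr(g, "orders"), c(6, 8, 10))
  # drop one network at one order: its group spans 1 order < min_orders = 2
  fl2 <- list(`6` = mk_level(6)[1:2], `8` = mk_level(8))
  fl2$`6` <- fl2$`6`[vapply(fl2$`6`, function(x)
    max(abs(cor(x$representative_map, m[3, ]))) < 0.9, TRUE)]
  groups2 <- hierarchical_match(fl2, min_orders = 2)
  spans <- lapply(groups2, attr, "orders")
  expect_true(all(vapply(spans, length, 0L) >= 2))
  expect_error(hierarchical_match(fl["6"]), "single|>= 2")
})

test_that("selection picks the alpha-maximal cluster with declared ties", {
  fake_cluster <- function(alpha, n, order) {
    structure(list(members = data.frame(
      subject_id = letters[seq_len(n)], model_order = order,
      component_index = 1, sign = 1),
      representative_map = rnorm(10), member_maps = NULL, alpha = alpha,
      mean_similarity = 0.9, level = "first"), class = "component_cluster")
  }
  g1 <- list(fake_cluster(0.9, 4, 8), fake_cluster(0.7, 4, 6))
  sel <- select_reproducible(list(g1))
  expect_equal(sel[[1]]$alpha, 0.9)
  g2 <- list(fake_cluster(0.8, 6, 10), fake_cluster(0.8, 8, 10))
  expect_equal(nrow(select_reproducible(list(g2))[[1]]$members), 8L)
  g3 <- list(fake_cluster(0.8, 6, 10), fake_cluster(0.8, 6, 6))
  expect_equal(select_reproducible(list(g3))[[1]]$members$model_order[1], 6)
  # output ordered by alpha descending
  sel2 <- select_reproducible(list(g1, g2))
  expect_equal(vapply(sel2, `[[`, 0, "alpha"), c(0.9, 0.8))
})
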