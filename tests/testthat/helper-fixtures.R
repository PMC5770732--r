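# Shared fixtures and independent oracles for the suite.

# Small standard cohort, built once per test run.
small_cohort <- local({
  cache <- NULL
  function(seed = 5L) {
    if (is.null(cache) || cache$truth$seed != seed)
      cache <<- generate_cohort(cohort_config(seed = seed))
    cache
  }
})

standardized_runs <- local({
  cache <- NULL
  function(seed = 5L) {
    if (is.null(cache))
      cache <<- lapply(small_cohort(seed)$runs, standardize_timecourses)
    cache
  }
})

# Build a bold_run directly from planted sources: data = sum_k a_k tc_k map_k.
mixture_run <- function(maps, timecourses, grid, noise_sd = 0,
                        amplitudes = rep(1, nrow(maps)), seed = 1L,
                        subject_id = "sub-01", group = "A") {
  set.seed(seed)
  nv <- prod(grid)
  sig <- crossprod(maps * amplitudes, timecourses)
  if (noise_sd > 0)
    sig <- sig + matrix(rnorm(length(sig), sd = noise_sd), nrow(sig))
  bold_run(subject_id, group, array(sig, c(grid, ncol(timecourses))),
           voxel_size_mm = c(3, 3, 3), mask = array(TRUE, grid))
}

# Exhaustive partner-matching oracle: one component per subject per cluster;
# enumerate all per-subject permutations (subject 1 fixed) and maximize the
# total within-cluster pairwise |r|. Returns the best partition as a list of
# row-index vectors into rbind(subject maps).
perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, ifelse(p >= i, p + 1L, p))))
}

brute_force_match <- function(map_list) {
  S <- length(map_list)
  K <- nrow(map_list[[1]])
  all_maps <- do.call(rbind, map_list)
  R <- abs(cor(t(all_maps)))
  offs <- cumsum(c(0L, vapply(map_list, nrow, 0L)))[seq_len(S)]
  pm <- perms(K)
  combos <- rep(list(seq_len(nrow(pm))), S - 1L)
  grid <- as.matrix(expand.grid(combos))
  best <- NULL; best_score <- -Inf
  for (g in seq_len(nrow(grid))) {
    assign <- rbind(seq_len(K),
                    t(vapply(seq_len(S - 1L),
                             function(s) pm[grid[g, s], ], integer(K))))
    score <- 0
    part <- vector("list", K)
    for (k in seq_len(K)) {
      rows <- offs + assign[, k]
      part[[k]] <- sort(rows)
      score <- score + sum(R[rows, rows][upper.tri(diag(S))])
    }
    if (score > best_score) { best_score <- score; best <- part }
  }
  best[order(vapply(best, min, 0L))]
}

# Brute-force re-implementation of the Monte-Carlo extent rule for tiny
# grids (independent of the package's cluster labelling: uses its own
# recursive labelling).
oracle_max_cluster <- function(supra) {
  dims <- dim(supra)
  seen <- array(FALSE, dims)
  best <- 0L
  coords <- which(supra, arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    start <- coords[r, ]
    if (seen[start[1], start[2], start[3]]) next
    queue <- list(start); seen[start[1], start[2], start[3]] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                     c(0,0,1), c(0,0,-1))) {
        q <- p + d
        if (all(q >= 1) && all(q <= dims) && supra[q[1], q[2], q[3]] &&
            !seen[q[1], q[2], q[3]]) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    best <- max(best, size)
  }
  best
}

oracle_mc_extent <- function(mask, voxel_p, n_sims, corrected_alpha, seed) {
  dims <- dim(mask)
  zthr <- qnorm(1 - voxel_p / 2)
  set.seed(seed)
  mx <- integer(n_sims)
  for (s in seq_len(n_sims)) {
    vol <- array(rnorm(prod(dims)), dims)
    v <- vol[which(mask)]
    v <- (v - mean(v)) / sd(v)
    supra <- array(FALSE, dims)
    supra[which(mask)[abs(v) > zthr]] <- TRUE
    mx[s] <- oracle_max_cluster(supra)
  }
  k <- 1L
  while (k <= max(mx) && mean(mx >= k) > corrected_alpha) k <- k + 1L
  k
}

# Null feature table for classification tests.
null_feature_table <- function(n = 24, d = 40, seed = 1) {
  set.seed(seed)
  structure(list(subjects = sprintf("s%02d", 1:n),
                 groups = rep(c("A", "B"), each = n / 2),
                 features = matrix(rnorm(n * d), n,
                                   dimnames = list(NULL, paste0("f", 1:d))),
                 feature_names = paste0("f", 1:d)),
            class = "feature_table")
}
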