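#' Cronbach's alpha of an item matrix
#'
#' Internal-consistency reliability: `alpha = k/(k-1) * (1 - sum(item
#' variances) / variance(item sum))`, with items in rows and observations in
#' columns. For matched component clusters the items are the members' spatial
#' maps and the observations are in-mask voxels, giving one alpha per cluster.
#'
#' @param item_matrix numeric matrix, items x observations (k >= 2 rows,
#'   >= 2 columns).
#' @return alpha (scalar, <= 1).
#' @export
cronbach_alpha <- function(item_matrix) {
  k <- nrow(item_matrix)
  if (is.null(k) || k < 2L) stop("need >= 2 items")
  if (ncol(item_matrix) < 2L) stop("need >= 2 observations")
  total_var <- stats::var(colSums(item_matrix))
  if (total_var == 0) stop("zero total variance: alpha undefined")
  item_vars <- apply(item_matrix, 1L, stats::var)
  (k / (k - 1)) * (1 - sum(item_vars) / total_var)
}

#' Partner matching of components across subjects
#'
#' Groups components from different subjects' decompositions by spatial
#' similarity (absolute Pearson correlation between z-scored maps). Clusters
#' are grown greedily from the globally most similar cross-subject pair; a
#' further subject's component joins only if its |r| to *every* current
#' member reaches `match_threshold` (the admitted component is the one with
#' the highest mean similarity; ties break to the lower component index).
#' Each subject contributes at most one component per cluster. Members are
#' sign-aligned to the representative (the z-scored mean of aligned maps),
#' and clusters are returned ordered by mean within-cluster similarity.
#'
#' @param sets list of `component_set` (>= 2 subjects, one mask).
#' @param match_threshold minimum pairwise |r| within a cluster (default 0.4).
#' @param min_members smallest cluster size kept (default 2).
#' @return list of `component_cluster`: `members` (subject_id, model_order,
#'   component_index, sign), `representative_map`, `member_maps` (aligned,
#'   members x voxels), `alpha`, `mean_similarity`, `level = "first"`.
#' @export
match_components <- function(sets, match_threshold = 0.4, min_members = 2L) {
  if (length(sets) < 2L) stop("need >= 2 subjects")
  masks <- lapply(sets, `[[`, "mask")
  if (!all(vapply(masks, function(m) identical(dim(m), dim(masks[[1]])) &&
                    all(m == masks[[1]]), TRUE)))
    stop("all component sets must share one mask")
  if (sum(masks[[1]]) == 0L) stop("empty mask")
  maps <- do.call(rbind, lapply(sets, `[[`, "spatial_maps"))
  meta <- do.call(rbind, lapply(seq_along(sets), function(i)
    data.frame(set = i, subject_id = sets[[i]]$subject_id,
               model_order = sets[[i]]$model_order,
               component_index = seq_len(nrow(sets[[i]]$spatial_maps)))))
  cl <- greedy_partner_match(maps, meta$set, match_threshold)
  clusters <- lapply(cl, function(members)
    build_cluster(members, maps, meta, level = "first"))
  clusters <- Filter(function(x) nrow(x$members) >= min_members, clusters)
  clusters[order(vapply(clusters, `[[`, 0, "mean_similarity"),
                 decreasing = TRUE)]
}

# Core greedy reciprocal matcher. maps: n x voxels; owner: integer id of the
# decomposition each row belongs to. Returns a list of integer member vectors.
greedy_partner_match <- function(maps, owner, match_threshold) {
  n <- nrow(maps)
  R <- abs(stats::cor(t(maps)))
  diag(R) <- 0
  same <- outer(owner, owner, "==")
  R[same] <- 0
  used <- logical(n)
  out <- list()
  repeat {
    Ravail <- R
    Ravail[used, ] <- 0; Ravail[, used] <- 0
    m <- max(Ravail)
    if (m < match_threshold || m == 0) break
    ij <- which(Ravail == m, arr.ind = TRUE)[1L, ]
    members <- as.integer(ij)
    for (s in setdiff(unique(owner), owner[members])) {
      cand <- which(owner == s & !used)
      if (length(cand) == 0L) next
      sims <- R[cand, members, drop = FALSE]
      ok <- apply(sims, 1L, min) >= match_threshold
      if (!any(ok)) next
      cand <- cand[ok]
      best <- cand[which.max(rowMeans(sims[ok, , drop = FALSE]))]
      members <- c(members, best)
    }
    used[members] <- TRUE
    out[[length(out) + 1L]] <- sort(members)
  }
  out
}

# Assemble a component_cluster from member row indices.
build_cluster <- function(members, maps, meta, level) {
  M <- maps[members, , drop = FALSE]
  # sign-align to the first member, then to the running mean
  signs <- rep(1, nrow(M))
  for (i in seq_len(nrow(M))[-1]) {
    r <- stats::cor(M[1, ], M[i, ])
    if (r < 0) { M[i, ] <- -M[i, ]; signs[i] <- -1 }
  }
  rep_map <- zscore(colMeans(M))
  sims <- stats::cor(t(M))
  mean_sim <- if (nrow(M) > 1) mean(sims[upper.tri(sims)]) else 1
  alpha <- if (nrow(M) > 1) cronbach_alpha(M) else NA_real_
  structure(list(
    members = cbind(meta[members, c("subject_id", "model_order",
                                    "component_index")],
                    sign = signs),
    representative_map = rep_map, member_maps = M, alpha = alpha,
    mean_similarity = mean_sim, level = level,
    member_rows = members), class = "component_cluster")
}

#' @export
print.component_cluster <- function(x, ...) {
  cat(sprintf("<component_cluster (%s level) | %d members | alpha %.3f | mean |r| %.3f>\n",
              x$level, nrow(x$members), x$alpha, x$mean_similarity))
  invisible(x)
}

#' Voxelwise one-sample t-map of a cluster
#'
#' One-sample t-test across the cluster's aligned member maps at every
#' in-mask voxel (`df = members - 1`). Voxels with zero variance and nonzero
#' mean get a signed `Inf` sentinel; zero variance and zero mean give 0.
#'
#' @param cluster a `component_cluster`, or a plain members x voxels matrix.
#' @param mask 3D logical analysis mask (voxel count must match columns).
#' @return a `stat_map`: 3D t array, `df`, `mask`.
#' @export
cluster_onesample_map <- function(cluster, mask) {
  M <- if (inherits(cluster, "component_cluster")) cluster$member_maps else
    cluster
  k <- nrow(M)
  if (is.null(k) || k < 2L) stop("need >= 2 member maps")
  mu <- colMeans(M)
  sdv <- sqrt(colSums((M - rep(mu, each = k))^2) / (k - 1))
  tval <- ifelse(sdv > 0, mu / (sdv / sqrt(k)),
                 ifelse(mu == 0, 0, sign(mu) * Inf))
  stat_map(tval, df = k - 1L, mask = mask)
}

#' Second-level partner matching across model orders
#'
#' Matches first-level cluster representatives across ICA model orders with
#' the same greedy rule used across subjects, yielding groups of first-level
#' clusters ("clusters of clusters"). Groups spanning fewer than `min_orders`
#' distinct orders are dropped.
#'
#' @param first_level named list: model order -> list of first-level
#'   `component_cluster` (>= 2 orders).
#' @param match_threshold minimum pairwise |r| (default 0.4).
#' @param min_orders minimum distinct orders a group must span; default the
#'   majority of supplied orders.
#' @return list of groups; each group is a list of first-level clusters with
#'   attributes `orders` (the distinct orders spanned).
#' @export
hierarchical_match <- function(first_level, match_threshold = 0.4,
                               min_orders = NULL) {
  if (length(first_level) < 2L)
    stop("hierarchical matching needs >= 2 model orders; use match_components() for a single order")
  if (is.null(min_orders))
    min_orders <- floor(length(first_level) / 2) + 1L
  reps <- list(); owner <- integer(0); ref <- list()
  for (o in seq_along(first_level)) {
    for (cl in first_level[[o]]) {
      reps[[length(reps) + 1L]] <- cl$representative_map
      owner <- c(owner, o)
      ref[[length(ref) + 1L]] <- cl
    }
  }
  if (length(reps) < 2L) return(list())
  maps <- do.call(rbind, reps)
  groups <- greedy_partner_match(maps, owner, match_threshold)
  out <- list()
  for (g in groups) {
    orders <- unique(vapply(ref[g], function(cl) cl$members$model_order[1], 0))
    if (length(orders) < min_orders) next
    grp <- ref[g]
    attr(grp, "orders") <- sort(orders)
    out[[length(out) + 1L]] <- grp
  }
  out
}

#' Select the most reproducible cluster per group
#'
#' From each cluster-of-clusters, keeps the first-level cluster with the
#' highest Cronbach's alpha; ties break to larger membership, then to lower
#' model order. The selection is returned ordered by alpha, descending.
#'
#' @param groups output of [hierarchical_match()].
#' @return list of first-level `component_cluster`.
#' @export
select_reproducible <- function(groups) {
  picked <- lapply(groups, function(grp) {
    a <- vapply(grp, `[[`, 0, "alpha")
    nm <- vapply(grp, function(cl) nrow(cl$members), 0)
    ord <- vapply(grp, function(cl) cl$members$model_order[1], 0)
    grp[[order(-a, -nm, ord)[1L]]]
  })
  picked[order(vapply(picked, `[[`, 0, "alpha"), decreasing = TRUE)]
}

#' Full HPM-ICA procedure
#'
#' Runs subject-level spatial ICA at each model order, first-level partner
#' matching across subjects within order, second-level matching across
#' orders, and alpha-based selection of one reproducible cluster per group.
#'
#' @param runs list of standardized [bold_run()].
#' @param orders integer vector of model orders (>= 2 values).
#' @param seed master seed.
#' @param n_restarts ICA restarts per decomposition.
#' @param match_threshold partner-matching similarity floor.
#' @param min_orders see [hierarchical_match()].
#' @return list: `selected` (clusters, alpha-ordered), `groups`,
#'   `first_level`, `sets` (per order, per subject `component_set`).
#' @export
hpm_ica <- function(runs, orders, seed = 1L, n_restarts = 3L,
                    match_threshold = 0.4, min_orders = NULL) {
  sets <- list()
  first_level <- list()
  for (o in orders) {
    so <- lapply(seq_along(runs), function(i)
      decompose_subject(runs[[i]], o, seed = derive_seed(seed, o * 1000L + i),
                        n_restarts = n_restarts))
    sets[[as.character(o)]] <- so
    first_level[[as.character(o)]] <- match_components(so, match_threshold)
  }
  groups <- hierarchical_match(first_level, match_threshold, min_orders)
  selected <- select_reproducible(groups)
  list(selected = selected, groups = groups, first_level = first_level,
       sets = sets)
}

#' Per-subject member maps and time courses of a selected cluster
#'
#' For each member of the cluster, pulls the subject's sign-aligned spatial
#' map and time course from the stored decompositions.
#'
#' @param cluster a first-level `component_cluster`.
#' @param sets the per-order decompositions from [hpm_ica()] (`$sets`).
#' @return list with `maps` (subjects x voxels), `timecourses` (list of t
#'   vectors), `subject_id` vector.
#' @export
cluster_member_data <- function(cluster, sets) {
  ord <- as.character(cluster$members$model_order[1])
  so <- sets[[ord]]
  ids <- vapply(so, `[[`, "", "subject_id")
  n <- nrow(cluster$members)
  maps <- matrix(NA_real_, n, length(cluster$representative_map))
  tcs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- so[[match(cluster$members$subject_id[i], ids)]]
    k <- cluster$members$component_index[i]
    sg <- cluster$members$sign[i]
    maps[i, ] <- sg * s$spatial_maps[k, ]
    tcs[[i]] <- sg * s$time_courses[, k]
  }
  list(maps = maps, timecourses = tcs,
       subject_id = cluster$members$subject_id)
}
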