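#' Pipeline configuration
#'
#' Builds the configuration for [run_pipeline()]: stage toggles, all module
#' parameters, and the master seed from which every stage's seed is derived.
#'
#' @param stages character vector of stages to run, in order, from
#'   `simulate`, `preprocess`, `ica`, `groupstats`, `granger`, `classify`.
#' @param cohort a [cohort_config()] (used by the `simulate` stage).
#' @param input_dir read a previously written cohort instead of simulating
#'   (used when `simulate` is disabled).
#' @param smooth_fwhm_mm preprocessing smoothing FWHM, mm (default 0: the
#'   synthetic sources are already smooth).
#' @param orders ICA model orders for the hierarchical sweep.
#' @param n_restarts,match_threshold,min_orders see [hpm_ica()].
#' @param voxel_p,corrected_alpha,n_sims,mask_p group-statistics thresholds:
#'   voxelwise two-sided p, target family-wise error, Monte-Carlo simulation
#'   count, and RSN-mask one-sided p.
#' @param gc_order VAR lag order for GCIs.
#' @param relays character vector of selected-cluster names (e.g. `"C3"`)
#'   used as relays for mediated GCIs.
#' @param fs_alpha,svm_width,svm_cost classification parameters.
#' @param seed master seed.
#' @param outdir optional output directory; when set, every stage persists
#'   its outputs (NIfTI/TSV/JSON) and the manifest records their hashes.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "preprocess", "ica",
                                       "groupstats", "granger", "classify"),
                            cohort = cohort_config(), input_dir = NULL,
                            smooth_fwhm_mm = 0, orders = c(6L, 8L, 10L),
                            n_restarts = 3L, match_threshold = 0.4,
                            min_orders = NULL, voxel_p = 0.01,
                            corrected_alpha = 0.05, n_sims = 500L,
                            mask_p = 0.001, gc_order = 1L,
                            relays = character(0), fs_alpha = 0.05,
                            svm_width = 0.5, svm_cost = 1, seed = 1L,
                            outdir = NULL) {
  structure(list(stages = stages, cohort = cohort, input_dir = input_dir,
                 smooth_fwhm_mm = smooth_fwhm_mm, orders = as.integer(orders),
                 n_restarts = as.integer(n_restarts),
                 match_threshold = match_threshold, min_orders = min_orders,
                 voxel_p = voxel_p, corrected_alpha = corrected_alpha,
                 n_sims = as.integer(n_sims), mask_p = mask_p,
                 gc_order = as.integer(gc_order), relays = relays,
                 fs_alpha = fs_alpha, svm_width = svm_width,
                 svm_cost = svm_cost, seed = as.integer(seed),
                 outdir = outdir), class = "pipeline_config")
}

.pipeline_stages <- c("simulate", "preprocess", "ica", "groupstats",
                      "granger", "classify")

#' Validate a pipeline configuration
#'
#' Returns structured issues instead of throwing: each issue has a `level`
#' (`"error"` or `"warning"`) and a message. Unknown stage names, unstable
#' coupling matrices, an order list too short for hierarchical matching, and
#' out-of-range thresholds are all reported.
#'
#' @param config a [pipeline_config()] (or plain list with the same fields).
#' @return data.frame with columns `level`, `message` (zero rows when clean).
#' @export
validate_config <- function(config) {
  issues <- list()
  add <- function(level, msg)
    issues[[length(issues) + 1L]] <<- data.frame(level = level, message = msg)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(config), known)
  for (u in unknown) {
    near <- known[which.min(utils::adist(u, known))]
    add("warning", sprintf("unknown key '%s' (did you mean '%s'?)", u, near))
  }
  bad_stage <- setdiff(config$stages, .pipeline_stages)
  for (s in bad_stage) add("error", sprintf("unknown stage '%s'", s))
  if ("ica" %in% config$stages && length(config$orders) < 2L)
    add("error", "hierarchical matching needs >= 2 model orders (min-orders rule); supply at least two entries in 'orders'")
  if (!is.null(config$cohort)) {
    for (nm in c("coupling_A", "coupling_B")) {
      m <- config$cohort[[nm]]
      if (is.matrix(m) &&
          max(Mod(eigen(m, only.values = TRUE)$values)) >= 1)
        add("error", sprintf("%s is unstable (spectral radius >= 1)", nm))
    }
  }
  if (!is.null(config$voxel_p) &&
      (config$voxel_p <= 0 || config$voxel_p >= 1))
    add("error", "voxel_p must be in (0, 1)")
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir))
    add("error", sprintf("input_dir '%s' does not exist", config$input_dir))
  if (length(issues) == 0L)
    return(data.frame(level = character(0), message = character(0)))
  do.call(rbind, issues)
}

#' Run the full connectivity pipeline
#'
#' Executes the enabled stages in order — simulate (or ingest), preprocess,
#' HPM-ICA, group statistics, Granger causality, classification — with every
#' stage seeded deterministically from the master seed. Re-running with the
#' same configuration reproduces all outputs.
#'
#' The group-statistics stage computes, per selected cluster: the one-sample
#' t-map, its RSN mask, the covariate-adjusted group GLM restricted to that
#' mask, and the cluster-extent-corrected group-difference clusters. One
#' Monte-Carlo extent threshold is derived on the full analysis mask and
#' shared across clusters (RSN masks are subsets, so the shared extent is
#' conservative there). Per-subject mean z within each surviving cluster
#' becomes a functional-connectivity feature; subject GCIs between selected
#' clusters' time courses become effective-connectivity features; both feed
#' MLDA and kernel-SVM LOOCV.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: per-stage outputs (`cohort`,
#'   `ica`, `groupstats`, `granger`, `classify`) and a `manifest` (stages,
#'   parameters, seeds, timings, output files with MD5 hashes).
#' @export
run_pipeline <- function(config) {
  issues <- validate_config(config)
  if (any(issues$level == "error"))
    stop(paste(c("invalid config:", issues$message[issues$level == "error"]),
               collapse = "\n  "))
  cf <- config
  out <- list()
  manifest <- list(stages = list(), seed = cf$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  files <- character(0)
  persist <- !is.null(cf$outdir)
  if (persist) dir.create(cf$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 2))
    res
  }

  runs <- NULL
  if ("simulate" %in% cf$stages) {
    out$cohort <- stage("simulate", {
      cc <- cf$cohort
      cc$seed <- derive_seed(cf$seed, 11L)
      co <- generate_cohort(cc)
      if (persist) write_cohort(co, file.path(cf$outdir, "cohort"), cc)
      co
    })
    runs <- out$cohort$runs
  } else if (!is.null(cf$input_dir)) {
    runs <- stage("ingest", read_cohort(cf$input_dir))
  }

  if ("preprocess" %in% cf$stages && !is.null(runs)) {
    runs <- stage("preprocess", lapply(runs, function(r) {
      if (cf$smooth_fwhm_mm > 0) {
        d <- dim(r$data)
        for (t in seq_len(d[4]))
          r$data[, , , t] <- gaussian_smooth(r$data[, , , t],
                                             cf$smooth_fwhm_mm,
                                             r$voxel_size_mm)
      }
      standardize_timecourses(r)
    }))
    out$runs <- runs
  }

  groups <- stats::setNames(vapply(runs, `[[`, "", "group"),
                            vapply(runs, `[[`, "", "subject_id"))

  ica <- NULL
  if ("ica" %in% cf$stages) {
    ica <- stage("ica", hpm_ica(runs, cf$orders,
                                seed = derive_seed(cf$seed, 22L),
                                n_restarts = cf$n_restarts,
                                match_threshold = cf$match_threshold,
                                min_orders = cf$min_orders))
    out$ica <- ica
  }

  gstats <- NULL
  if ("groupstats" %in% cf$stages && !is.null(ica)) {
    gstats <- stage("groupstats", {
      mask <- runs[[1]]$mask
      design_all <- data.frame(
        subject_id = names(groups), group = unname(groups),
        age = vapply(runs, function(r) r$covariates$age, 0),
        sex = vapply(runs, function(r) r$covariates$sex, 0))
      extent_k <- mc_cluster_extent(mask, cf$voxel_p, cf$smooth_fwhm_mm,
                                    runs[[1]]$voxel_size_mm,
                                    n_sims = cf$n_sims,
                                    corrected_alpha = cf$corrected_alpha,
                                    seed = derive_seed(cf$seed, 33L))
      per_cluster <- list()
      fc_scores <- data.frame(subject_id = names(groups))
      for (ci in seq_along(ica$selected)) {
        cl <- ica$selected[[ci]]
        mem <- cluster_member_data(cl, ica$sets)
        onesamp <- cluster_onesample_map(cl, mask)
        rsn <- make_rsn_mask(onesamp, cf$mask_p)
        des <- design_all[match(mem$subject_id, design_all$subject_id), ]
        glm_mask <- if (any(rsn)) rsn else mask
        cols <- match(which(glm_mask), which(mask))
        gm <- fit_group_glm(mem$maps[, cols, drop = FALSE],
                            des[, c("group", "age", "sex")], glm_mask)
        thr <- apply_threshold(gm, cf$voxel_p, as.integer(extent_k))
        scores <- NULL
        if (nrow(thr$clusters) > 0) {
          for (j in seq_len(nrow(thr$clusters))) {
            sc <- cluster_scores(mem$maps[, cols, drop = FALSE], thr,
                                 thr$clusters[j, ])
            nm <- sprintf("C%d.cl%d", ci, j)
            v <- rep(NA_real_, nrow(fc_scores))
            v[match(mem$subject_id, fc_scores$subject_id)] <- sc
            fc_scores[[nm]] <- v
          }
        }
        per_cluster[[sprintf("C%d", ci)]] <-
          list(onesample = onesamp, rsn_mask = rsn, glm = thr,
               members = mem$subject_id)
      }
      list(per_cluster = per_cluster, extent_k = as.integer(extent_k),
           fc_scores = fc_scores, design = design_all)
    })
    out$groupstats <- gstats
  }

  granger_res <- NULL
  if ("granger" %in% cf$stages && !is.null(ica)) {
    granger_res <- stage("granger", {
      common <- Reduce(intersect, lapply(ica$selected, function(cl)
        cl$members$subject_id))
      tabs <- lapply(common, function(sid) {
        tcs <- lapply(seq_along(ica$selected), function(ci) {
          mem <- cluster_member_data(ica$selected[[ci]], ica$sets)
          mem$timecourses[[match(sid, mem$subject_id)]]
        })
        names(tcs) <- sprintf("C%d", seq_along(ica$selected))
        gci_table(tcs, order = cf$gc_order, relays = cf$relays,
                  subject_id = sid)
      })
      tab <- do.call(rbind, tabs)
      list(table = tab, report = gci_group_report(tab, groups),
           subjects = common)
    })
    out$granger <- granger_res
  }

  if ("classify" %in% cf$stages && !is.null(granger_res)) {
    out$classify <- stage("classify", {
      common <- granger_res$subjects
      fc <- gstats$fc_scores[match(common, gstats$fc_scores$subject_id), ,
                             drop = FALSE]
      fc <- fc[, c(TRUE, !vapply(fc[-1], anyNA, TRUE)), drop = FALSE]
      ft <- build_features(fc, granger_res$table, groups)
      res <- list(
        mlda = loocv(ft, "mlda", alpha = cf$fs_alpha, positive = "A"),
        ksvm = loocv(ft, "ksvm", alpha = cf$fs_alpha, positive = "A",
                     width = cf$svm_width, cost = cf$svm_cost))
      res$features <- ft
      res$weights <- average_feature_weights(
        lapply(res$mlda$folds, `[[`, "weights"),
        ncol(ft$features), ft$feature_names)
      res
    })
  }

  # severity correlation: first surviving cluster of the alpha-top component
  if (!is.null(gstats)) {
    sev <- vapply(runs, `[[`, 0, "severity")
    names(sev) <- names(groups)
    fcn <- setdiff(names(gstats$fc_scores), "subject_id")
    if (length(fcn) > 0 && any(is.finite(sev))) {
      sc <- gstats$fc_scores[[fcn[1]]]
      keep <- is.finite(sc) & is.finite(sev)
      if (sum(keep) >= 3)
        out$severity <- c(severity_correlation(sc[keep], sev[keep]),
                          feature = fcn[1])
    }
  }

  if (persist) {
    if (!is.null(granger_res))
      utils::write.table(granger_res$table,
                         file.path(cf$outdir, "gci_table.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(out$classify)) {
      utils::write.table(out$classify$weights,
                         file.path(cf$outdir, "feature_weights.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(
        mlda = out$classify$mlda[c("accuracy", "sensitivity", "specificity")],
        ksvm = out$classify$ksvm[c("accuracy", "sensitivity", "specificity")]),
        file.path(cf$outdir, "classification.json"), auto_unbox = TRUE,
        digits = NA)
    }
    files <- list.files(cf$outdir, recursive = TRUE, full.names = TRUE)
    manifest$outputs <- lapply(stats::setNames(files, basename(files)),
                               function(f) unname(tools::md5sum(f)))
  }
  manifest$parameters <- unclass(cf)[setdiff(names(cf), c("cohort", "outdir"))]
  manifest$parameters$cohort <- lapply(unclass(cf$cohort), function(x)
    if (is.matrix(x)) as.vector(x) else x)
  out$manifest <- manifest
  if (persist)
    jsonlite::write_json(manifest, file.path(cf$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  stages:",
      paste(names(x$manifest$stages), collapse = ", "), "\n")
  if (!is.null(x$classify))
    cat(sprintf("  MLDA accuracy %.1f%% | kSVM accuracy %.1f%%\n",
                100 * x$classify$mlda$accuracy,
                100 * x$classify$ksvm$accuracy))
  invisible(x)
}
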