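#' Configuration for a synthetic resting-state cohort
#'
#' Builds the full parameter set for [generate_cohort()]. The generator plants
#' the statistical structure the downstream analysis assumes: a shared set of
#' smooth spatial networks mixed by stable lag-1 vector-autoregressive (VAR)
#' time courses, with group differences expressed as (a) altered spatial-map
#' amplitude in chosen networks (the functional-connectivity analog) and
#' (b) altered directed lag-1 coupling coefficients (the effective-connectivity
#' analog), plus Gaussian observation noise.
#'
#' Defaults are a desk-scale cohort: 12 subjects per group on a 16 x 16 x 8
#' grid with 150 volumes at TR = 2 s and 6 networks. Acquisition-scale runs
#' (20 per group, 64 x 64 x 36, 240 volumes) are a configuration choice.
#'
#' The default coupling matrices share a stable backbone (self-coupling 0.3,
#' directed edges 2->1, 3->1 at 0.35, and a relay chain 4->5->6 at 0.4) and
#' differ between groups by a 0.3 reduction of the 2->1 and 3->1 edges in
#' group A, mimicking weakened top-down influence in patients. The default
#' amplitude effect raises networks 1-3 in group A by one between-subject
#' standard deviation (multiplier 1.2 with subject-level amplitude SD 0.2).
#'
#' @param n_per_group subjects per group (>= 2).
#' @param grid integer 3-vector of voxel dimensions (nx, ny, nz).
#' @param n_volumes number of timepoints per run.
#' @param tr_seconds repetition time in seconds.
#' @param n_networks number of planted spatial networks.
#' @param coupling_A,coupling_B lag-1 VAR coupling matrices
#'   (n_networks x n_networks), spectral radius < 1. `NULL` uses the defaults
#'   described above.
#' @param effect_map 2 x n_networks matrix of per-group spatial amplitude
#'   multipliers (rows: group A, group B). `NULL` uses the default.
#' @param amp_sd between-subject SD of network amplitude.
#' @param signal_scale multiplier applied to the unit-norm source maps; the
#'   default (10) puts the peak in-blob signal SD near 1, twice the default
#'   `noise_sd`.
#' @param noise_sd observation-noise standard deviation.
#' @param smooth_fwhm_mm spatial smoothness (FWHM, mm) of the planted sources.
#' @param voxel_size_mm numeric 3-vector of voxel edge lengths in mm.
#' @param innovation_sd SD of the VAR innovations.
#' @param confound_age if `TRUE`, inject a true age effect on network 1
#'   amplitude (off by default so covariate adjustment is testable as a no-op).
#' @param seed integer seed controlling all randomness.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 12, grid = c(16, 16, 8),
                          n_volumes = 150, tr_seconds = 2, n_networks = 6,
                          coupling_A = NULL, coupling_B = NULL,
                          effect_map = NULL, amp_sd = 0.2, signal_scale = 10,
                          noise_sd = 0.5,
                          smooth_fwhm_mm = 6, voxel_size_mm = c(3, 3, 3),
                          innovation_sd = 1, confound_age = FALSE, seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (n_volumes <= 10 * n_networks)
    stop("n_volumes must exceed 10 x n_networks")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(coupling_B)) coupling_B <- default_coupling(n_networks)
  if (is.null(coupling_A)) {
    coupling_A <- coupling_B
    # weakened top-down edges in the patient-analog group
    if (n_networks >= 3) {
      coupling_A[1, 2] <- coupling_A[1, 2] - 0.3
      coupling_A[1, 3] <- coupling_A[1, 3] - 0.3
    }
  }
  for (m in list(A = coupling_A, B = coupling_B)) {
    if (!is.matrix(m) || nrow(m) != n_networks || ncol(m) != n_networks)
      stop("coupling matrices must be n_networks x n_networks")
    if (max(Mod(eigen(m, only.values = TRUE)$values)) >= 1)
      stop("coupling matrix is unstable (spectral radius >= 1)")
  }
  if (is.null(effect_map)) {
    effect_map <- rbind(A = rep(1, n_networks), B = rep(1, n_networks))
    if (n_networks >= 3) effect_map[1, 1:3] <- 1 + amp_sd  # 1-SD amplitude gap
  }
  structure(list(
    n_per_group = as.integer(n_per_group), grid = as.integer(grid),
    n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
    n_networks = as.integer(n_networks),
    coupling_A = coupling_A, coupling_B = coupling_B,
    effect_map = effect_map, amp_sd = amp_sd, signal_scale = signal_scale,
    noise_sd = noise_sd,
    smooth_fwhm_mm = smooth_fwhm_mm, voxel_size_mm = voxel_size_mm,
    innovation_sd = innovation_sd, confound_age = isTRUE(confound_age),
    seed = as.integer(seed)), class = "cohort_config")
}

default_coupling <- function(k) {
  m <- diag(0.3, k)
  if (k >= 3) { m[1, 2] <- 0.35; m[1, 3] <- 0.35 }  # 2->1, 3->1
  if (k >= 6) { m[5, 4] <- 0.4;  m[6, 5] <- 0.4 }   # relay chain 4->5->6
  m
}

#' Planted smooth spatial source maps
#'
#' Places `n_networks` non-overlapping blob templates on the grid (centres on
#' a lattice with spacing chosen to avoid overlap), optionally smooths each
#' with a separable Gaussian kernel of the given FWHM, and scales every map to
#' unit Euclidean norm.
#'
#' @param grid integer 3-vector (nx, ny, nz).
#' @param n_networks number of maps.
#' @param smooth_fwhm_mm FWHM (mm) of the smoothing applied to the blob
#'   indicator; 0 leaves the raw indicator template.
#' @param voxel_size_mm numeric 3-vector, mm.
#' @param seed integer seed (controls which lattice centres are used).
#' @param radius blob half-width in voxels.
#' @return matrix `n_networks x prod(grid)`, rows unit-norm; attribute
#'   `centers` holds the blob centres.
#' @export
make_spatial_sources <- function(grid, n_networks, smooth_fwhm_mm = 6,
                                 voxel_size_mm = c(3, 3, 3), seed = 1L,
                                 radius = 2L) {
  grid <- as.integer(grid)
  pos <- lapply(grid, function(d) {
    if (d - radius < radius + 1L) return(as.integer(ceiling(d / 2)))
    seq(radius + 1L, d - radius, by = 2L * radius + 1L)
  })
  centers <- as.matrix(expand.grid(pos[[1]], pos[[2]], pos[[3]]))
  if (nrow(centers) < n_networks)
    stop(sprintf("grid %s too small to place %d non-overlapping networks (%d sites)",
                 paste(grid, collapse = "x"), n_networks, nrow(centers)))
  set.seed(seed)
  centers <- centers[sample(nrow(centers), n_networks), , drop = FALSE]
  maps <- matrix(0, n_networks, prod(grid))
  for (k in seq_len(n_networks)) {
    vol <- array(0, grid)
    cx <- centers[k, ]
    rng <- lapply(1:3, function(a)
      max(1L, cx[a] - radius):min(grid[a], cx[a] + radius))
    vol[rng[[1]], rng[[2]], rng[[3]]] <- 1
    if (smooth_fwhm_mm > 0)
      vol <- gaussian_smooth(vol, smooth_fwhm_mm, voxel_size_mm)
    maps[k, ] <- as.vector(vol) / sqrt(sum(vol^2))
  }
  attr(maps, "centers") <- centers
  maps
}

#' Simulate stable VAR(1) network time courses
#'
#' Draws `x_t = coupling %*% x_{t-1} + e_t` with i.i.d. Gaussian innovations,
#' discarding a burn-in so the returned sample is stationary.
#'
#' @param coupling square coupling matrix, spectral radius < 1.
#' @param n_volumes timepoints to return.
#' @param innovation_sd innovation standard deviation.
#' @param seed integer seed.
#' @param burn_in steps discarded before recording (>= 100).
#' @return matrix `nrow(coupling) x n_volumes`.
#' @export
generate_var_timecourses <- function(coupling, n_volumes, innovation_sd = 1,
                                     seed = 1L, burn_in = 200L) {
  coupling <- as.matrix(coupling)
  if (nrow(coupling) != ncol(coupling)) stop("coupling must be square")
  if (max(Mod(eigen(coupling, only.values = TRUE)$values)) >= 1)
    stop("unstable coupling: spectral radius >= 1")
  burn_in <- max(100L, as.integer(burn_in))
  k <- nrow(coupling)
  set.seed(seed)
  total <- burn_in + n_volumes
  eps <- matrix(stats::rnorm(k * total, sd = innovation_sd), k, total)
  x <- matrix(0, k, total)
  x[, 1] <- eps[, 1]
  for (t in 2:total) x[, t] <- coupling %*% x[, t - 1] + eps[, t]
  out <- x[, (burn_in + 1):total, drop = FALSE]
  stopifnot(all(is.finite(out)))
  out
}

#' Generate a synthetic multi-subject cohort
#'
#' For every subject, 4D data are built as
#' `sum_k amplitude_k * timecourse_k(t) * source_map_k + noise`, where the
#' per-subject network amplitudes are the group's effect multipliers perturbed
#' by between-subject variation, and time courses follow the group's VAR(1)
#' coupling. Age and sex are drawn from matched distributions with zero true
#' effect (unless `confound_age`); a severity score is generated for group A
#' subjects as a noisy linear readout of their network-1 amplitude, so a
#' severity-connectivity correlation exists by construction.
#'
#' @param config a [cohort_config()].
#' @return list with `runs` (list of `bold_run`) and `truth` (ground-truth
#'   manifest: source maps, per-subject amplitudes and time courses, coupling
#'   matrices, planted group-different networks and edges, seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  maps <- make_spatial_sources(cf$grid, cf$n_networks, cf$smooth_fwhm_mm,
                               cf$voxel_size_mm, seed = derive_seed(cf$seed, 1L))
  n <- 2L * cf$n_per_group
  groups <- rep(c("A", "B"), each = cf$n_per_group)
  set.seed(derive_seed(cf$seed, 2L))
  age <- round(stats::rnorm(n, mean = 32, sd = 8))
  sex <- stats::rbinom(n, 1, 0.5)
  runs <- vector("list", n)
  amps <- matrix(NA_real_, n, cf$n_networks)
  tcs <- vector("list", n)
  nv <- prod(cf$grid)
  for (i in seq_len(n)) {
    g <- groups[i]
    sseed <- derive_seed(cf$seed, 100L + i)
    coup <- if (g == "A") cf$coupling_A else cf$coupling_B
    tc <- generate_var_timecourses(coup, cf$n_volumes, cf$innovation_sd,
                                   seed = sseed)
    set.seed(derive_seed(cf$seed, 1000L + i))
    amp <- cf$effect_map[if (g == "A") 1 else 2, ] +
      stats::rnorm(cf$n_networks, sd = cf$amp_sd)
    if (cf$confound_age) amp[1] <- amp[1] + 0.02 * (age[i] - 32)
    # signal_scale puts the peak in-blob signal SD near 1, i.e. the default
    # noise_sd of 0.5 is half the signal SD
    sig <- crossprod(maps * (amp * cf$signal_scale), tc)  # voxels x time
    noise <- matrix(stats::rnorm(nv * cf$n_volumes, sd = cf$noise_sd),
                    nv, cf$n_volumes)
    dat <- array(sig + noise, c(cf$grid, cf$n_volumes))
    amps[i, ] <- amp
    tcs[[i]] <- tc
    runs[[i]] <- bold_run(
      subject_id = sprintf("sub-%02d", i), group = g, data = dat,
      voxel_size_mm = cf$voxel_size_mm, tr_seconds = cf$tr_seconds,
      mask = array(TRUE, cf$grid),
      covariates = list(age = age[i], sex = sex[i]),
      severity = NA_real_)
  }
  # severity: linear readout of network-1 amplitude in the patient-analog group
  set.seed(derive_seed(cf$seed, 3L))
  is_a <- groups == "A"
  sev <- rep(NA_real_, n)
  sev[is_a] <- 15 + 10 * (amps[is_a, 1] - mean(amps[is_a, 1])) / cf$amp_sd +
    stats::rnorm(sum(is_a), sd = 1.5)
  for (i in which(is_a)) runs[[i]]$severity <- sev[i]
  planted_networks <- which(cf$effect_map[1, ] != cf$effect_map[2, ])
  diff <- which(cf$coupling_A != cf$coupling_B, arr.ind = TRUE)
  planted_edges <- if (nrow(diff))
    data.frame(source = diff[, 2], target = diff[, 1]) else
    data.frame(source = integer(0), target = integer(0))
  truth <- list(source_maps = maps, amplitudes = amps, timecourses = tcs,
                coupling_A = cf$coupling_A, coupling_B = cf$coupling_B,
                planted_networks = planted_networks,
                planted_edges = planted_edges,
                groups = groups, severity = sev, seed = cf$seed)
  list(runs = runs, truth = truth)
}

#' Write a cohort to disk
#'
#' Per-subject NIfTI-1 images (`.nii.gz`, voxel sizes in the header), a
#' subject table TSV (`subject_id`, `group`, `age`, `sex`, `severity`), the
#' ground-truth manifest as JSON, and the configuration as YAML.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param config the [cohort_config()] used (written as `config.yaml`).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(
    subject_id = vapply(cohort$runs, `[[`, "", "subject_id"),
    group = vapply(cohort$runs, `[[`, "", "group"),
    age = vapply(cohort$runs, function(r) r$covariates$age, 0),
    sex = vapply(cohort$runs, function(r) r$covariates$sex, 0),
    severity = vapply(cohort$runs, `[[`, 0, "severity"))
  for (r in cohort$runs)
    write_run(r, file.path(dir, paste0(r$subject_id, "_bold.nii.gz")))
  utils::write.table(tab, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$timecourses <- NULL  # bulky; reproducible from seed
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  if (!is.null(config))
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  invisible(dir)
}
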