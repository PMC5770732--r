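#' A single subject's 4D run
#'
#' Container for one subject's volumetric time series plus the metadata the
#' pipeline needs: voxel geometry, analysis mask, and covariates.
#'
#' @param subject_id character id.
#' @param group group label.
#' @param data 4D numeric array (x, y, z, t), t >= 2.
#' @param voxel_size_mm numeric 3-vector, all > 0.
#' @param tr_seconds repetition time, seconds.
#' @param mask 3D logical array; `NULL` selects nonzero-variance voxels.
#' @param covariates list with `age` (years) and `sex` (0/1).
#' @param severity optional severity score (`NA` if absent).
#' @return object of class `bold_run`.
#' @export
bold_run <- function(subject_id, group, data, voxel_size_mm,
                     tr_seconds = 2, mask = NULL,
                     covariates = list(age = NA_real_, sex = NA_real_),
                     severity = NA_real_) {
  if (length(dim(data)) != 4L) stop("data must be 4D (x, y, z, t)")
  if (dim(data)[4] < 2L) stop("run must have at least 2 timepoints")
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be > 0")
  if (is.null(mask)) mask <- default_mask(data)
  if (!all(dim(mask) == dim(data)[1:3])) stop("mask/data shape mismatch")
  if (sum(mask) < 1L) stop("mask has no voxels")
  if (!all(is.finite(data[array(mask, dim(data)[1:3])])) &&
      !all(is.finite(as.vector(data))))
    stop("non-finite values inside mask")
  structure(list(subject_id = subject_id, group = group, data = data,
                 voxel_size_mm = voxel_size_mm, tr_seconds = tr_seconds,
                 mask = mask == TRUE, covariates = covariates,
                 severity = severity), class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run %s | group %s | %dx%dx%d x %d vols | %d mask voxels>\n",
              x$subject_id, x$group, d[1], d[2], d[3], d[4], sum(x$mask)))
  invisible(x)
}

# Default analysis mask: voxels whose time series has nonzero variance.
default_mask <- function(data) {
  d <- dim(data)
  m <- matrix(data, prod(d[1:3]), d[4])
  v <- rowSums((m - rowMeans(m))^2)
  array(v > 0, d[1:3])
}

#' Read a 4D NIfTI run
#'
#' Loads a NIfTI-1 file, taking voxel sizes and TR from the header, and
#' attaches the subject metadata row. If no mask is given, voxels with
#' nonzero temporal variance form the default mask.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param subject_row one-row data.frame with `subject_id`, `group`, `age`,
#'   `sex` and optionally `severity`.
#' @param mask optional 3D logical array or NIfTI mask path.
#' @return a [bold_run()].
#' @export
read_run <- function(path, subject_row, mask = NULL) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "cannot read NIfTI file '%s': %s", path, conditionMessage(e))))
  if (length(dim(img)) != 4L)
    stop(sprintf("'%s' is %dD; a 4D run is required", path, length(dim(img))))
  pd <- RNifti::pixdim(img)
  if (is.character(mask)) mask <- RNifti::readNifti(mask) != 0
  bold_run(subject_id = as.character(subject_row$subject_id),
           group = as.character(subject_row$group),
           data = unclass(img)[, , , , drop = FALSE],
           voxel_size_mm = pd[1:3],
           tr_seconds = if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2,
           mask = mask,
           covariates = list(age = subject_row$age, sex = subject_row$sex),
           severity = if ("severity" %in% names(subject_row))
             subject_row$severity else NA_real_)
}

#' Write a run (or any volume) as NIfTI-1
#'
#' @param run a [bold_run()], or a plain 3D/4D array (then `voxel_size_mm`
#'   must be supplied).
#' @param path output path (.nii or .nii.gz).
#' @param voxel_size_mm voxel sizes when `run` is a bare array.
#' @param tr_seconds TR when `run` is a bare 4D array.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path, voxel_size_mm = NULL, tr_seconds = 2) {
  if (inherits(run, "bold_run")) {
    arr <- run$data; vs <- run$voxel_size_mm; tr <- run$tr_seconds
  } else {
    arr <- run; vs <- voxel_size_mm; tr <- tr_seconds
    if (is.null(vs)) stop("voxel_size_mm required for bare arrays")
  }
  img <- RNifti::asNifti(arr)
  pd <- if (length(dim(arr)) == 4L) c(vs, tr) else vs
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `subjects.tsv` and per-subject NIfTI runs.
#' @return list of [bold_run()].
#' @export
read_cohort <- function(dir) {
  tab <- utils::read.delim(file.path(dir, "subjects.tsv"))
  lapply(seq_len(nrow(tab)), function(i)
    read_run(file.path(dir, paste0(tab$subject_id[i], "_bold.nii.gz")),
             tab[i, ]))
}
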