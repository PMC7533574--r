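# File formats: scheme JSON/CSV (console units: ms, mT/m), FSL-style
# bval/bvec export, NIfTI volumes via RNifti, cohort output layout, and the
# run manifest.

#' Write an acquisition scheme to JSON or CSV
#'
#' The on-disk dialect carries acquisition-console units (ms, mT/m);
#' in-memory schemes are SI. The JSON form has a header (gamma, delta_ms,
#' n_b0) and one row per weighted measurement (Delta_ms, G0_mT_per_m,
#' direction, b_s_per_mm2); the CSV form carries the header as its first
#' three columns, repeated per row. Round-trips preserve full precision.
#'
#' @param scheme an `fm_scheme`.
#' @param path output path; format chosen by extension (.json or .csv).
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "fm_scheme"))
  m <- scheme$measurements
  rows <- data.frame(Delta_ms = m$Delta * 1e3, G0_mT_per_m = m$G0 * 1e3,
                     direction = m$direction, b_s_per_mm2 = m$bvalue,
                     stringsAsFactors = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(gamma = scheme$gamma, delta_ms = scheme$delta * 1e3,
           n_b0 = scheme$n_b0, measurements = rows),
      path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    out <- cbind(gamma = scheme$gamma, delta_ms = scheme$delta * 1e3,
                 n_b0 = scheme$n_b0, rows)
    utils::write.csv(format(out, digits = 17, trim = TRUE), path,
                     row.names = FALSE, quote = FALSE)
  } else stop("unsupported scheme format (use .json or .csv): ", path)
  invisible(path)
}

#' Read an acquisition scheme from JSON or CSV
#'
#' Validates invariants on read (positive gamma, n_b0 >= 1,
#' 0 < delta <= Delta per row, stored b consistent with the
#' Stejskal-Tanner value recomputed from the row's timing).
#'
#' @param path scheme file written by [write_scheme()] (or hand-authored in
#'   the same dialect).
#' @return an `fm_scheme`.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    header <- obj; rows <- obj$measurements
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    header <- list(gamma = tab$gamma[1], delta_ms = tab$delta_ms[1],
                   n_b0 = tab$n_b0[1])
    rows <- tab
  } else stop("unsupported scheme format (use .json or .csv): ", path)

  for (f in c("gamma", "delta_ms", "n_b0"))
    if (is.null(header[[f]]) || !is.finite(header[[f]]))
      stop("scheme header field missing or non-numeric: ", f)
  for (f in c("Delta_ms", "G0_mT_per_m", "direction", "b_s_per_mm2"))
    if (is.null(rows[[f]])) stop("scheme rows missing field: ", f)
  if (header$gamma <= 0) stop("invalid scheme: gamma must be positive")
  if (header$n_b0 < 1) stop("invalid scheme: n_b0 must be >= 1")
  delta <- header$delta_ms * 1e-3
  bad <- which(rows$Delta_ms * 1e-3 < delta)
  if (length(bad))
    stop("invalid scheme: delta exceeds Delta in row(s) ",
         paste(bad, collapse = ", "))
  b_check <- compute_bvalue(header$gamma, rows$G0_mT_per_m * 1e-3, delta,
                            rows$Delta_ms * 1e-3)
  off <- which(abs(b_check - rows$b_s_per_mm2) >
                 1e-6 * pmax(1, abs(b_check)))
  if (length(off))
    stop("invalid scheme: stored b-value inconsistent with timing in row(s) ",
         paste(off, collapse = ", "))
  meas <- data.frame(Delta = rows$Delta_ms * 1e-3, G0 = rows$G0_mT_per_m * 1e-3,
                     direction = rows$direction, bvalue = b_check,
                     stringsAsFactors = FALSE)
  structure(list(gamma = header$gamma, delta = delta,
                 n_b0 = as.integer(header$n_b0), measurements = meas),
            class = "fm_scheme")
}

#' Export FSL-style bval/bvec files
#'
#' One column per volume (b0 volumes first, then scheme order); b-values
#' rounded to integers for display, unit vectors along x/y/z for the
#' weighted volumes and zeros for b0.
#'
#' @param scheme an `fm_scheme`.
#' @param prefix output prefix; writes `<prefix>.bval` and `<prefix>.bvec`.
#' @return the two paths, invisibly.
#' @export
write_bval_bvec <- function(scheme, prefix) {
  stopifnot(inherits(scheme, "fm_scheme"))
  m <- scheme$measurements
  bvals <- c(rep(0, scheme$n_b0), round(m$bvalue))
  ax <- match(m$direction, c("x", "y", "z"))
  bvec <- matrix(0, 3, scheme$n_b0 + nrow(m))
  bvec[cbind(ax, scheme$n_b0 + seq_len(nrow(m)))] <- 1
  bval_path <- paste0(prefix, ".bval"); bvec_path <- paste0(prefix, ".bvec")
  writeLines(paste(bvals, collapse = " "), bval_path)
  writeLines(apply(bvec, 1, paste, collapse = " "), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI-1 file, optionally gzipped.
#' @param mask if TRUE, return a logical array (any non-zero voxel = TRUE).
#' @return array with attribute `affine` (the 4x4 xform) and
#'   `pixdim` (voxel spacing).
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))
  if (mask) arr <- array(arr != 0, dim(arr))
  attr(arr, "affine") <- structure(RNifti::xform(img), class = NULL)
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' Write an array as NIfTI
#'
#' @param arr 3D or 4D numeric/logical array.
#' @param path output path (.nii or .nii.gz).
#' @param affine optional 4x4 affine to install; `reference` wins if both
#'   are given.
#' @param reference optional template image or path whose header to reuse.
#' @param pixdim voxel spacing used when no reference/affine is given
#'   (default 1.875 x 1.875 x 5 mm, the phantom's nominal spacing).
#' @return `path`, invisibly.
#' @export
write_volume <- function(arr, path, affine = NULL, reference = NULL,
                         pixdim = c(1.875, 1.875, 5)) {
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  img <- if (!is.null(reference)) RNifti::asNifti(arr, reference = reference)
  else RNifti::asNifti(arr)
  if (is.null(reference)) {
    if (!is.null(affine)) {
      RNifti::qform(img) <- structure(affine, code = 2L)
    } else {
      pd <- RNifti::pixdim(img)
      pd[seq_along(pixdim)] <- pixdim
      RNifti::pixdim(img) <- pd
    }
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a cohort to a dataset directory
#'
#' Layout: `scheme.json`, `subjects.csv` (covariates and true parameters),
#' and per subject `<id>_dwi.nii.gz`, `<id>_roi_left.nii.gz`,
#' `<id>_roi_right.nii.gz` when phantoms are present.
#'
#' @param cohort an `fm_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_scheme(cohort$scheme, file.path(dir, "scheme.json"))
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$phantoms)) {
    for (i in seq_len(nrow(cohort$subjects))) {
      id <- cohort$subjects$id[i]; ph <- cohort$phantoms[[i]]
      write_volume(ph$dwi, file.path(dir, paste0(id, "_dwi.nii.gz")))
      write_volume(ph$roi_left, file.path(dir, paste0(id, "_roi_left.nii.gz")))
      write_volume(ph$roi_right, file.path(dir, paste0(id, "_roi_right.nii.gz")))
    }
  }
  invisible(dir)
}

#' Write parameter maps as NIfTI plus a QC report
#'
#' One file per map (alpha, hurst, mu, D, adc) named `<prefix>_<map>.nii.gz`
#' with the supplied affine, and `<prefix>_qc.json` with fitted/unfittable
#' counts and the ADC b-value used.
#'
#' @param maps an `fm_maps`.
#' @param prefix output path prefix.
#' @param affine optional 4x4 affine (e.g. from the input DWI).
#' @return written paths, invisibly.
#' @export
write_maps <- function(maps, prefix, affine = NULL) {
  stopifnot(inherits(maps, "fm_maps"))
  paths <- character(0)
  for (nm in c("alpha", "hurst", "mu", "D", "adc")) {
    p <- paste0(prefix, "_", nm, ".nii.gz")
    write_volume(maps[[nm]], p, affine = affine)
    paths <- c(paths, p)
  }
  qc_path <- paste0(prefix, "_qc.json")
  jsonlite::write_json(maps$qc, qc_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, qc_path))
}

#' Write an analysis report to JSON and CSV
#'
#' @param report an `fm_report` from [run_group_analysis()].
#' @param prefix output prefix; writes `<prefix>.json` and flat
#'   `<prefix>_ttests.csv`, `<prefix>_roc.csv`, `<prefix>_correlations.csv`.
#' @return written paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "fm_report"))
  json_path <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(ttests = report$ttests, roc = report$roc,
         correlations = report$correlations, config = report$config),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- json_path
  for (nm in c("ttests", "roc", "correlations")) {
    p <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a run manifest
#'
#' Records what is needed to reproduce a pipeline stage exactly: the
#' configuration echo, seed, package version and the md5 checksum of every
#' input file.
#'
#' @param path output JSON path.
#' @param stage stage name.
#' @param config list echoed verbatim.
#' @param seed seed used (or NULL).
#' @param inputs character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, config = list(), seed = NULL,
                           inputs = character(0)) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  jsonlite::write_json(
    list(stage = stage,
         package = "fmdiff",
         version = as.character(utils::packageVersion("fmdiff")),
         seed = seed, config = config, input_md5 = sums,
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
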