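#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A 3D array with a `spacing` attribute (mm per axis).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_kbp("no such volume file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_kbp("failed to read NIfTI file ",
                                               path, ": ", conditionMessage(e)))
  vol <- array(as.numeric(img), dim = dim(img))
  attr(vol, "spacing") <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))]
  vol
}

#' Write a 3D volume as NIfTI
#'
#' @param volume 3D numeric array with finite values.
#' @param spacing Voxel spacing in mm per axis (length 3).
#' @param path Destination path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, spacing = c(3.5, 3.5, 2), path) {
  assert_volume3d(volume)
  if (!all(is.finite(volume))) stop_kbp("volume contains non-finite values")
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- as.numeric(spacing)
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) stop_kbp("failed to write ", path, ": ",
                                        conditionMessage(e)))
  invisible(path)
}

#' Read a sparse-voxel CSV into a dense volume
#'
#' The sparse dialect stores one `(flat_index, value)` record per line for
#' each nonzero voxel of a known grid, as used by the OpenKBP challenge
#' distribution of down-sampled 128^3 plans. Flat indices are 0-based. The
#' default flattening is row-major (last axis fastest); a column-major switch
#' is provided because the convention is not universal.
#'
#' @param path CSV file with two columns (a header line is detected and
#'   skipped automatically). An empty record list yields an all-zero volume.
#' @param shape Grid dimensions, e.g. `c(128, 128, 128)`.
#' @param order `"row-major"` (default) or `"column-major"` flattening.
#' @return A dense 3D array of dim `shape`.
#' @export
read_openkbp_sparse <- function(path, shape,
                                order = c("row-major", "column-major")) {
  order <- match.arg(order)
  if (!file.exists(path)) stop_kbp("no such sparse file: ", path)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L)
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L &&
    is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  df <- tryCatch(
    utils::read.csv(path, header = has_header,
                    col.names = c("flat_index", "value")),
    error = function(e) stop_kbp("malformed sparse CSV ", path, ": ",
                                 conditionMessage(e)))
  vol <- array(0, dim = shape)
  if (nrow(df) == 0) return(vol)
  idx <- suppressWarnings(as.numeric(df$flat_index))
  val <- suppressWarnings(as.numeric(df$value))
  if (any(is.na(idx)) || any(is.na(val)))
    stop_kbp("non-numeric record in sparse CSV ", path)
  if (any(idx < 0) || any(idx >= prod(shape)))
    stop_kbp("flat index out of range in ", path,
             " (grid has ", prod(shape), " voxels)")
  if (any(!is.finite(val))) stop_kbp("non-finite value in sparse CSV ", path)
  if (order == "row-major") {
    # i = (x1 * d2 + x2) * d3 + x3, x3 fastest
    x3 <- idx %% shape[3]
    x2 <- (idx %/% shape[3]) %% shape[2]
    x1 <- idx %/% (shape[2] * shape[3])
  } else {
    x1 <- idx %% shape[1]
    x2 <- (idx %/% shape[1]) %% shape[2]
    x3 <- idx %/% (shape[1] * shape[2])
  }
  lin <- x1 + x2 * shape[1] + x3 * shape[1] * shape[2] + 1
  vol[lin] <- val
  vol
}

#' Write a dense volume in the sparse-voxel CSV dialect
#'
#' Inverse of [read_openkbp_sparse()]: records the nonzero voxels only.
#'
#' @param volume Dense 3D array.
#' @param path Destination CSV.
#' @param order Flattening convention; see [read_openkbp_sparse()].
#' @return The path, invisibly.
#' @export
write_openkbp_sparse <- function(volume, path,
                                 order = c("row-major", "column-major")) {
  order <- match.arg(order)
  assert_volume3d(volume)
  d <- dim(volume)
  lin <- which(volume != 0)
  x1 <- (lin - 1) %% d[1]
  x2 <- ((lin - 1) %/% d[1]) %% d[2]
  x3 <- (lin - 1) %/% (d[1] * d[2])
  idx <- if (order == "row-major") (x1 * d[2] + x2) * d[3] + x3
         else x1 + x2 * d[1] + x3 * d[1] * d[2]
  df <- data.frame(flat_index = idx, value = volume[lin])
  df <- df[sort.list(df$flat_index), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a plan sample to disk
#'
#' Canonical on-disk layout: one NIfTI file per volume (CT, dose and each
#' mask) plus a JSON manifest recording the structure names, prescription and
#' voxel spacing, so channel ordering is reconstructible by name.
#'
#' @param sample A `plan_sample`.
#' @param dir Destination directory (created if needed).
#' @param spacing Voxel spacing in mm.
#' @return `dir`, invisibly.
#' @export
write_plan <- function(sample, dir, spacing = c(3.5, 3.5, 2)) {
  stopifnot(inherits(sample, "plan_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(sample$ct, spacing, file.path(dir, "ct.nii.gz"))
  write_volume(sample$dose, spacing, file.path(dir, "dose.nii.gz"))
  for (nm in names(sample$masks)) {
    write_volume(sample$masks[[nm]], spacing,
                 file.path(dir, paste0("mask_", nm, ".nii.gz")))
  }
  manifest <- list(prescription = sample$prescription,
                   spacing = as.numeric(spacing),
                   structures = names(sample$masks))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a plan sample written by [write_plan()]
#'
#' @param dir Plan directory containing `manifest.json`.
#' @return A `plan_sample`.
#' @export
read_plan <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop_kbp("no plan manifest at ", mpath)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  ct <- read_volume(file.path(dir, "ct.nii.gz"))
  dose <- read_volume(file.path(dir, "dose.nii.gz"))
  masks <- list()
  for (nm in manifest$structures) {
    masks[[nm]] <- read_volume(file.path(dir, paste0("mask_", nm, ".nii.gz")))
    attr(masks[[nm]], "spacing") <- NULL
    masks[[nm]] <- round(masks[[nm]])
  }
  sp <- attr(ct, "spacing")
  attr(ct, "spacing") <- NULL
  attr(dose, "spacing") <- NULL
  out <- structure(list(ct = ct, masks = masks, dose = dose,
                        prescription = manifest$prescription),
                   class = "plan_sample")
  attr(out, "spacing") <- sp
  out
}

#' Write a cohort metrics report as CSV
#'
#' One row per (structure, dosimetric index) with cohort mean and standard
#' deviation for the predicted plans, the ground-truth plans, and their
#' difference (predicted minus ground truth).
#'
#' @param report A `dose_metrics` object from [evaluate_cohort()].
#' @param path Destination CSV.
#' @return The path, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  if (!inherits(report, "dose_metrics") || nrow(report$summary) == 0)
    stop_kbp("empty or invalid metrics report")
  utils::write.csv(report$summary, path, row.names = FALSE)
  invisible(path)
}

#' Write DVH curves as CSV triplets
#'
#' @param dvhs Named list of DVH curves from [dvh()] (names = structures).
#' @param path Destination CSV with columns structure, dose, volume_fraction.
#' @return The path, invisibly.
#' @export
write_dvh_csv <- function(dvhs, path) {
  rows <- do.call(rbind, lapply(names(dvhs), function(nm) {
    data.frame(structure = nm, dose = dvhs[[nm]]$dose,
               volume_fraction = dvhs[[nm]]$volume_fraction)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
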