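#' Crop a volume to a cubic window centered on the body
#'
#' The crop center is the rounded centroid of the body mask; the window is
#' clamped to lie inside the grid, so anatomy near an edge shifts the window
#' rather than falling outside it. Cropping to the input size is the
#' identity.
#'
#' @param volume 3D array.
#' @param body_mask Binary 3D array of the same shape; must be nonempty.
#' @param out_size Output edge length in voxels (<= input size per axis).
#' @return The cropped `out_size^3` array.
#' @export
crop_volume <- function(volume, body_mask, out_size) {
  assert_volume3d(volume)
  assert_same_dim(volume, body_mask, "volume and body mask")
  d <- dim(volume)
  out_size <- as.integer(out_size)
  if (any(out_size > d)) stop_kbp("out_size exceeds the input grid")
  if (sum(body_mask) == 0)
    stop_kbp("empty body mask: no crop center definable")
  idx <- which(body_mask == 1, arr.ind = TRUE)
  centroid <- round(colMeans(idx))
  start <- pmin(pmax(centroid - out_size %/% 2 + 1, 1), d - out_size + 1)
  volume[start[1]:(start[1] + out_size - 1),
         start[2]:(start[2] + out_size - 1),
         start[3]:(start[3] + out_size - 1), drop = FALSE]
}

#' Crop every volume of a plan sample around the body centroid
#'
#' @param sample A `plan_sample`.
#' @param out_size Output edge length.
#' @return The cropped `plan_sample`.
#' @export
crop_plan <- function(sample, out_size) {
  stopifnot(inherits(sample, "plan_sample"))
  body <- sample$masks$body
  sample$ct <- crop_volume(sample$ct, body, out_size)
  sample$dose <- crop_volume(sample$dose, body, out_size)
  sample$masks <- lapply(sample$masks, crop_volume, body_mask = body,
                         out_size = out_size)
  sample
}

#' Normalize CT intensities to `[0, 1]`
#'
#' Values are clipped to the nonnegative `[0, 4095]` CT-number range, then
#' divided by 4095. The map is idempotent on its own output. Inputs using a
#' signed Hounsfield convention must be offset upstream.
#'
#' @param ct Numeric array (any shape); must contain no NaN.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
normalize_ct <- function(ct) {
  if (anyNA(ct)) stop_kbp("CT volume contains NaN/NA values")
  # already on the normalized [0, 1] scale: leave untouched (idempotence)
  if (min(ct) >= 0 && max(ct) <= 1) return(ct)
  pmin(pmax(ct, 0), 4095) / 4095
}

#' Normalize a dose volume to the prescription
#'
#' @param dose Dose array in Gy.
#' @param prescription Prescription dose in Gy (> 0); 70 for these plans.
#' @return Dimensionless array `dose / prescription`.
#' @export
normalize_dose <- function(dose, prescription = 70) {
  if (prescription <= 0) stop_kbp("prescription must be positive")
  dose / prescription
}

#' Rescale a normalized dose prediction back to Gy
#'
#' Reverse of [normalize_dose()]: multiplies by the prescription (70 Gy for
#' these plans), recovering the physical dose scale before evaluation.
#'
#' @param pred Dimensionless dose array.
#' @param prescription Prescription dose in Gy (> 0).
#' @return Dose array in Gy.
#' @export
denormalize_dose <- function(pred, prescription = 70) {
  if (prescription <= 0) stop_kbp("prescription must be positive")
  pred * prescription
}

#' Zero-fill a missing structure mask
#'
#' A plan missing a secondary target or an OAR still needs a complete,
#' consistently ordered channel set; absent structures are represented by
#' all-zero masks. Idempotent if the structure is already present.
#'
#' @param masks Named list of binary masks.
#' @param name One of the eleven canonical structure names.
#' @param shape Grid dimensions for the zero mask.
#' @return The mask list, with `name` guaranteed present.
#' @export
fill_missing_structure <- function(masks, name, shape) {
  if (!name %in% CANONICAL_STRUCTURES)
    stop_kbp("unknown structure name: ", name)
  if (is.null(masks[[name]])) {
    masks[[name]] <- array(0, dim = shape)
  }
  masks
}

#' Assemble the 12-channel network input tensor
#'
#' Stacks the normalized CT and the eleven structure masks in the fixed
#' channel order: (1) CT, (2) PTV_70, (3) PTV_63, (4) PTV_56, (5) brainstem,
#' (6) left parotid, (7) right parotid, (8) spinal cord, (9) mandible,
#' (10) esophagus, (11) larynx, (12) body. Missing masks are zero-filled
#' first, so the order never depends on which structures a plan happens to
#' have, nor on the insertion order of the mask list.
#'
#' @param sample A `plan_sample` whose CT is already normalized to `[0, 1]`.
#' @return An `input_tensor`: an `n x 12` matrix (voxels by channels, voxels
#'   in column-major x/y/z order) with attributes `dims` and `channels`.
#' @export
assemble_input_tensor <- function(sample) {
  stopifnot(inherits(sample, "plan_sample"))
  d <- dim(sample$ct)
  if (min(sample$ct) < 0 || max(sample$ct) > 1)
    stop_kbp("CT channel must be normalized to [0, 1]; ",
             "call normalize_ct() first")
  masks <- sample$masks
  for (nm in CANONICAL_STRUCTURES) {
    masks <- fill_missing_structure(masks, nm, d)
    assert_same_dim(sample$ct, masks[[nm]], paste0("ct and mask ", nm))
    if (!is_binary_mask(masks[[nm]]))
      stop_kbp("mask ", nm, " is not binary")
  }
  channels <- c("CT", CANONICAL_STRUCTURES)
  x <- matrix(0, prod(d), length(channels))
  x[, 1] <- as.numeric(sample$ct)
  for (i in seq_along(CANONICAL_STRUCTURES)) {
    x[, i + 1] <- as.numeric(masks[[CANONICAL_STRUCTURES[i]]])
  }
  colnames(x) <- channels
  attr(x, "dims") <- d
  class(x) <- c("input_tensor", class(x))
  x
}

#' Prepare a plan sample for training or prediction
#'
#' Full preparation chain: crop all volumes to `out_size^3` around the body
#' centroid, normalize the CT, zero-fill missing structures, stack the
#' 12-channel input tensor, and normalize the ground-truth dose to the
#' prescription.
#'
#' @param sample A `plan_sample`.
#' @param out_size Cropped edge length (default 64).
#' @return List with elements `x` (the `input_tensor`), `y` (normalized dose
#'   vector in voxel order), `prescription`, and `sample` (the cropped plan).
#' @export
prepare_pair <- function(sample, out_size = 64) {
  cropped <- crop_plan(sample, out_size)
  cropped$ct <- normalize_ct(cropped$ct)
  x <- assemble_input_tensor(cropped)
  y <- as.numeric(normalize_dose(cropped$dose, cropped$prescription))
  list(x = x, y = y, prescription = cropped$prescription, sample = cropped)
}

#' Split plan identifiers into train/validation/test cohorts
#'
#' Identifiers are put in a canonical sorted order, shuffled with the given
#' seed, and partitioned. The test and validation sizes are rounded to the
#' nearest integer (ties to even, the R convention) and the training set
#' takes the remainder; with 340 plans and fractions 0.64/0.16/0.20 this
#' yields cohorts of 218/54/68.
#'
#' @param ids Character or integer identifiers (N >= 3, no duplicates).
#' @param fractions Train/validation/test fractions, positive, summing to 1.
#' @param seed Shuffle seed; the split is deterministic in `(ids, fractions,
#'   seed)` and invariant to the input order of `ids`.
#' @return A `cohort_split`: list with `train_ids`, `val_ids`, `test_ids`.
#' @export
split_cohort <- function(ids, fractions = c(0.64, 0.16, 0.20), seed = 1L) {
  n <- length(ids)
  if (n < 3) stop_kbp("need at least 3 identifiers to split")
  if (anyDuplicated(ids)) stop_kbp("duplicate identifiers")
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop_kbp("fractions must be three positive numbers summing to 1")
  ids <- sort(as.character(ids))
  set.seed(as.integer(seed))
  shuffled <- sample(ids)
  n_test <- round(fractions[3] * n)
  n_val <- round(fractions[2] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop_kbp("fractions leave an empty cohort for N = ", n)
  structure(list(train_ids = shuffled[seq_len(n_train)],
                 val_ids = shuffled[n_train + seq_len(n_val)],
                 test_ids = shuffled[n_train + n_val + seq_len(n_test)]),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("Cohort split: train", length(x$train_ids),
      "/ val", length(x$val_ids), "/ test", length(x$test_ids), "\n")
  invisible(x)
}
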