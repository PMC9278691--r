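#' Mean absolute dose error within a structure
#'
#' `(1/n) * sum |predicted_i - truth_i|` over the voxels of the structure
#' mask, in Gy. The global "body" figure uses the external body contour as
#' the mask.
#'
#' @param predicted,truth Dose arrays in Gy, same shape.
#' @param mask Binary structure mask, same shape, nonempty.
#' @return MAE in Gy.
#' @export
mae <- function(predicted, truth, mask) {
  assert_same_dim(predicted, truth, "predicted and truth")
  assert_same_dim(predicted, mask, "dose and mask")
  sel <- mask == 1
  if (!any(sel)) stop_kbp("empty structure mask")
  mean(abs(predicted[sel] - truth[sel]))
}

#' Voxelwise dose difference map
#'
#' Signed residual `predicted - truth` per voxel, in Gy; highlights hot and
#' cold spots of a predicted plan.
#'
#' @param predicted,truth Dose arrays in Gy, same shape.
#' @return Signed 3D array.
#' @export
difference_map <- function(predicted, truth) {
  assert_same_dim(predicted, truth, "predicted and truth")
  predicted - truth
}

#' Cumulative dose-volume histogram of a structure
#'
#' For each dose level d on a binned axis from 0 past the maximum dose, the
#' fraction of structure voxels receiving at least d. Starts at 1 for
#' nonempty structures with nonnegative dose, is monotonically nonincreasing,
#' and reaches 0 beyond the maximum dose.
#'
#' @param dose Dose array in Gy.
#' @param mask Binary structure mask, nonempty.
#' @param bin_width Dose-axis step in Gy (> 0).
#' @return A `dvh` data frame with columns `dose` and `volume_fraction`.
#' @export
dvh <- function(dose, mask, bin_width = 0.1) {
  assert_same_dim(dose, mask, "dose and mask")
  if (bin_width <= 0) stop_kbp("bin_width must be positive")
  sel <- mask == 1
  if (!any(sel)) stop_kbp("empty structure mask")
  doses <- dose[sel]
  top <- (floor(max(doses) / bin_width) + 1) * bin_width
  axis <- seq(0, top, by = bin_width)
  frac <- vapply(axis, function(d) mean(doses >= d), numeric(1))
  structure(data.frame(dose = axis, volume_fraction = frac),
            class = c("dvh", "data.frame"))
}

#' Dose received by at least q% of a structure
#'
#' D_q: the dose level such that q% of the structure's voxels receive at
#' least that dose. Computed as the (100 - q)th percentile of the within-mask
#' voxel doses with linear interpolation between order statistics; `q = 100`
#' gives the minimum voxel dose. D99 quantifies target coverage; D2% and
#' D98% enter the homogeneity index.
#'
#' @param dose Dose array in Gy.
#' @param mask Binary structure mask, nonempty.
#' @param q Volume percentage in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dose, mask, q) {
  assert_same_dim(dose, mask, "dose and mask")
  if (q <= 0 || q > 100) stop_kbp("q must lie in (0, 100]")
  sel <- mask == 1
  if (!any(sel)) stop_kbp("empty structure mask")
  stats::quantile(dose[sel], probs = (100 - q) / 100, type = 7, names = FALSE)
}

#' Maximum and mean structure dose
#'
#' @param dose Dose array in Gy.
#' @param mask Binary structure mask, nonempty.
#' @return Named numeric vector `c(dmax = , dmean = )` in Gy.
#' @export
dmax_dmean <- function(dose, mask) {
  assert_same_dim(dose, mask, "dose and mask")
  sel <- mask == 1
  if (!any(sel)) stop_kbp("empty structure mask")
  c(dmax = max(dose[sel]), dmean = mean(dose[sel]))
}

#' Homogeneity index of the primary target
#'
#' `HI = D2% - D98%` over the PTV_70 voxel doses: the spread between the
#' near-maximum and near-minimum target dose. Reported in Gy by default;
#' lower is more homogeneous. The relative variant divides by the
#' prescription and multiplies by 100.
#'
#' @param dose Dose array in Gy.
#' @param ptv70 Binary mask of the 70 Gy target, nonempty.
#' @param relative Report as percent of prescription instead of Gy.
#' @param prescription Prescription in Gy (used only when `relative`).
#' @return HI (Gy, or percent when `relative`).
#' @export
homogeneity_index <- function(dose, ptv70, relative = FALSE,
                              prescription = 70) {
  hi <- dose_at_volume(dose, ptv70, 2) - dose_at_volume(dose, ptv70, 98)
  if (relative) hi <- hi / prescription * 100
  hi
}

#' Conformity index of the primary target
#'
#' `CI = V_RI / TV`, where V_RI is the number of body voxels receiving at
#' least the reference dose and TV the number of target voxels. The default
#' reference dose is the full prescription (70 Gy).
#'
#' @param dose Dose array in Gy.
#' @param ptv70 Binary mask of the 70 Gy target, nonempty.
#' @param body Binary body mask.
#' @param reference_dose Reference isodose level in Gy (> 0).
#' @return Dimensionless CI (>= 0).
#' @export
conformity_index <- function(dose, ptv70, body, reference_dose = 70) {
  assert_same_dim(dose, ptv70, "dose and PTV mask")
  assert_same_dim(dose, body, "dose and body mask")
  if (reference_dose <= 0) stop_kbp("reference_dose must be positive")
  tv <- sum(ptv70 == 1)
  if (tv == 0) stop_kbp("empty PTV mask")
  v_ri <- sum(body == 1 & dose >= reference_dose)
  v_ri / tv
}

# Which dosimetric index applies to which structure (besides MAE, computed
# for every structure including the body).
structure_indices <- function(structure) {
  switch(structure,
         PTV_70 = c("D99", "HI", "CI"),
         PTV_63 = ,
         PTV_56 = "D99",
         brainstem = ,
         spinal_cord = ,
         mandible = "Dmax",
         left_parotid = ,
         right_parotid = ,
         esophagus = ,
         larynx = "Dmean",
         body = character(0),
         character(0))
}

compute_index <- function(index, dose, masks, reference_dose) {
  switch(index,
         D99 = dose_at_volume(dose, masks$current, 99),
         Dmax = unname(dmax_dmean(dose, masks$current)["dmax"]),
         Dmean = unname(dmax_dmean(dose, masks$current)["dmean"]),
         HI = homogeneity_index(dose, masks$current),
         CI = conformity_index(dose, masks$current, masks$body,
                               reference_dose))
}

#' Evaluate a cohort of predicted plans against ground truth
#'
#' Computes, per plan and structure, the MAE plus the applicable dosimetric
#' indices (D99 for the targets; Dmax for brainstem, spinal cord and
#' mandible; Dmean for the parotids, esophagus and larynx; HI and CI for
#' PTV_70), then aggregates over plans as mean and sample standard
#' deviation, with differences reported as predicted minus ground truth.
#' Structures absent (or empty) in a plan contribute nothing to that
#' structure's aggregate; a single-plan cohort reports SD 0 by convention.
#'
#' @param predicted List of predicted dose arrays in Gy.
#' @param samples List of ground-truth `plan_sample` objects (same length
#'   and order), providing the masks and true dose.
#' @param reference_dose Reference isodose for the CI (default: the plan
#'   prescription).
#' @return A `dose_metrics` object: list with `per_plan` (long data frame)
#'   and `summary` (one row per structure and index).
#' @export
evaluate_cohort <- function(predicted, samples, reference_dose = NULL) {
  if (length(predicted) == 0) stop_kbp("empty cohort")
  if (length(predicted) != length(samples))
    stop_kbp("predicted and ground-truth lists differ in length")
  rows <- list()
  for (i in seq_along(predicted)) {
    s <- samples[[i]]
    pred <- predicted[[i]]
    assert_same_dim(pred, s$dose, "predicted and ground-truth dose")
    ref <- reference_dose %||% s$prescription
    for (nm in intersect(CANONICAL_STRUCTURES, names(s$masks))) {
      m <- s$masks[[nm]]
      if (sum(m) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        plan = i, structure = nm, index = "MAE",
        predicted = mae(pred, s$dose, m), truth = 0,
        difference = mae(pred, s$dose, m))
      env <- list(current = m, body = s$masks$body)
      for (idx in structure_indices(nm)) {
        pv <- compute_index(idx, pred, env, ref)
        tv <- compute_index(idx, s$dose, env, ref)
        rows[[length(rows) + 1]] <- data.frame(
          plan = i, structure = nm, index = idx,
          predicted = pv, truth = tv, difference = pv - tv)
      }
    }
  }
  per_plan <- do.call(rbind, rows)
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  key <- interaction(per_plan$structure, per_plan$index, drop = TRUE)
  summ <- do.call(rbind, lapply(split(per_plan, key), function(d) {
    data.frame(structure = d$structure[1], index = d$index[1],
               predicted_mean = mean(d$predicted), predicted_sd = sd0(d$predicted),
               truth_mean = mean(d$truth), truth_sd = sd0(d$truth),
               difference_mean = mean(d$difference),
               difference_sd = sd0(d$difference),
               n_plans = nrow(d))
  }))
  ord <- order(match(summ$structure, CANONICAL_STRUCTURES),
               match(summ$index, c("MAE", "D99", "Dmax", "Dmean", "HI", "CI")))
  summ <- summ[ord, , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(per_plan = per_plan, summary = summ),
            class = "dose_metrics")
}

#' @export
print.dose_metrics <- function(x, digits = 3, ...) {
  cat("Cohort dosimetric evaluation (", max(x$per_plan$plan), " plans)\n",
      sep = "")
  df <- x$summary
  df$predicted <- sprintf("%.*f ± %.*f", digits, df$predicted_mean,
                          digits, df$predicted_sd)
  df$truth <- sprintf("%.*f ± %.*f", digits, df$truth_mean,
                      digits, df$truth_sd)
  df$difference <- sprintf("%.*f ± %.*f", digits, df$difference_mean,
                           digits, df$difference_sd)
  print(df[, c("structure", "index", "predicted", "truth", "difference")],
        row.names = FALSE)
  invisible(x)
}

#' Plot a DVH curve
#'
#' @param x A `dvh` from [dvh()].
#' @param add Overlay on an existing plot.
#' @param ... Passed to [graphics::lines()]/[graphics::plot()].
#' @export
plot.dvh <- function(x, add = FALSE, ...) {
  if (add) {
    graphics::lines(x$dose, 100 * x$volume_fraction, ...)
  } else {
    graphics::plot(x$dose, 100 * x$volume_fraction, type = "l",
                   xlab = "Dose (Gy)", ylab = "Volume (%)",
                   ylim = c(0, 100), ...)
  }
  invisible(x)
}
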