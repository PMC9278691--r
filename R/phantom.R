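#' Configuration for the synthetic head-and-neck phantom generator
#'
#' Defines the geometry and intensity model of the synthetic planning cases
#' used to exercise the full dose-prediction pipeline without clinical data.
#' Each case mimics a simultaneous-integrated-boost head-and-neck plan: up to
#' three disjoint spherical planning target volumes (PTVs) prescribed 70, 63
#' and 56 Gy, eight organ-at-risk (OAR) structures plus an external body
#' contour, a CT-like intensity volume on a nonnegative `[0, 4095]` scale, and
#' an analytic dose distribution that peaks at the prescription inside each
#' target and falls off smoothly with distance from the target surface.
#'
#' @param grid_size Voxels per axis of the cubic grid (default 64).
#' @param n_ptvs Number of targets in `[1, 3]`; the primary 70 Gy target is
#'   always present.
#' @param prescriptions Dose levels in Gy per target, strictly decreasing.
#' @param ptv_radii Sphere radius in voxels for each target (at `grid_size`
#'   64; radii scale linearly with grid size).
#' @param oar_names Names of the eight OAR structures.
#' @param falloff_sigma Gaussian dose-falloff scale in voxels (at grid 64).
#' @param noise_sd Standard deviation of the Gaussian CT intensity noise.
#' @param seed Default random seed used when none is supplied to
#'   [generate_phantom()].
#'
#' @return An object of class `phantom_config`.
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_config <- function(grid_size = 64L,
                           n_ptvs = 3L,
                           prescriptions = c(70, 63, 56),
                           ptv_radii = c(6, 5, 4),
                           oar_names = c("brainstem", "left_parotid",
                                         "right_parotid", "spinal_cord",
                                         "mandible", "esophagus", "larynx"),
                           falloff_sigma = 6,
                           noise_sd = 60,
                           seed = 1L) {
  grid_size <- as.integer(grid_size)
  n_ptvs <- as.integer(n_ptvs)
  if (grid_size < 16L) stop_kbp("grid_size must be >= 16")
  if (n_ptvs < 1L || n_ptvs > 3L) stop_kbp("n_ptvs must be in [1, 3]")
  if (length(prescriptions) < n_ptvs)
    stop_kbp("need a prescription for each target")
  if (any(diff(prescriptions) >= 0))
    stop_kbp("prescriptions must be strictly decreasing")
  if (length(ptv_radii) < n_ptvs) stop_kbp("need a radius for each target")
  if (falloff_sigma <= 0) stop_kbp("falloff_sigma must be positive")
  structure(list(grid_size = grid_size, n_ptvs = n_ptvs,
                 prescriptions = prescriptions, ptv_radii = ptv_radii,
                 oar_names = oar_names, falloff_sigma = falloff_sigma,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

# Voxel center coordinate grids for an N^3 grid, as three N^3 arrays.
coord_grids <- function(n) {
  ax <- seq_len(n)
  list(x = array(rep(ax, times = n * n), dim = c(n, n, n)),
       y = array(rep(rep(ax, each = n), times = n), dim = c(n, n, n)),
       z = array(rep(ax, each = n * n), dim = c(n, n, n)))
}

ellipsoid_mask <- function(g, center, semi) {
  m <- ((g$x - center[1]) / semi[1])^2 +
       ((g$y - center[2]) / semi[2])^2 +
       ((g$z - center[3]) / semi[3])^2 <= 1
  array(as.numeric(m), dim = dim(g$x))
}

sphere_mask <- function(g, center, radius) {
  ellipsoid_mask(g, center, rep(radius, 3))
}

# Vertical (z-axis) cylinder clipped to [z0, z1].
cylinder_mask <- function(g, center_xy, radius, z0, z1) {
  m <- ((g$x - center_xy[1])^2 + (g$y - center_xy[2])^2 <= radius^2) &
       g$z >= z0 & g$z <= z1
  array(as.numeric(m), dim = dim(g$x))
}

#' Generate one synthetic planning case
#'
#' Builds a complete plan sample: CT-like volume, binary structure masks
#' (targets, OARs and body) and an analytic dose distribution. Targets are
#' spheres, so the surface distance entering the dose falloff is exact:
#' for each target with prescription \eqn{P}, the per-target dose is
#' \eqn{P \exp(-d^2 / 2\sigma^2)} with \eqn{d = \max(0, \lVert v - c\rVert - r)},
#' and the plan dose is the voxelwise maximum over targets, clipped to
#' `[0, 1.1 * max(prescription)]`. Targets are placed with a minimum
#' center separation so their masks are pairwise disjoint; if a jittered
#' placement cannot be made disjoint after a bounded number of retries,
#' generation fails with a diagnostic.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed; identical `(config, seed)` give identical output.
#' @param active_targets Logical vector of length 3 selecting which of
#'   PTV_70/PTV_63/PTV_56 exist in this plan (the first must be `TRUE`);
#'   used by [generate_cohort()] to emulate plans with missing targets.
#'
#' @return An object of class `plan_sample`: a list with elements `ct`
#'   (3D array on the `[0, 4095]` scale), `masks` (named list of binary 3D
#'   arrays including `body`), `dose` (3D array in Gy) and `prescription`
#'   (70, the primary target level).
#' @export
generate_phantom <- function(config = phantom_config(), seed = config$seed,
                             active_targets = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$grid_size
  s <- n / 64
  if (is.null(active_targets)) {
    active_targets <- seq_len(3) <= config$n_ptvs
  }
  if (!active_targets[1]) stop_kbp("every plan must contain a PTV_70")
  set.seed(as.integer(seed))

  g <- coord_grids(n)
  c0 <- rep((n + 1) / 2, 3)
  body <- ellipsoid_mask(g, c0, c(0.42, 0.45, 0.47) * n)

  jit <- function(k = 3) stats::runif(k, -1.5, 1.5) * s

  # Target placement: nominal centers far enough apart that the spheres
  # cannot intersect; jitter retried if a draw violates the separation.
  radii <- config$ptv_radii * s
  nominal <- rbind(c0 + c(0, -6, 0) * s,
                   c0 + c(13, 0, -4) * s,
                   c0 + c(-13, 0, -5) * s)
  centers <- NULL
  for (try in seq_len(25)) {
    cand <- nominal + t(vapply(1:3, function(i) jit(), numeric(3)))
    ok <- TRUE
    act <- which(active_targets)
    if (length(act) > 1) {
      for (i in act) for (j in act) if (i < j) {
        margin <- max(0.75, 1.5 * s)
        if (sqrt(sum((cand[i, ] - cand[j, ])^2)) < radii[i] + radii[j] + margin)
          ok <- FALSE
      }
    }
    if (ok) { centers <- cand; break }
  }
  if (is.null(centers))
    stop_kbp("phantom generation failed: could not place disjoint PTVs ",
             "after 25 retries (radii too large for the grid?)")

  masks <- list()
  for (i in which(active_targets)) {
    masks[[PTV_NAMES[i]]] <- sphere_mask(g, centers[i, ], radii[i]) * body
  }
  # Disjointness safety net: subtract higher-priority targets from lower ones.
  act <- which(active_targets)
  if (length(act) > 1) {
    for (k in seq_along(act)[-1]) {
      lower <- PTV_NAMES[act[k]]
      for (j in seq_len(k - 1)) {
        higher <- PTV_NAMES[act[j]]
        masks[[lower]] <- masks[[lower]] * (1 - masks[[higher]])
      }
    }
  }

  # Canonical OAR geometry, jittered per seed, clipped to the body.
  oar <- list(
    brainstem    = cylinder_mask(g, c0[1:2] + c(0, 8) * s + jit(2), 3.5 * s,
                                 c0[3] + 6 * s, 0.88 * n),
    left_parotid = ellipsoid_mask(g, c0 + c(-16, 2, 2) * s + jit(),
                                  c(3.5, 4.5, 5) * s),
    right_parotid = ellipsoid_mask(g, c0 + c(16, 2, 2) * s + jit(),
                                   c(3.5, 4.5, 5) * s),
    spinal_cord  = cylinder_mask(g, c0[1:2] + c(0, 9) * s + jit(2), 2.5 * s,
                                 0.10 * n, c0[3] + 6 * s),
    mandible     = ellipsoid_mask(g, c0 + c(0, -13, -2) * s + jit(),
                                  c(9, 4, 3) * s),
    esophagus    = cylinder_mask(g, c0[1:2] + c(0, 6) * s + jit(2), 2 * s,
                                 0.06 * n, 0.35 * n),
    larynx       = ellipsoid_mask(g, c0 + c(0, -6, -14) * s + jit(),
                                  c(4, 3.5, 4) * s)
  )
  for (nm in config$oar_names) masks[[nm]] <- oar[[nm]] * body
  masks[["body"]] <- body

  # CT: air outside the body, soft tissue inside, bone in the mandible,
  # plus Gaussian noise, clipped to the nonnegative [0, 4095] scale.
  ct <- array(0, dim = c(n, n, n))
  ct[body == 1] <- 1000
  if (!is.null(masks$mandible)) ct[masks$mandible == 1] <- 2800
  ct <- ct + array(stats::rnorm(n^3, 0, config$noise_sd), dim = dim(ct)) *
    body
  ct <- pmin(pmax(ct, 0), 4095)

  # Analytic dose: per-target Gaussian falloff from the sphere surface,
  # superposed by voxelwise maximum.
  sigma <- config$falloff_sigma * s
  dose <- array(0, dim = c(n, n, n))
  for (i in which(active_targets)) {
    d <- sqrt((g$x - centers[i, 1])^2 + (g$y - centers[i, 2])^2 +
              (g$z - centers[i, 3])^2) - radii[i]
    d[d < 0] <- 0
    dose <- pmax(dose, config$prescriptions[i] * exp(-d^2 / (2 * sigma^2)))
  }
  dose <- pmin(dose, 1.1 * config$prescriptions[1])

  structure(list(ct = ct, masks = masks, dose = dose,
                 prescription = config$prescriptions[1]),
            class = "plan_sample")
}

#' Validate the structural invariants of a plan sample
#'
#' Checks that all volumes share one shape, masks are binary, the dose is
#' nonnegative, PTV masks are pairwise disjoint, and every non-body mask is a
#' subset of the body.
#'
#' @param sample A `plan_sample`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_plan_sample <- function(sample) {
  stopifnot(inherits(sample, "plan_sample"))
  d <- dim(sample$ct)
  assert_volume3d(sample$ct, "ct")
  assert_same_dim(sample$ct, sample$dose, "ct and dose")
  for (nm in names(sample$masks)) {
    m <- sample$masks[[nm]]
    assert_same_dim(sample$ct, m, paste0("ct and mask ", nm))
    if (!is_binary_mask(m)) stop_kbp("mask ", nm, " is not binary")
  }
  if (any(sample$dose < 0)) stop_kbp("dose has negative voxels")
  ptvs <- intersect(PTV_NAMES, names(sample$masks))
  if (length(ptvs) > 1) {
    for (i in seq_along(ptvs)[-1]) for (j in seq_len(i - 1)) {
      if (any(sample$masks[[ptvs[i]]] * sample$masks[[ptvs[j]]] > 0))
        stop_kbp("PTV masks ", ptvs[i], " and ", ptvs[j], " overlap")
    }
  }
  body <- sample$masks$body
  if (is.null(body)) stop_kbp("missing body mask")
  for (nm in setdiff(names(sample$masks), "body")) {
    if (any(sample$masks[[nm]] > body))
      stop_kbp("mask ", nm, " extends outside the body")
  }
  invisible(TRUE)
}

#' Generate a cohort of synthetic planning cases
#'
#' Seeds for the individual cases are derived deterministically from the
#' master seed. Optionally drops the secondary targets (PTV_63, PTV_56) in a
#' random fraction of plans to emulate the missing-structure pattern of real
#' cohorts, where only the primary target is guaranteed.
#'
#' @param config A [phantom_config()].
#' @param n Number of plans (>= 1).
#' @param seed Master seed.
#' @param missing_fraction Probability that each secondary target is absent
#'   from a plan. Either a single number applied to both, or a named vector
#'   with entries `PTV_63` and/or `PTV_56`.
#' @return A list of `plan_sample` objects.
#' @export
generate_cohort <- function(config = phantom_config(), n, seed = config$seed,
                            missing_fraction = 0.3) {
  if (n < 1) stop_kbp("n must be >= 1")
  mf <- c(PTV_63 = 0, PTV_56 = 0)
  if (is.null(names(missing_fraction))) {
    mf[] <- missing_fraction[1]
  } else {
    mf[names(missing_fraction)] <- missing_fraction
  }
  if (any(mf < 0 | mf > 1)) stop_kbp("missing_fraction must be in [0, 1]")
  set.seed(as.integer(seed))
  drop63 <- stats::runif(n) < mf["PTV_63"]
  drop56 <- stats::runif(n) < mf["PTV_56"]
  lapply(seq_len(n), function(i) {
    act <- c(TRUE,
             config$n_ptvs >= 2 && !drop63[i],
             config$n_ptvs >= 3 && !drop56[i])
    generate_phantom(config, seed = derive_seed(seed, i),
                     active_targets = act)
  })
}

#' @export
print.plan_sample <- function(x, ...) {
  d <- dim(x$ct)
  cat("Synthetic/loaded plan sample\n")
  cat("  grid:", paste(d, collapse = " x "), "voxels\n")
  cat("  prescription:", x$prescription, "Gy\n")
  cat("  structures:", paste(names(x$masks), collapse = ", "), "\n")
  cat("  dose range: [", round(min(x$dose), 2), ",",
      round(max(x$dose), 2), "] Gy\n")
  invisible(x)
}
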