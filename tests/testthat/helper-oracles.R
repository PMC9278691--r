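# Brute-force oracles and tiny fixtures shared across the test files.
# Oracles deliberately use naive loops / explicit order-statistic formulas,
# independent of the package's implementation paths.

# naive MAE over a mask
oracle_mae <- function(pred, truth, mask) {
  tot <- 0; k <- 0
  for (i in seq_along(mask)) {
    if (mask[i] == 1) { tot <- tot + abs(pred[i] - truth[i]); k <- k + 1 }
  }
  tot / k
}

# naive max / mean over a mask
oracle_dmax_dmean <- function(dose, mask) {
  vals <- c()
  for (i in seq_along(mask)) if (mask[i] == 1) vals <- c(vals, dose[i])
  c(dmax = max(vals), dmean = sum(vals) / length(vals))
}

# (100 - q)th percentile with linear interpolation between order statistics
# (explicit formula, independent of stats::quantile)
oracle_dq <- function(dose, mask, q) {
  vals <- sort(dose[mask == 1])
  n <- length(vals)
  p <- (100 - q) / 100
  h <- (n - 1) * p + 1
  fl <- floor(h)
  if (fl >= n) return(vals[n])
  vals[fl] + (h - fl) * (vals[fl + 1] - vals[fl])
}

# cumulative DVH fraction at one dose level by counting
oracle_dvh_fraction <- function(dose, mask, level) {
  vals <- dose[mask == 1]
  sum(vals >= level) / length(vals)
}

# reference-isodose conformity by counting
oracle_ci <- function(dose, ptv, body, ref) {
  v <- 0
  for (i in seq_along(dose)) if (body[i] == 1 && dose[i] >= ref) v <- v + 1
  v / sum(ptv == 1)
}

# dense volume from sparse records by a plain scatter loop (row-major)
oracle_scatter <- function(idx, val, shape) {
  vol <- array(0, dim = shape)
  for (r in seq_along(idx)) {
    i <- idx[r]
    x3 <- i %% shape[3]
    x2 <- (i %/% shape[3]) %% shape[2]
    x1 <- i %/% (shape[2] * shape[3])
    vol[x1 + 1, x2 + 1, x3 + 1] <- val[r]
  }
  vol
}

# random small structure on a random small grid
random_structure <- function(min_dim = 4, max_dim = 7) {
  d <- sample(min_dim:max_dim, 3, replace = TRUE)
  dose <- array(runif(prod(d), 0, 80), dim = d)
  mask <- array(0, dim = d)
  k <- sample(2:prod(d), 1)
  mask[sample(prod(d), k)] <- 1
  list(dose = dose, mask = mask, dims = d)
}

# hand-built minimal plan sample on a tiny grid with fully known dose
make_tiny_plan <- function(dose_in = 70, dose_out = 10, n = 4) {
  body <- array(1, dim = c(n, n, n))
  ptv <- array(0, dim = c(n, n, n))
  ptv[2:3, 2:3, 2:3] <- 1
  dose <- array(dose_out, dim = c(n, n, n))
  dose[ptv == 1] <- dose_in
  masks <- list(PTV_70 = ptv, body = body)
  structure(list(ct = array(0.5, dim = c(n, n, n)), masks = masks,
                 dose = dose, prescription = 70),
            class = "plan_sample")
}

# small phantom cohorts used by several files
tiny_phantom_config <- function(grid = 32, ...) {
  phantom_config(grid_size = grid, ...)
}
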