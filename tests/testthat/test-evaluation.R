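test_that("structure MAE matches naive loops and is symmetric", {
  set.seed(21)
  for (rep in 1:10) {
    st <- random_structure()
    pred <- array(runif(prod(st$dims), 0, 80), dim = st$dims)
    expect_equal(mae(pred, st$dose, st$mask),
                 oracle_mae(pred, st$dose, st$mask), tolerance = 1e-12)
    expect_equal(mae(pred, st$dose, st$mask), mae(st$dose, pred, st$mask))
  }
  a <- array(runif(27, 0, 70), dim = c(3, 3, 3))
  m <- array(1, dim = c(3, 3, 3))
  expect_equal(mae(a, a, m), 0)
  expect_equal(mae(a + 2, a, m), 2)
  expect_error(mae(a, a, array(0, dim = c(3, 3, 3))), "empty")
})

test_that("difference maps are signed residuals, antisymmetric, tied to MAE", {
  a <- array(runif(4^3, 0, 70), dim = c(4, 4, 4))
  b <- array(runif(4^3, 0, 70), dim = c(4, 4, 4))
  expect_equal(difference_map(a, a), array(0, dim = dim(a)))
  expect_equal(difference_map(a + 3, a), array(3, dim = dim(a)))
  expect_equal(difference_map(a, b), -difference_map(b, a))
  m <- array(rbinom(4^3, 1, 0.5), dim = c(4, 4, 4))
  if (sum(m) > 0)
    expect_equal(mean(abs(difference_map(a, b))[m == 1]), mae(a, b, m))
  expect_error(difference_map(a, array(0, dim = c(4, 4, 2))), "mismatch")
})

test_that("DVH curves are correct cumulative volume fractions", {
  m <- array(1, dim = c(5, 5, 4))
  uniform <- array(70, dim = dim(m))
  curve <- dvh(uniform, m, bin_width = 1)
  expect_equal(curve$volume_fraction[curve$dose <= 70], rep(1, 71))
  expect_equal(curve$volume_fraction[curve$dose > 70], 0)
  expect_equal(curve$volume_fraction[1], 1)

  doses <- array(as.numeric(1:100), dim = c(100, 1, 1))
  mk <- array(1, dim = c(100, 1, 1))
  cv <- dvh(doses, mk, bin_width = 0.1)
  expect_equal(cv$volume_fraction[abs(cv$dose - 50.5) < 1e-9], 0.50)
  expect_true(all(diff(cv$volume_fraction) <= 0))
  expect_equal(cv$volume_fraction[nrow(cv)], 0)
  expect_error(dvh(doses, mk, bin_width = 0), "positive")
})

test_that("dose-at-volume follows the interpolated order-statistic rule", {
  m4 <- array(1, dim = c(4, 1, 1))
  d4 <- array(c(10, 20, 30, 40), dim = c(4, 1, 1))
  expect_equal(dose_at_volume(d4, m4, 50), 25)
  expect_equal(dose_at_volume(d4, m4, 100), 10)
  u <- array(70, dim = c(3, 3, 3)); mu <- array(1, dim = c(3, 3, 3))
  expect_equal(dose_at_volume(u, mu, 99), 70)
  expect_equal(dose_at_volume(u, mu, 2), 70)
  # monotone: larger coverage requirement -> lower dose
  set.seed(3)
  st <- random_structure()
  qs <- c(2, 50, 98, 99, 100)
  dq <- vapply(qs, function(q) dose_at_volume(st$dose, st$mask, q), numeric(1))
  expect_true(all(diff(dq) <= 1e-12))
  expect_error(dose_at_volume(st$dose, st$mask, 0), "0, 100")
  expect_error(dose_at_volume(st$dose, st$mask, 101), "0, 100")
})

test_that("Dmax/Dmean and HI behave on closed-form cases", {
  u <- array(70, dim = c(3, 3, 3)); m <- array(1, dim = c(3, 3, 3))
  expect_equal(dmax_dmean(u, m), c(dmax = 70, dmean = 70))
  d2 <- array(c(0, 70), dim = c(2, 1, 1)); m2 <- array(1, dim = c(2, 1, 1))
  expect_equal(dmax_dmean(d2, m2), c(dmax = 70, dmean = 35))
  expect_equal(homogeneity_index(u, m), 0)
  # linear ramp: HI equals the oracle's D2% - D98%
  ramp <- array(seq(60, 80, length.out = 50), dim = c(50, 1, 1))
  mr <- array(1, dim = c(50, 1, 1))
  expect_equal(homogeneity_index(ramp, mr),
               oracle_dq(ramp, mr, 2) - oracle_dq(ramp, mr, 98),
               tolerance = 1e-9)
  expect_equal(homogeneity_index(ramp, mr, relative = TRUE),
               homogeneity_index(ramp, mr) / 70 * 100)
  expect_gte(homogeneity_index(ramp, mr), 0)
})

test_that("conformity index counts the reference isodose volume", {
  n <- 8
  body <- array(1, dim = c(n, n, n))
  ptv <- array(0, dim = c(n, n, n)); ptv[3:6, 3:6, 3:6] <- 1
  dose <- array(0, dim = c(n, n, n)); dose[ptv == 1] <- 70
  expect_equal(conformity_index(dose, ptv, body, 70), 1)
  expect_equal(conformity_index(dose * 0.9, ptv, body, 70), 0)
  # spilling dose outside the target raises CI above 1
  dose2 <- array(70, dim = c(n, n, n))
  expect_equal(conformity_index(dose2, ptv, body, 70),
               sum(body) / sum(ptv))
  set.seed(14)
  st <- random_structure()
  body2 <- array(1, dim = st$dims)
  expect_equal(conformity_index(st$dose, st$mask, body2, 40),
               oracle_ci(st$dose, st$mask, body2, 40), tolerance = 1e-12)
  expect_error(conformity_index(dose, ptv * 0, body, 70), "empty")
})

test_that("phantom PTV_70 coverage matches the analytic dose model", {
  # inside the target the analytic dose equals the prescription exactly,
  # so the DVH fraction just below 70 Gy must be 1 (within 2%)
  s <- generate_phantom(tiny_phantom_config(32), seed = 8)
  frac <- oracle_dvh_fraction(s$dose, s$masks$PTV_70, 69.9)
  expect_equal(frac, 1, tolerance = 0.02)
  cv <- dvh(s$dose, s$masks$PTV_70, bin_width = 0.5)
  expect_equal(cv$volume_fraction[which(cv$dose <= 69.5)][1], 1,
               tolerance = 0.02)
})

test_that("cohort evaluation aggregates per-plan indices correctly", {
  # identical predictions: zero MAE, zero index differences
  cohort <- generate_cohort(tiny_phantom_config(32), 2, seed = 12,
                            missing_fraction = 0)
  rep0 <- evaluate_cohort(lapply(cohort, `[[`, "dose"), cohort)
  expect_true(all(rep0$summary$difference_mean == 0))
  expect_true(all(rep0$summary$predicted_mean[rep0$summary$index == "MAE"] == 0))

  # single plan: SD reported as 0 by convention
  rep1 <- evaluate_cohort(list(cohort[[1]]$dose * 0.95), cohort[1])
  expect_true(all(rep1$summary$predicted_sd == 0))
  expect_equal(unique(rep1$summary$n_plans), 1)

  # two hand-computable plans
  p1 <- make_tiny_plan(dose_in = 70, dose_out = 10)
  p2 <- make_tiny_plan(dose_in = 60, dose_out = 20)
  preds <- list(p1$dose + 1, p2$dose - 2)
  rep2 <- evaluate_cohort(preds, list(p1, p2))
  maes <- rep2$summary[rep2$summary$structure == "body" &
                         rep2$summary$index == "MAE", ]
  expect_equal(maes$predicted_mean, mean(c(1, 2)))
  expect_equal(maes$predicted_sd, stats::sd(c(1, 2)))
  d99 <- rep2$summary[rep2$summary$structure == "PTV_70" &
                        rep2$summary$index == "D99", ]
  expect_equal(d99$predicted_mean, mean(c(71, 58)))
  expect_equal(d99$truth_mean, mean(c(70, 60)))
  expect_equal(d99$difference_mean, mean(c(1, -2)))

  # plans missing a structure are skipped in that structure's aggregate
  p3 <- p1; p3$masks$PTV_70 <- NULL
  rep3 <- evaluate_cohort(list(p1$dose, p3$dose), list(p1, p3))
  expect_equal(rep3$summary$n_plans[rep3$summary$structure == "PTV_70"][1], 1)
  expect_error(evaluate_cohort(list(), list()), "empty")
})
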