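test_that("cropping centers on the body centroid and clamps at edges", {
  n <- 64
  vol <- array(seq_len(n^3), dim = c(n, n, n))
  # symmetric body: centroid at the grid center -> central block
  body <- array(0, dim = c(n, n, n)); body[17:48, 17:48, 17:48] <- 1
  expect_identical(crop_volume(vol, body, 32), vol[17:48, 17:48, 17:48])
  # centroid shifted +10 along x -> window shifted by 10, still in bounds
  body2 <- array(0, dim = c(n, n, n)); body2[27:58, 17:48, 17:48] <- 1
  expect_identical(crop_volume(vol, body2, 32), vol[27:58, 17:48, 17:48])
  # centroid near the face -> clamped
  body3 <- array(0, dim = c(n, n, n)); body3[1:8, 1:8, 1:8] <- 1
  expect_identical(crop_volume(vol, body3, 32), vol[1:32, 1:32, 1:32])
  # out_size equal to the grid -> identity
  expect_identical(crop_volume(vol, body, n), vol)
  expect_error(crop_volume(vol, array(0, dim = dim(vol)), 32), "empty body")
  expect_error(crop_volume(vol, body, 128), "exceeds")
})

test_that("CT normalization clips to [0, 4095] and is idempotent", {
  expect_equal(normalize_ct(4095), 1)
  expect_equal(normalize_ct(5000), 1)
  expect_equal(normalize_ct(0), 0)
  expect_equal(normalize_ct(-250), 0)
  expect_equal(normalize_ct(Inf), 1)
  x <- array(runif(4^3, -500, 6000), dim = c(4, 4, 4))
  y <- normalize_ct(x)
  expect_true(all(y >= 0 & y <= 1))
  expect_equal(normalize_ct(y), y)
  expect_equal(y[x > 0 & x < 4095], x[x > 0 & x < 4095] / 4095)
  expect_error(normalize_ct(c(1, NaN)), "NaN")
})

test_that("dose normalization and denormalization are exact inverses", {
  expect_equal(normalize_dose(70, 70), 1)
  expect_equal(normalize_dose(35, 70), 0.5)
  expect_equal(denormalize_dose(1, 70), 70)
  expect_equal(denormalize_dose(0, 70), 0)
  d <- array(runif(5^3, 0, 77), dim = c(5, 5, 5))
  expect_identical(denormalize_dose(normalize_dose(d, 70), 70), d)
  expect_error(normalize_dose(d, 0), "positive")
  expect_error(denormalize_dose(d, -1), "positive")
})

test_that("missing structures are zero-filled idempotently", {
  masks <- list(PTV_70 = array(1, dim = c(4, 4, 4)))
  out <- fill_missing_structure(masks, "PTV_63", c(4, 4, 4))
  expect_true("PTV_63" %in% names(out))
  expect_equal(sum(out$PTV_63), 0)
  expect_identical(fill_missing_structure(out, "PTV_63", c(4, 4, 4)), out)
  expect_identical(fill_missing_structure(masks, "PTV_70", c(4, 4, 4)), masks)
  expect_error(fill_missing_structure(masks, "PTV_50", c(4, 4, 4)), "unknown")
})

test_that("input tensors stack twelve channels in the fixed order", {
  s <- generate_phantom(tiny_phantom_config(32), seed = 6)
  s$ct <- normalize_ct(s$ct)
  x <- assemble_input_tensor(s)
  expect_equal(ncol(x), 12)
  expect_identical(colnames(x),
                   c("CT", "PTV_70", "PTV_63", "PTV_56", "brainstem",
                     "left_parotid", "right_parotid", "spinal_cord",
                     "mandible", "esophagus", "larynx", "body"))
  expect_true(all(x[, 1] >= 0 & x[, 1] <= 1))
  expect_true(all(x[, -1] %in% c(0, 1)))
  expect_equal(x[, 2], as.numeric(s$masks$PTV_70))
  expect_equal(x[, 12], as.numeric(s$masks$body))

  # plan missing PTV_56 -> channel 4 is the zero fill
  s2 <- s
  s2$masks$PTV_56 <- NULL
  x2 <- assemble_input_tensor(s2)
  expect_equal(sum(x2[, 4]), 0)

  # mask insertion order never affects the tensor
  s3 <- s
  s3$masks <- rev(s$masks)
  expect_equal(assemble_input_tensor(s3), x)

  # contract violations
  s4 <- s
  s4$masks$larynx <- array(0, dim = c(16, 16, 16))
  expect_error(assemble_input_tensor(s4), "shape mismatch")
  s5 <- generate_phantom(tiny_phantom_config(32), seed = 6)
  expect_error(assemble_input_tensor(s5), "normalized")
})

test_that("cohort splitting reproduces the published 340-plan arithmetic", {
  ids <- sprintf("pt%03d", 1:340)
  sp <- split_cohort(ids, c(0.64, 0.16, 0.20), seed = 1)
  expect_length(sp$train_ids, 218)
  expect_length(sp$val_ids, 54)
  expect_length(sp$test_ids, 68)
  sp10 <- split_cohort(sprintf("p%02d", 1:10), c(0.64, 0.16, 0.20), seed = 1)
  expect_equal(vapply(sp10, length, integer(1)),
               c(train_ids = 6L, val_ids = 2L, test_ids = 2L))
})

test_that("cohort splits are disjoint partitions, deterministic and order-invariant", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    ids <- sprintf("id%03d", sample(1000, n))
    fr <- c(0.5, 0.25, 0.25)
    sp <- split_cohort(ids, fr, seed = rep)
    expect_equal(sort(c(sp$train_ids, sp$val_ids, sp$test_ids)), sort(ids))
    expect_length(intersect(sp$train_ids, sp$val_ids), 0)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    expect_length(intersect(sp$val_ids, sp$test_ids), 0)
    expect_identical(split_cohort(ids, fr, seed = rep), sp)
    expect_identical(split_cohort(rev(ids), fr, seed = rep), sp)
  }
  expect_error(split_cohort(c("a", "b"), seed = 1), "at least 3")
  expect_error(split_cohort(letters[1:5], c(0.5, 0.5, 0.5), seed = 1),
               "summing to 1")
})
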