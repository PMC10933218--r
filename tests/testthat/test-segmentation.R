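test_that("threshold_fat marks exactly the voxels inside the window", {
  win <- fat_window(-190, -30)
  v <- ct_volume(array(c(-100, -29, -190, -30, -191, 40), c(6, 1, 1)),
                 c(1, 1, 1))
  m <- threshold_fat(v, win)
  expect_equal(as.vector(m$data), c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))

  set.seed(7)
  arr <- array(runif(20^3, -1100, 200), c(20, 20, 20))
  mask <- threshold_fat(ct_volume(arr, c(1, 1, 1)), win)
  # brute-force per-voxel oracle
  expect_equal(sum(mask$data), sum(arr >= -190 & arr <= -30))
  expect_identical(mask$data, arr >= -190 & arr <= -30)
  # re-application on the same volume is unchanged
  expect_identical(threshold_fat(ct_volume(arr, c(1, 1, 1)), win)$data,
                   mask$data)
})

test_that("non-HU-scaled input triggers a warning", {
  v <- ct_volume(array(5000, c(3, 3, 3)), c(1, 1, 1))
  expect_warning(threshold_fat(v), "HU-scaled")
})

test_that("body_mask recovers the elliptical body and contains all fat", {
  spec <- small_phantom_spec(noise_sd = 0, seed = 8)
  ph <- generate_phantom(spec)
  body <- body_mask(ph$volume)
  # analytic ellipse area oracle, mid-volume slice
  mid <- dim(body$data)[3] %/% 2
  area_mm2 <- sum(body$data[, , mid]) * prod(spec$voxel_spacing[1:2])
  analytic <- pi * spec$body_radius[1] * spec$body_radius[2]
  expect_lt(abs(area_mm2 - analytic) / analytic, 0.02)
  expect_true(all(body$data[ph$masks$sat$data]))
  expect_true(all(body$data[ph$masks$vat$data]))
})

test_that("an all-air volume has no body", {
  v <- ct_volume(array(-1000, c(10, 10, 5)), c(1, 1, 1))
  expect_error(body_mask(v), "entirely air")
})

test_that("compartment separation partitions fat into VAT and SAT", {
  ph <- generate_phantom(small_phantom_spec(concentration = 0.6, seed = 9))
  seg <- segment_vat(ph$volume)
  fat <- seg$fat$data
  expect_true(all((seg$vat$data | seg$sat$data) == fat))   # union
  expect_false(any(seg$vat$data & seg$sat$data))           # disjoint
  expect_gte(overlap_scores(seg$vat, ph$masks$vat)$dice, 0.95)
  expect_gte(overlap_scores(seg$sat, ph$masks$sat)$dice, 0.95)
})

test_that("empty fat gives empty compartments; fat outside body errors", {
  d <- c(8, 8, 4)
  body <- label_mask(array(TRUE, d))
  empty <- label_mask(array(FALSE, d))
  out <- separate_compartments(empty, body)
  expect_equal(sum(out$vat$data), 0)
  expect_equal(sum(out$sat$data), 0)
  stray <- array(FALSE, d); stray[1, 1, 1] <- TRUE
  expect_error(separate_compartments(label_mask(stray),
                                     label_mask(array(FALSE, d))),
               "not contained")
})

test_that("overlap scores follow the set formulas and dice = 2j/(1+j)", {
  d <- c(10, 10, 10)
  a <- random_mask(d, 0.4, seed = 1)
  expect_equal(overlap_scores(a, a), list(dice = 1, jaccard = 1),
               ignore_attr = TRUE)
  b <- label_mask(!a$data)
  expect_equal(overlap_scores(a, b), list(dice = 0, jaccard = 0),
               ignore_attr = TRUE)
  # |a| = |b| = 100, |a ∩ b| = 50 by construction
  x <- array(FALSE, c(20, 20, 1)); y <- array(FALSE, c(20, 20, 1))
  x[1:100] <- TRUE; y[51:150] <- TRUE
  ov <- overlap_scores(label_mask(x, c(1, 1, 1)), label_mask(y, c(1, 1, 1)))
  expect_equal(ov$dice, 0.5)
  expect_equal(ov$jaccard, 1 / 3)
  # both-empty convention and shape mismatch
  e <- label_mask(array(FALSE, d))
  expect_equal(overlap_scores(e, e)$dice, 1)
  expect_equal(overlap_scores(e, a)$dice, 0)
  expect_error(overlap_scores(a, label_mask(array(TRUE, c(5, 5, 5)))),
               "mismatch")
  # identity dice = 2j/(1+j) over random pairs
  for (s in 1:5) {
    m1 <- random_mask(d, 0.3, seed = s)
    m2 <- random_mask(d, 0.3, seed = s + 100)
    ov <- overlap_scores(m1, m2)
    expect_equal(ov$dice, 2 * ov$jaccard / (1 + ov$jaccard))
    expect_lte(ov$jaccard, ov$dice)
  }
})

test_that("pipeline recovers the ground-truth VAT mask", {
  clean <- generate_phantom(small_phantom_spec(concentration = 0.5,
                                               noise_sd = 0, seed = 10))
  seg <- segment_vat(clean$volume)
  expect_gte(overlap_scores(seg$vat, clean$masks$vat)$dice, 0.99)

  noisy <- generate_phantom(small_phantom_spec(concentration = 0.5,
                                               noise_sd = 10, seed = 10))
  seg_n <- segment_vat(noisy$volume)
  expect_gte(overlap_scores(seg_n$vat, noisy$masks$vat)$dice, 0.95)
  # predicted vs ground-truth lumbar CV agree within 3 CV points
  cv_pred <- subject_metrics(seg_n$vat, noisy$landmarks)$lumbar_cv
  cv_true <- subject_metrics(noisy$masks$vat, noisy$landmarks)$lumbar_cv
  expect_lt(abs(cv_pred - cv_true), 3)
})
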