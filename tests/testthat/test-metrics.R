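test_that("vfa converts pixel counts to cm^2", {
  m <- matrix(FALSE, 20, 20); m[1:100] <- TRUE
  expect_equal(vfa(m, pixel_area_mm2 = 1), 1)
  expect_equal(vfa(matrix(FALSE, 5, 5)), 0)
  set.seed(3)
  r <- matrix(runif(400) < 0.4, 20, 20)
  expect_equal(vfa(r, 4), sum(r) * 4 / 100)  # brute-force pixel count
})

test_that("vat_volume is the voxel count times voxel volume", {
  m <- array(TRUE, c(10, 10, 10))
  expect_equal(vat_volume(m, 1), 1)          # 1000 voxels at 1 mm^3
  expect_equal(vat_volume(array(FALSE, c(5, 5, 5)), 10), 0)
  # tiling identity: sum over slices of vfa x thickness equals the volume
  msk <- random_mask(c(15, 12, 9), 0.35, seed = 5, spacing = c(1.5, 2, 4))
  vfas <- slice_vfas(msk)
  expect_equal(sum(vfas * msk$spacing[3] / 10), vat_volume(msk))
})

test_that("vai follows the standardization formula", {
  expect_equal(vai(50, 0.2), 1250)
  expect_equal(vai(0, 0.2), 0)
  expect_equal(vai(50, 0.4), 1250 / 4)  # doubling height quarters VAI
  expect_error(vai(50, 0), "> 0")
})

test_that("vat_ratio is the slice share of total volume in percent", {
  expect_equal(vat_ratio(30, 3, 900), 1.0)
  # a single slice containing all the fat
  expect_equal(vat_ratio(100, 10, 100), 100)
  # N identical slices tiling the mask -> 100/N each
  expect_equal(vat_ratio(10, 5, 10 * 0.5 * 8), rep(100 / 8, 1))
  expect_error(vat_ratio(10, 3, 0), "> 0")
  # full tiling sums to exactly 100%
  msk <- random_mask(c(15, 12, 9), 0.35, seed = 6, spacing = c(1, 1, 3))
  vfas <- slice_vfas(msk)
  ratios <- vat_ratio(vfas, 3, vat_volume(msk))
  expect_equal(sum(ratios), 100, tolerance = 1e-9)
})

test_that("distribution_stats gives mean, sample SD, and CV in percent", {
  s <- distribution_stats(c(5, 5, 5, 5))
  expect_equal(s$sd, 0)
  expect_equal(s$cv, 0)
  s2 <- distribution_stats(c(1, 3))
  expect_equal(s2$mean, 2)
  expect_equal(s2$sd, sqrt(2))          # n-1 denominator
  expect_equal(s2$cv, 70.71068, tolerance = 1e-6)
  # CV is scale invariant
  x <- c(2, 7, 4, 9, 5)
  expect_equal(distribution_stats(x * 3.7)$cv, distribution_stats(x)$cv)
  expect_error(distribution_stats(5), "at least 2")
  expect_warning(distribution_stats(c(0, 0, 0)), "undefined")
})

test_that("inter-subject CV matches distribution_stats and is symmetric", {
  expect_equal(inter_subject_cv(c(10, 10, 10)), 0)
  expect_equal(inter_subject_cv(c(10, 30)), 70.71068, tolerance = 1e-6)
  x <- c(12, 55, 31, 8, 40)
  expect_equal(inter_subject_cv(x), inter_subject_cv(rev(x)))
})

test_that("level-volume correlation matches the textbook formula", {
  vols <- c(900, 1500, 1200, 2100, 1800)
  expect_equal(level_volume_correlation(0.04 * vols, vols), 1)
  expect_equal(level_volume_correlation(100 - 0.04 * vols, vols), -1)
  vfas <- c(35, 62, 44, 88, 70)
  r_hand <- sum((vfas - mean(vfas)) * (vols - mean(vols))) /
    sqrt(sum((vfas - mean(vfas))^2) * sum((vols - mean(vols))^2))
  expect_equal(level_volume_correlation(vfas, vols), r_hand)
  expect_equal(level_volume_correlation(vfas, vols, "spearman"),
               cor(rank(vfas), rank(vols)))
  expect_error(level_volume_correlation(c(1, 1, 1), vols[1:3]),
               "zero variance")
})

test_that("subject_metrics ties the indicator set together coherently", {
  ph <- generate_phantom(small_phantom_spec(concentration = 0.7, seed = 12))
  sm <- subject_metrics(ph$masks$vat, ph$landmarks)
  expect_equal(nrow(sm$slices), 35)
  expect_equal(sum(sm$slices$lumbar), 25)
  expect_equal(sm$lumbar_cv, sm$lumbar_sd / sm$lumbar_mean * 100)
  expect_equal(sm$lumbar_height, 0.17)
  expect_equal(sm$slices$vai, sm$slices$vfa / 0.17^2)
  # caudal concentration: pelvic representative slices carry more fat
  expect_gt(mean(sm$slices$vfa[!sm$slices$lumbar]),
            mean(sm$slices$vfa[sm$slices$lumbar]))
})
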