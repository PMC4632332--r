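test_that("TSA is the dice coefficient in percent", {
  a <- matrix(FALSE, 4, 4); a[1, 1:4] <- TRUE
  expect_equal(tsa(a, a), 100)
  b <- matrix(FALSE, 4, 4); b[3, 1:3] <- TRUE
  expect_equal(tsa(a, b), 0)
  # pred 4 px, ref 6 px, overlap 3 -> 2*3*100/(4+6)
  ref <- matrix(FALSE, 4, 4); ref[1, 1:3] <- TRUE; ref[2, 1:3] <- TRUE
  expect_equal(tsa(a, ref), 60)
  expect_equal(tsa(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 100)
  expect_error(tsa(a, matrix(FALSE, 3, 3)), "shapes")
})

test_that("TSA is symmetric", {
  set.seed(3)
  for (i in 1:5) {
    a <- matrix(stats::runif(36) > 0.5, 6)
    b <- matrix(stats::runif(36) > 0.5, 6)
    expect_equal(tsa(a, b), tsa(b, a))
  }
})

test_that("D_TSA measures distance from the perfect (100, 100) corner", {
  expect_equal(d_tsa(100, 100), 0)
  expect_equal(d_tsa(100, 0), 100)
  expect_equal(d_tsa(98, 94), sqrt(4 + 36))
  expect_equal(d_tsa(98, 94), 6.325, tolerance = 1e-4)
  expect_error(d_tsa(101, 50), "\\[0, 100\\]")
  expect_error(d_tsa(90, -2), "\\[0, 100\\]")
  # monotone decreasing in each argument
  expect_true(d_tsa(95, 90) > d_tsa(96, 90))
  expect_true(d_tsa(95, 90) > d_tsa(95, 91))
})

test_that("accuracy_report combines both classes and their confusion counts", {
  lab_ref <- matrix(0L, 4, 4); lab_ref[2:3, 2:3] <- 1L; lab_ref[2, 2] <- 2L
  lab_pred <- lab_ref; lab_pred[3, 3] <- 2L
  acc <- accuracy_report(segmentation_mask(lab_pred, source = "1D-FCM"),
                         segmentation_mask(lab_ref))
  expect_equal(acc$confusion$vessel$TP, 1)
  expect_equal(acc$confusion$vessel$FP, 1)
  expect_equal(acc$tsa_vessels, 2 * 1 * 100 / (2 + 1))
  expect_equal(acc$d_tsa, d_tsa(acc$tsa_parenchyma, acc$tsa_vessels))
})

test_that("LIC summaries use interpolated quartiles and the nIQR formula", {
  s <- lic_summary(make_lic(1:9), klass = "roi-all")
  expect_equal(s$q1, 3); expect_equal(s$q3, 7); expect_equal(s$median, 5)
  expect_equal(s$niqr, (7 - 3) * 100 / 5)

  const <- lic_summary(make_lic(rep(10, 6)), klass = "roi-all")
  expect_equal(const$median, 10)
  expect_equal(const$niqr, 0)
  expect_equal(const$level, "moderate")

  expect_error(lic_summary(make_lic(c(-1, -1, 1, 1)), klass = "roi-all"),
               "zero median")
  expect_error(lic_summary(make_lic(c(1, 2, 3)), klass = "roi-all"),
               "at least 4")
  expect_error(lic_summary(make_lic(1:9), mask = NULL, klass = "parenchyma"),
               "mask")
})

test_that("nIQR is invariant to rescaling the LIC map", {
  set.seed(6)
  v <- stats::rlnorm(200, log(10), 0.2)
  s1 <- lic_summary(make_lic(v), klass = "roi-all")
  s2 <- lic_summary(make_lic(3.7 * v), klass = "roi-all")
  expect_equal(s1$niqr, s2$niqr, tolerance = 1e-10)
})

test_that("the median withstands outlier pixels that inflate IQR and mean", {
  set.seed(8)
  core <- stats::rnorm(300, 20, 0.5)
  contaminated <- c(core, stats::runif(30, 0.5, 2))  # 10 % vessel-like pixels
  s_clean <- lic_summary(make_lic(core), klass = "roi-all")
  s_dirty <- lic_summary(make_lic(contaminated), klass = "roi-all")
  expect_lt(abs(s_dirty$median - s_clean$median) / s_clean$median, 0.02)
  expect_gt(s_dirty$iqr / s_clean$iqr, 1.15)
  # the mean, in contrast, is dragged far off by the same contamination
  expect_gt(abs(mean(contaminated) - mean(core)) / mean(core), 0.05)
})

test_that("parenchyma-only summaries respect the segmentation mask", {
  vals <- matrix(c(20, 21, 22, 23, 1, 1.5, 19, 20.5), 2)
  lic <- structure(list(values = vals, valid = matrix(TRUE, 2, 4),
                        roi = matrix(TRUE, 2, 4),
                        calibration = lic_calibration()), class = "lic_map")
  labels <- matrix(1L, 2, 4); labels[1, 3] <- 2L; labels[2, 3] <- 2L
  mask <- segmentation_mask(labels, source = "manual")
  s_par <- lic_summary(lic, mask, "parenchyma")
  s_all <- lic_summary(lic, klass = "roi-all")
  expect_identical(s_par$n_pixels, 6L)
  expect_identical(s_all$n_pixels, 8L)
  expect_lt(s_par$niqr, s_all$niqr)
})

test_that("agreement CV follows 1.96 SD of differences over the grand mean", {
  expect_equal(cv_agreement(c(3, 4, 5), c(3, 4, 5))$cv, 0)
  r <- cv_agreement(c(9.5, 10.5), c(10.5, 9.5))
  expect_equal(r$cv, 1.96 * stats::sd(c(-1, 1)) / 10 * 100)
  expect_equal(r$bias, 0)
  expect_error(cv_agreement(1, 2), "at least 2")
  expect_error(cv_agreement(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(cv_agreement(c(1, -1), c(-1, 1)), "grand mean")
})
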