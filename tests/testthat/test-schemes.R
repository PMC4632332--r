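test_that("RNR is the ROI signal range over the noise SD", {
  # noise region values {0, 5, 10} have sample SD exactly 5
  img <- matrix(60, 6, 6)
  img[3:4, 3:4] <- c(10, 110, 50, 70)      # ROI min 10, max 110
  img[1, 1:3] <- c(0, 5, 10)
  stk <- multi_echo_stack(list(img, img, img), c(1, 2, 3))
  roi <- matrix(FALSE, 6, 6); roi[3:4, 3:4] <- TRUE
  nmask <- matrix(FALSE, 6, 6); nmask[1, 1:3] <- TRUE
  prof <- compute_rnr(stk, roi, noise_mask = nmask)
  expect_equal(prof$rnr, rep((110 - 10) / 5, 3))

  img2 <- img; img2[3:4, 3:4] <- 42        # constant ROI
  stk2 <- multi_echo_stack(list(img2, img2, img2), c(1, 2, 3))
  expect_equal(compute_rnr(stk2, roi, noise_mask = nmask)$rnr, rep(0, 3))

  img3 <- img; img3[1, 1:3] <- 7           # constant noise region
  stk3 <- multi_echo_stack(list(img3, img3, img3), c(1, 2, 3))
  expect_error(compute_rnr(stk3, roi, noise_mask = nmask), "noise SD")
})

test_that("the SA echo choice is the earliest RNR maximum", {
  expect_identical(select_te_rnr_max(
    structure(list(rnr = c(3, 9, 7)), class = "rnr_profile")), 2L)
  expect_identical(select_te_rnr_max(
    structure(list(rnr = c(5, 5, 2)), class = "rnr_profile")), 1L)
})

test_that("faster-decaying parenchyma pulls the RNR-selected echo earlier", {
  ph_mild <- cached_phantom("mild", seed = 31L)
  ph_severe <- cached_phantom("severe", seed = 31L)
  te_mild <- select_te_rnr_max(compute_rnr(ph_mild$stack, ph_mild$roi))
  te_severe <- select_te_rnr_max(compute_rnr(ph_severe$stack, ph_severe$roi))
  expect_lt(te_severe, te_mild)
})

test_that("threshold scoring matches mask-level defuzzification exactly", {
  ph <- cached_phantom()
  lic <- cached_lic(ph)
  feats <- build_features(ph$stack, lic, ph$roi, "2D", 2L)
  res <- fcm_cluster(feats)
  vidx <- identify_vessel_cluster(res, feats)
  uv <- res$memberships[vidx, ]
  sc <- liverfcm:::score_thresholds(uv, feats$pixel_index, ph$roi, ph$truth,
                                    c(0, 0.3, 0.5, 0.8))
  for (i in seq_len(nrow(sc))) {
    mask <- defuzzify(res, vidx, sc$u0[i], feats, ph$roi)
    acc <- accuracy_report(mask, ph$truth)
    expect_equal(sc$tsa_parenchyma[i], acc$tsa_parenchyma)
    expect_equal(sc$tsa_vessels[i], acc$tsa_vessels)
    expect_equal(sc$d_tsa[i], acc$d_tsa)
  }
})

test_that("the OP search enumerates the full grid and attains its minimum", {
  ph <- cached_phantom()
  op <- cached_op(ph)
  expect_equal(unname(op$n_candidates), c(1000, 1000))
  expect_identical(nrow(op$candidates), 2000L)
  scored <- op$candidates[!is.na(op$candidates$d_tsa), ]
  for (mode in c("1D-FCM", "2D-FCM")) {
    best <- if (mode == "1D-FCM") op$best_1d else op$best_2d
    expect_equal(best$d_tsa,
                 min(scored$d_tsa[scored$mode == mode]), tolerance = 1e-10)
  }
  expect_equal(op$mix$d_tsa, min(op$best_1d$d_tsa, op$best_2d$d_tsa))
  expect_identical(op$mix$method, "MIX-FCM")
  expect_error(op_search(ph$stack, cached_lic(ph), ph$roi, NULL),
               "reference")
})

test_that("OP tie-breaks are deterministic towards low TE and low threshold", {
  ph <- cached_phantom()
  op <- cached_op(ph)
  for (best in list(op$best_1d, op$best_2d)) {
    sub <- op$candidates[op$candidates$mode == best$method &
                           !is.na(op$candidates$d_tsa), ]
    ties <- sub[abs(sub$d_tsa - best$d_tsa) < 1e-12, ]
    first <- ties[order(ties$te_index, ties$u0), ][1, ]
    expect_equal(best$te_index, first$te_index)
    expect_equal(best$u0, first$u0)
  }
})

test_that("the SA gallery has 50 outcomes per mode and never beats OP", {
  ph <- cached_phantom()
  lic <- cached_lic(ph)
  sa <- sa_run(ph$stack, lic, ph$roi, reference = ph$truth,
               selection = "reference-auto")
  expect_identical(nrow(sa$candidates_1d), 50L)
  expect_identical(nrow(sa$candidates_2d), 50L)
  expect_identical(sa$te_index,
                   select_te_rnr_max(compute_rnr(ph$stack, ph$roi)))
  op <- cached_op(ph)
  expect_gte(sa$chosen$d_tsa, op$mix$d_tsa - 1e-9)
  # SA candidates are a subset of the OP grid at the RNR-selected echo
  sub <- op$candidates[op$candidates$mode == "1D-FCM" &
                         op$candidates$te_index == sa$te_index, ]
  expect_equal(sa$candidates_1d$d_tsa, sub$d_tsa, tolerance = 1e-9)
})

test_that("SA runs are reproducible and honour an explicit user choice", {
  ph <- cached_phantom("mild", seed = 31L)
  lic <- cached_lic(ph)
  sa1 <- sa_run(ph$stack, lic, ph$roi, reference = ph$truth,
                selection = "reference-auto")
  sa2 <- sa_run(ph$stack, lic, ph$roi, reference = ph$truth,
                selection = "reference-auto")
  expect_identical(sa1$candidates_1d, sa2$candidates_1d)
  expect_identical(sa1$chosen$u0, sa2$chosen$u0)

  pick <- sa_run(ph$stack, lic, ph$roi, reference = ph$truth,
                 selection = "interactive-export",
                 choice = list(mode = "2D", index = 31L))
  expect_equal(pick$chosen$u0, threshold_grid()[31L])
  expect_identical(pick$chosen$scheme, "SA")
  expect_error(sa_run(ph$stack, lic, ph$roi, selection = "reference-auto"),
               "reference")
})
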