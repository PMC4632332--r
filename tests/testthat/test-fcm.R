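te20 <- default_te_grid()

# small handmade study: 4x4 grid, two-level decay, full ROI
tiny_study <- function() {
  r2map <- matrix(100, 4, 4); r2map[2:3, 2:3] <- 600
  stk <- toy_stack(r2map)
  roi <- matrix(TRUE, 4, 4)
  lic <- r2star_to_lic(fit_r2star_map(stk, roi))
  list(stack = stk, roi = roi, lic = lic)
}

test_that("feature matrices are ROI-indexed and min-max normalised", {
  s <- tiny_study()
  f2 <- build_features(s$stack, s$lic, s$roi, "2D", te_index = 3L)
  expect_identical(dim(f2$x), c(2L, 16L))
  expect_equal(range(f2$x[1, ]), c(0, 1))
  expect_equal(range(f2$x[2, ]), c(0, 1))
  f1 <- build_features(s$stack, NULL, s$roi, "1D", te_index = 3L)
  expect_identical(dim(f1$x), c(1L, 16L))
  v <- s$stack$echoes[[3L]][s$roi]
  expect_equal(f1$x[1, ], (v - min(v)) / (max(v) - min(v)))

  # invalid-LIC pixels are dropped from 2D features and recorded
  lic_bad <- s$lic
  lic_bad$valid[1, 1] <- FALSE
  f2b <- build_features(s$stack, lic_bad, s$roi, "2D", te_index = 3L)
  expect_identical(ncol(f2b$x), 15L)
  expect_identical(f2b$excluded, 1L)

  expect_error(build_features(s$stack, NULL, s$roi, "2D", 1L), "LIC")
  expect_error(build_features(s$stack, NULL, s$roi, "1D", 21L), "range")
  flat <- multi_echo_stack(replicate(3, matrix(5, 4, 4), simplify = FALSE),
                           c(1, 2, 3))
  expect_error(build_features(flat, NULL, s$roi, "1D", 1L), "degenerate")
})

test_that("two symmetric 1D groups give mirror-image centroids", {
  res <- fcm_cluster(matrix(c(0, 0.01, 0.99, 1), 1), fcm_params(tol = 1e-10))
  v <- sort(res$centroids[, 1])
  expect_true(res$converged)
  expect_equal(sum(v), 1, tolerance = 1e-6)
  expect_equal(v[1], 0.005, tolerance = 0.01)
  expect_equal(v[2], 0.995, tolerance = 0.01)
})

test_that("membership columns sum to one and the objective never increases", {
  set.seed(4)
  for (k in 1:2) {
    x <- matrix(stats::runif(k * 40), k)
    res <- fcm_cluster(x)
    expect_true(res$converged)
    expect_equal(colSums(res$memberships), rep(1, 40), tolerance = 1e-9)
    expect_true(all(res$memberships >= 0 & res$memberships <= 1))
    expect_true(all(diff(res$objective_trace) <= 1e-9))
  }
})

test_that("converged centroids match the brute-force fixed-point oracle", {
  set.seed(9)
  for (rep in 1:5) {
    k <- sample(1:2, 1)
    n <- sample(6:20, 1)
    x <- matrix(stats::runif(k * n), k)
    res <- fcm_cluster(x, fcm_params(tol = 1e-10, max_iter = 2000))
    oracle <- brute_fcm(x)
    expect_equal(res$centroids, oracle$centroids, tolerance = 1e-6)
    expect_equal(res$memberships, oracle$memberships, tolerance = 1e-5)
  }
})

test_that("centroids agree with an independent FCM implementation", {
  skip_if_not_installed("e1071")
  set.seed(21)
  x <- matrix(stats::runif(2 * 60), 2)
  res <- fcm_cluster(x, fcm_params(tol = 1e-10, max_iter = 2000))
  ext <- e1071::cmeans(t(x), centers = res$centroids, m = 2,
                       iter.max = 1000, method = "cmeans")
  expect_equal(unname(res$centroids), unname(ext$centers), tolerance = 1e-3)
})

test_that("permuting input columns permutes memberships identically", {
  set.seed(12)
  x <- matrix(stats::runif(2 * 25), 2)
  perm <- sample(25)
  r1 <- fcm_cluster(x)
  r2 <- fcm_cluster(x[, perm])
  expect_equal(r2$memberships, r1$memberships[, perm], tolerance = 1e-6)
})

test_that("points sitting exactly on a centroid get crisp membership", {
  x <- matrix(c(0, 0, 1, 1), 1)
  res <- fcm_cluster(x, fcm_params(tol = 1e-12, max_iter = 1000))
  expect_equal(sort(res$centroids[, 1]), c(0, 1), tolerance = 1e-6)
  expect_equal(max(res$memberships[, 1]), 1, tolerance = 1e-9)
  expect_error(fcm_cluster(matrix(0.5, 1, 1)), "at least")
})

test_that("the vessel cluster is low-LIC in 2D and bright in 1D", {
  res2 <- list(centroids = matrix(c(0.5, 0.5, 0.2, 0.8), 2),
               converged = TRUE)
  expect_identical(
    identify_vessel_cluster(res2, list(mode = "2D")), 1L)
  res1 <- list(centroids = matrix(c(0.3, 0.7), 2), converged = TRUE)
  expect_identical(
    identify_vessel_cluster(res1, list(mode = "1D")), 2L)
  res_eq <- list(centroids = matrix(c(0.5, 0.5), 2), converged = TRUE)
  expect_error(identify_vessel_cluster(res_eq, list(mode = "1D")),
               "degenerate")
})

test_that("defuzzification thresholds the vessel membership with ties to vessel", {
  s <- tiny_study()
  feats <- build_features(s$stack, NULL, s$roi, "1D", 1L)
  res <- fcm_cluster(feats)
  vidx <- identify_vessel_cluster(res, feats)

  # direct rule evaluation on a hand-made result restricted to 3 pixels
  hand <- list(memberships = rbind(c(0.9, 0.6, 0.3), c(0.1, 0.4, 0.7)))
  hand_feats <- list(pixel_index = c(1L, 2L, 3L), shape = c(1L, 3L),
                     mode = "1D")
  m <- defuzzify(hand, 1L, 0.5, hand_feats, matrix(TRUE, 1, 3))
  expect_identical(as.integer(m$labels), c(2L, 2L, 1L))

  m0 <- defuzzify(res, vidx, 0, feats, s$roi)
  expect_true(all(m0$labels[s$roi] == 2L))
  hi <- list(memberships = rbind(c(0.9, 0.6), c(0.1, 0.4)))
  hi_feats <- list(pixel_index = 1:2, shape = c(1L, 2L), mode = "1D")
  m98 <- defuzzify(hi, 1L, 0.98, hi_feats, matrix(TRUE, 1, 2))
  expect_true(all(m98$labels == 1L))
  expect_error(defuzzify(res, vidx, 1, feats, s$roi), "u0")
  expect_error(defuzzify(res, vidx, -0.1, feats, s$roi), "u0")
})

test_that("raising the threshold can only shrink the vessel mask", {
  s <- tiny_study()
  feats <- build_features(s$stack, s$lic, s$roi, "2D", 2L)
  res <- fcm_cluster(feats)
  vidx <- identify_vessel_cluster(res, feats)
  prev <- NULL
  for (u0 in threshold_grid()) {
    cur <- class_mask(defuzzify(res, vidx, u0, feats, s$roi), "vessel")
    if (!is.null(prev)) expect_true(all(!cur | prev))  # cur subset of prev
    prev <- cur
  }
})

test_that("vessel and parenchyma always partition the ROI", {
  s <- tiny_study()
  feats <- build_features(s$stack, s$lic, s$roi, "2D", 2L)
  res <- fcm_cluster(feats)
  vidx <- identify_vessel_cluster(res, feats)
  for (u0 in c(0, 0.3, 0.6, 0.98)) {
    m <- defuzzify(res, vidx, u0, feats, s$roi)
    vp <- class_mask(m, "vessel") | class_mask(m, "parenchyma")
    expect_identical(vp, s$roi)
    expect_false(any(class_mask(m, "vessel") & class_mask(m, "parenchyma")))
  }
})
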