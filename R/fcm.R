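#' FCM clustering parameters
#'
#' Parameters of the fuzzy c-means runs used for vessel/parenchyma
#' segmentation: two clusters and fuzzifier `m = 2`, the standard choices
#' for this task. Initialisation is deterministic (no RNG): centroids are
#' seeded with the maximin rule — the data point farthest from the
#' feature-space mean, then, repeatedly, the point farthest from the seeds
#' chosen so far — so repeated runs on the same input are identical.
#'
#' @param n_clusters Number of clusters `C` (>= 2; the segmentation pipeline
#'   uses 2: parenchyma and vessel).
#' @param m Fuzzifier (> 1). Larger values give softer memberships.
#' @param tol Convergence tolerance on the maximum centroid displacement
#'   between iterations.
#' @param max_iter Iteration cap.
#' @return A list of class `fcm_params`.
#' @export
fcm_params <- function(n_clusters = 2L, m = 2, tol = 1e-6, max_iter = 300L) {
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 2L) stop("need at least 2 clusters", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  structure(list(n_clusters = n_clusters, m = m, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "fcm_params")
}

#' Build the clustering feature matrix for one echo
#'
#' Assembles the `k x n` input matrix for FCM from the ROI pixels of one
#' echo image (1D mode: acquired intensity only) or from that echo plus the
#' LIC map (2D mode). Each feature is independently min-max normalised to
#' `[0, 1]` over the ROI, so intensity and LIC enter the Euclidean distance
#' on a common scale. In 2D mode, ROI pixels whose LIC fit is invalid are
#' excluded from the matrix and recorded in `excluded`.
#'
#' @param stack A [multi_echo_stack()].
#' @param lic A `lic_map` from [r2star_to_lic()]; required for `mode = "2D"`.
#' @param roi Logical ROI matrix.
#' @param mode `"1D"` (intensity only) or `"2D"` (intensity + LIC).
#' @param te_index Which echo supplies the intensity feature (1-based).
#'
#' @return An object of class `fcm_features`: `x` (`k x n` matrix in
#'   `[0, 1]`), `pixel_index` (linear index of each column in the image),
#'   `excluded` (linear indices of ROI pixels dropped for invalid LIC),
#'   `mode`, `te_index`, `te_ms`, and `shape`.
#' @export
build_features <- function(stack, lic = NULL, roi, mode = c("1D", "2D"),
                           te_index = 1L) {
  stopifnot(inherits(stack, "multi_echo_stack"))
  mode <- match.arg(mode)
  roi <- check_roi(stack, roi)
  te_index <- as.integer(te_index)
  if (te_index < 1L || te_index > length(stack$echoes))
    stop(sprintf("te_index %d out of range 1..%d", te_index,
                 length(stack$echoes)), call. = FALSE)
  idx <- which(roi)
  excluded <- integer(0)
  if (mode == "2D") {
    if (is.null(lic))
      stop("2D mode requires a LIC map", call. = FALSE)
    keep <- lic$valid[idx]
    excluded <- idx[!keep]
    idx <- idx[keep]
    if (length(idx) == 0L)
      stop("no ROI pixel has a valid LIC fit", call. = FALSE)
  }
  ai <- stack$echoes[[te_index]][idx]
  x <- rbind(intensity = minmax_normalize(ai))
  if (mode == "2D")
    x <- rbind(x, lic = minmax_normalize(lic$values[idx]))
  structure(list(x = x, pixel_index = idx, excluded = excluded,
                 mode = mode, te_index = te_index,
                 te_ms = stack$te_ms[te_index], shape = stack$shape),
            class = "fcm_features")
}

minmax_normalize <- function(v) {
  rng <- range(v)
  if (!all(is.finite(rng)))
    stop("feature contains non-finite values", call. = FALSE)
  if (rng[2L] - rng[1L] <= 0)
    stop_degenerate("degenerate feature: all values identical (max == min)")
  (v - rng[1L]) / (rng[2L] - rng[1L])
}

#' Fuzzy c-means clustering
#'
#' Minimises the fuzzy partition objective
#' \deqn{J_m(u, v) = \sum_{i=1}^{C} \sum_{j=1}^{n} u_{ij}^m \,
#'   \lVert x_j - v_i \rVert^2,\qquad \sum_i u_{ij} = 1,}
#' by alternating the standard update rules: memberships from
#' inverse-squared Euclidean distances with exponent `1/(m-1)`, centroids as
#' `u^m`-weighted means. Iteration stops when the maximum centroid
#' displacement drops below `tol` or after `max_iter` iterations. A point
#' coinciding exactly with a centroid receives membership 1 for that cluster.
#' The run is fully deterministic given the features and parameters.
#'
#' @param features An `fcm_features` object (or a bare `k x n` numeric
#'   matrix).
#' @param params An [fcm_params()].
#'
#' @return An object of class `fcm_result`: `memberships` (`C x n`, columns
#'   sum to 1), `centroids` (`C x k`), `objective_trace` (value of the
#'   objective after each iteration, non-increasing), `iterations`, and
#'   `converged`.
#' @export
fcm_cluster <- function(features, params = fcm_params()) {
  x <- if (inherits(features, "fcm_features")) features$x else features
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  k <- nrow(x); n <- ncol(x)
  C <- params$n_clusters
  if (n < C)
    stop(sprintf("need at least C = %d points, got %d", C, n), call. = FALSE)

  v <- fcm_init_centroids(x, C)
  exponent <- 1 / (params$m - 1)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  u <- NULL
  while (iter < params$max_iter) {
    iter <- iter + 1L
    d2 <- fcm_dist2(x, v)                       # C x n
    u <- fcm_memberships(d2, exponent)
    um <- u^params$m
    v_new <- (um %*% t(x)) / rowSums(um)        # C x k
    trace <- c(trace, sum(um * d2))
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < params$tol) { converged <- TRUE; break }
  }
  structure(list(memberships = u, centroids = v, objective_trace = trace,
                 iterations = iter, converged = converged,
                 params = params),
            class = "fcm_result")
}

# Deterministic maximin (KKZ) seeding: the first centroid is the data
# point farthest from the feature-space mean, each further one the point
# farthest from its nearest already-chosen centroid. Unlike quantile-based
# diagonal seeding this cannot start symmetric to an anti-correlated cloud
# (the typical intensity/LIC geometry), which would collapse both
# centroids onto the grand mean.
fcm_init_centroids <- function(x, C) {
  mu <- rowMeans(x)
  v <- matrix(0, C, nrow(x))
  v[1L, ] <- x[, which.max(colSums((x - mu)^2))]
  for (i in seq_len(C - 1L)) {
    d2 <- fcm_dist2(x, v[seq_len(i), , drop = FALSE])
    nearest <- if (i == 1L) d2[1L, ] else apply(d2, 2L, min)
    v[i + 1L, ] <- x[, which.max(nearest)]
  }
  v
}

# Squared Euclidean distances between C centroids (C x k) and n points
# (k x n); returns C x n.
fcm_dist2 <- function(x, v) {
  C <- nrow(v)
  d2 <- matrix(0, C, ncol(x))
  for (i in seq_len(C)) d2[i, ] <- colSums((x - v[i, ])^2)
  d2
}

# Membership update with the zero-distance convention: a point sitting on a
# centroid belongs entirely to that cluster (split evenly if on several).
fcm_memberships <- function(d2, exponent) {
  inv <- d2^(-exponent)
  zero <- d2 <= .Machine$double.xmin
  hit <- colSums(zero) > 0
  u <- inv / rep(colSums(inv), each = nrow(inv))
  if (any(hit)) {
    u[, hit] <- 0
    u[, hit][zero[, hit, drop = FALSE]] <- 1
    u[, hit] <- u[, hit, drop = FALSE] /
      rep(colSums(u[, hit, drop = FALSE]), each = nrow(u))
  }
  u
}

#' Identify which cluster is the vessel cluster
#'
#' In 2D mode, vessels have low iron signal, so the vessel cluster is the
#' one with the lower LIC-feature centroid. In 1D mode, vessels retain
#' signal longer than iron-loaded parenchyma, so the vessel cluster is the
#' one with the higher intensity centroid.
#'
#' @param result An `fcm_result`.
#' @param features The `fcm_features` the result was computed from.
#' @return Integer index (row of `result$centroids`) of the vessel cluster.
#' @export
identify_vessel_cluster <- function(result, features) {
  v <- result$centroids
  key <- if (features$mode == "2D") v[, 2L] else -v[, 1L]
  if (abs(diff(range(key))) <= .Machine$double.eps)
    stop_degenerate("degenerate clustering: cluster centroids coincide")
  which.min(key)
}

#' Defuzzify memberships into a hard vessel/parenchyma mask
#'
#' A ROI pixel is labelled vessel when its vessel-cluster membership is at
#' least the threshold `u0` (ties go to vessel); every other ROI pixel is
#' parenchyma, so the two classes always partition the ROI. Raising `u0`
#' can only shrink the vessel mask. ROI pixels that were excluded from the
#' feature matrix (invalid LIC fit in 2D mode) are labelled parenchyma.
#'
#' @param result An `fcm_result`.
#' @param vessel_idx Index of the vessel cluster, from
#'   [identify_vessel_cluster()].
#' @param u0 Membership threshold in `[0, 0.98]`.
#' @param features The `fcm_features` the result was computed from.
#' @param roi Logical ROI matrix.
#' @param source Label recorded on the mask (e.g. `"1D-FCM"`).
#'
#' @return A `segmentation_mask`: `labels` matrix coded 0 outside, 1
#'   parenchyma, 2 vessel; plus `u0` and `source`.
#' @export
defuzzify <- function(result, vessel_idx, u0, features, roi,
                      source = features$mode) {
  if (!is.finite(u0) || u0 < 0 || u0 >= 1)
    stop("u0 must lie in [0, 1)", call. = FALSE)
  roi <- if (is.numeric(roi)) roi != 0 else roi
  labels <- matrix(0L, features$shape[1L], features$shape[2L])
  labels[roi] <- 1L
  uv <- result$memberships[vessel_idx, ]
  labels[features$pixel_index[uv >= u0]] <- 2L
  segmentation_mask(labels, u0 = u0, source = source)
}

#' Segmentation mask container
#'
#' @param labels Integer matrix coded 0 (outside ROI), 1 (parenchyma),
#'   2 (vessel).
#' @param u0 Membership threshold that produced the mask (`NA` for manual
#'   masks).
#' @param source One of `"1D-FCM"`, `"2D-FCM"`, `"MIX-FCM"`, `"manual"`, or
#'   a mode tag.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(labels, u0 = NA_real_, source = "manual") {
  if (!all(labels %in% 0:2))
    stop("labels must be coded 0 (outside), 1 (parenchyma), 2 (vessel)",
         call. = FALSE)
  structure(list(labels = labels, u0 = u0, source = source),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf(
    "segmentation_mask [%s]: %d parenchyma, %d vessel, %d outside (u0 = %s)\n",
    x$source, sum(x$labels == 1L), sum(x$labels == 2L), sum(x$labels == 0L),
    format(x$u0)))
  invisible(x)
}

#' Logical class mask from a segmentation
#'
#' @param mask A `segmentation_mask`.
#' @param class_label `"vessel"` or `"parenchyma"`.
#' @return Logical matrix selecting that class.
#' @export
class_mask <- function(mask, class_label = c("vessel", "parenchyma")) {
  class_label <- match.arg(class_label)
  mask$labels == if (class_label == "vessel") 2L else 1L
}
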