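# Independent oracles and shared fixtures for the test suite.

# Brute-force fuzzy c-means fixed-point iteration, written as plain scalar
# loops straight from the objective's stationarity conditions. Used as an
# oracle for the vectorised implementation; run to a much tighter tolerance.
brute_fcm <- function(x, C = 2L, m = 2, tol = 1e-12, max_iter = 10000L) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  k <- nrow(x); n <- ncol(x)
  # maximin seeding, written out naively: farthest point from the mean,
  # then the point farthest from its nearest seed
  v <- matrix(0, C, k)
  mu <- rowMeans(x)
  dmu <- numeric(n)
  for (j in seq_len(n)) dmu[j] <- sum((x[, j] - mu)^2)
  v[1L, ] <- x[, which.max(dmu)]
  for (i in seq_len(C - 1L)) {
    dmin <- numeric(n)
    for (j in seq_len(n)) {
      ds <- numeric(i)
      for (s in seq_len(i)) ds[s] <- sum((x[, j] - v[s, ])^2)
      dmin[j] <- min(ds)
    }
    v[i + 1L, ] <- x[, which.max(dmin)]
  }
  u <- matrix(0, C, n)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(n)) {
      d2 <- numeric(C)
      for (i in seq_len(C)) d2[i] <- sum((x[, j] - v[i, ])^2)
      if (any(d2 == 0)) {
        u[, j] <- ifelse(d2 == 0, 1 / sum(d2 == 0), 0)
      } else {
        for (i in seq_len(C))
          u[i, j] <- 1 / sum((d2[i] / d2)^(1 / (m - 1)))
      }
    }
    v_new <- v
    for (i in seq_len(C))
      for (f in seq_len(k))
        v_new[i, f] <- sum(u[i, ]^m * x[f, ]) / sum(u[i, ]^m)
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < tol) break
  }
  list(centroids = v, memberships = u)
}

# Forward C-EXP signal on a TE grid (ms), the generating model for
# relaxometry recovery tests.
cexp_signal <- function(te_ms, s0, r2star, c_offset = 0) {
  s0 * exp(-te_ms / 1000 * r2star) + c_offset
}

# Shared phantom fixtures, memoised so several test files can reuse the
# same generated study and its (relatively expensive) pixel-wise fit.
.fixture_cache <- new.env(parent = emptyenv())

cached_phantom <- function(level = "severe", seed = 11L, shape = c(48L, 48L),
                           ...) {
  key <- paste0("ph_", level, "_", seed, "_", paste(shape, collapse = "x"),
                "_", paste(deparse(list(...)), collapse = ""))
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_phantom(
      phantom_config(shape = shape, lic_level = level, seed = seed, ...))
  .fixture_cache[[key]]
}

cached_lic <- function(ph) {
  key <- paste0("lic_", ph$config$lic_level, "_", ph$config$seed, "_",
                paste(ph$config$shape, collapse = "x"))
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- r2star_to_lic(fit_r2star_map(ph$stack, ph$roi))
  .fixture_cache[[key]]
}

cached_op <- function(ph) {
  key <- paste0("op_", ph$config$lic_level, "_", ph$config$seed, "_",
                paste(ph$config$shape, collapse = "x"))
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- op_search(ph$stack, cached_lic(ph), ph$roi,
                                       ph$truth)
  .fixture_cache[[key]]
}

# Wrap a numeric vector as a single-row lic_map for metric tests.
make_lic <- function(values) {
  v <- matrix(values, 1)
  structure(list(values = v, valid = !is.na(v),
                 roi = matrix(TRUE, 1, length(values)),
                 calibration = lic_calibration()), class = "lic_map")
}

# Tiny hand-made stack: every pixel decays with the given R2* map.
toy_stack <- function(r2map, te_ms = default_te_grid(), s0 = 1000,
                      c_offset = 0) {
  echoes <- lapply(te_ms, function(te)
    s0 * exp(-te / 1000 * r2map) + c_offset)
  multi_echo_stack(echoes, te_ms)
}
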