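#' Defuzzification threshold grid
#'
#' The 50 membership thresholds searched by the OP scheme and offered to the
#' user by the SA scheme: 0 to 0.98 in 0.02 increments.
#'
#' @return Numeric vector of 50 thresholds.
#' @export
threshold_grid <- function() {
  seq(0, 0.98, by = 0.02)
}

#' Per-echo signal-range-to-noise ratio (RNR)
#'
#' For each echo, the ratio of the intensity range inside the ROI (largest
#' minus smallest signal) to the standard deviation of the noise in that
#' echo image. The echo with the maximum RNR carries the strongest
#' parenchyma/vessel contrast relative to noise and is the SA scheme's
#' automatic TE choice.
#'
#' Noise is estimated per echo either from the pooled standard deviation of
#' four 8x8 corner patches (assumed signal-free background) or from a
#' user-supplied noise mask.
#'
#' @param stack A [multi_echo_stack()].
#' @param roi Logical ROI matrix.
#' @param noise_mask Optional logical matrix selecting signal-free pixels
#'   for noise estimation; when `NULL`, the four image corners are used.
#' @param patch Corner patch edge length in pixels (default 8).
#' @return A list of class `rnr_profile`: `rnr` (per echo), `noise_sd`
#'   (per echo), and `argmax_te` (smallest index attaining the maximum).
#' @export
compute_rnr <- function(stack, roi, noise_mask = NULL, patch = 8L) {
  stopifnot(inherits(stack, "multi_echo_stack"))
  roi <- check_roi(stack, roi)
  nr <- stack$shape[1L]; nc <- stack$shape[2L]
  if (is.null(noise_mask)) {
    p <- min(as.integer(patch), nr %/% 2L, nc %/% 2L)
    noise_mask <- matrix(FALSE, nr, nc)
    noise_mask[c(seq_len(p), nr - p + seq_len(p)),
               c(seq_len(p), nc - p + seq_len(p))] <- TRUE
  } else {
    noise_mask <- if (is.numeric(noise_mask)) noise_mask != 0 else noise_mask
    if (!identical(dim(noise_mask), stack$shape))
      stop("noise mask shape does not match stack", call. = FALSE)
  }
  if (sum(noise_mask) < 2L)
    stop("noise region must contain at least 2 pixels", call. = FALSE)
  rnr <- numeric(length(stack$echoes))
  noise_sd <- numeric(length(stack$echoes))
  for (e in seq_along(stack$echoes)) {
    img <- stack$echoes[[e]]
    noise_sd[e] <- stats::sd(img[noise_mask])
    if (!is.finite(noise_sd[e]) || noise_sd[e] <= 0)
      stop_degenerate(sprintf("estimated noise SD is zero for echo %d", e))
    rnr[e] <- (max(img[roi]) - min(img[roi])) / noise_sd[e]
  }
  structure(list(rnr = rnr, noise_sd = noise_sd,
                 argmax_te = which.max(rnr)),
            class = "rnr_profile")
}

#' SA-scheme echo selection: the echo with maximum RNR
#'
#' @param profile An `rnr_profile` from [compute_rnr()].
#' @return Integer echo index (earliest index on ties).
#' @export
select_te_rnr_max <- function(profile) {
  stopifnot(inherits(profile, "rnr_profile"))
  which.max(profile$rnr)
}

# Score every threshold of one clustered (mode, TE) candidate against the
# reference by pure count arithmetic; exactly equivalent to
# defuzzify() + accuracy_report() but without materialising masks.
score_thresholds <- function(uv, pixel_index, roi, reference, thresholds) {
  ref_lab <- reference$labels
  refv <- ref_lab[pixel_index] == 2L
  n_roi <- sum(roi)
  n_ref_v <- sum(ref_lab == 2L)
  n_ref_p <- sum(ref_lab == 1L)
  refp <- ref_lab[pixel_index] == 1L
  out <- data.frame(u0 = thresholds, tsa_parenchyma = NA_real_,
                    tsa_vessels = NA_real_, d_tsa = NA_real_)
  for (t in seq_along(thresholds)) {
    vsel <- uv >= thresholds[t]
    n_v <- sum(vsel)
    tp_v <- sum(refv & vsel)
    n_p <- n_roi - n_v
    tp_p <- n_ref_p - sum(refp & vsel)
    tv <- if (n_v + n_ref_v == 0L) 100 else 2 * tp_v * 100 / (n_v + n_ref_v)
    tp <- if (n_p + n_ref_p == 0L) 100 else 2 * tp_p * 100 / (n_p + n_ref_p)
    out$tsa_parenchyma[t] <- tp
    out$tsa_vessels[t] <- tv
    out$d_tsa[t] <- sqrt((100 - tp)^2 + (100 - tv)^2)
  }
  out
}

# Cluster one (mode, TE) candidate; returns NULL when the features or the
# clustering are degenerate (constant feature, coincident centroids).
cluster_candidate <- function(stack, lic, roi, mode, te_index, params) {
  tryCatch({
    feats <- build_features(stack, lic, roi, mode = mode,
                            te_index = te_index)
    res <- fcm_cluster(feats, params)
    vidx <- identify_vessel_cluster(res, feats)
    list(features = feats, result = res, vessel_idx = vidx)
  }, error = function(e) NULL)
}

# Assemble a scheme outcome (with a materialised mask) for one candidate.
make_outcome <- function(cand, roi, method, scheme, u0, stack,
                         reference = NULL) {
  mask <- defuzzify(cand$result, cand$vessel_idx, u0, cand$features, roi,
                    source = method)
  out <- list(method = method, scheme = scheme,
              te_index = cand$features$te_index,
              te_ms = cand$features$te_ms, u0 = u0, mask = mask,
              tsa_parenchyma = NA_real_, tsa_vessels = NA_real_,
              d_tsa = NA_real_)
  if (!is.null(reference)) {
    acc <- accuracy_report(mask, reference)
    out$tsa_parenchyma <- acc$tsa_parenchyma
    out$tsa_vessels <- acc$tsa_vessels
    out$d_tsa <- acc$d_tsa
  }
  structure(out, class = "scheme_outcome")
}

#' @export
print.scheme_outcome <- function(x, ...) {
  cat(sprintf("%s [%s]: TE %d (%.2f ms), u0 %.2f, D_TSA %s\n",
              x$method, x$scheme, x$te_index, x$te_ms, x$u0,
              if (is.na(x$d_tsa)) "n/a" else sprintf("%.2f%%", x$d_tsa)))
  invisible(x)
}

#' OP scheme: exhaustive search for the optimal segmentation
#'
#' Enumerates, for each FCM mode (1D and 2D), every combination of echo
#' image and defuzzification threshold — with the default grids, 20 echoes
#' times 50 thresholds = 1,000 candidates per mode — scores each candidate's
#' D_TSA against the manual reference segmentation, and keeps the minimum.
#' The MIX outcome is the better of the two per-mode optima. The OP scheme
#' is defined only relative to a reference mask and is the package's
#' reference ("best achievable") scheme.
#'
#' Ties are broken deterministically towards the lower echo index, then the
#' lower threshold. A candidate whose features or clustering are degenerate
#' (e.g. a constant echo image) is skipped and recorded with `NA` scores.
#'
#' @param stack A [multi_echo_stack()].
#' @param lic A `lic_map` (needed for the 2D mode).
#' @param roi Logical ROI matrix.
#' @param reference A `segmentation_mask` with the manual reference.
#' @param te_indices Echo indices to search (default: all echoes).
#' @param thresholds Membership thresholds to search (default:
#'   [threshold_grid()]).
#' @param params [fcm_params()].
#'
#' @return A list of class `op_result`: `best_1d`, `best_2d`, `mix`
#'   (`scheme_outcome`s; `mix$method == "MIX-FCM"`), `candidates` (one row
#'   per scored candidate: mode, te_index, te_ms, u0, TSAs, d_tsa),
#'   `n_candidates` (named per-mode grid cardinality), and `skipped`
#'   (degenerate (mode, TE) pairs).
#' @export
op_search <- function(stack, lic, roi, reference,
                      te_indices = seq_along(stack$echoes),
                      thresholds = threshold_grid(),
                      params = fcm_params()) {
  stopifnot(inherits(stack, "multi_echo_stack"))
  if (is.null(reference) || !inherits(reference, "segmentation_mask"))
    stop("the OP scheme requires a reference segmentation mask",
         call. = FALSE)
  roi <- check_roi(stack, roi)
  modes <- c("1D", "2D")
  rows <- vector("list", length(modes) * length(te_indices))
  skipped <- list()
  best <- list()
  ri <- 0L
  for (mode in modes) {
    method <- paste0(mode, "-FCM")
    best_score <- Inf
    best_at <- NULL
    for (te in te_indices) {
      ri <- ri + 1L
      cand <- cluster_candidate(stack, lic, roi, mode, te, params)
      tab <- data.frame(mode = method, te_index = te,
                        te_ms = stack$te_ms[te], u0 = thresholds,
                        tsa_parenchyma = NA_real_, tsa_vessels = NA_real_,
                        d_tsa = NA_real_)
      if (is.null(cand)) {
        skipped[[length(skipped) + 1L]] <- list(mode = method, te_index = te)
      } else {
        sc <- score_thresholds(cand$result$memberships[cand$vessel_idx, ],
                               cand$features$pixel_index, roi, reference,
                               thresholds)
        tab$tsa_parenchyma <- sc$tsa_parenchyma
        tab$tsa_vessels <- sc$tsa_vessels
        tab$d_tsa <- sc$d_tsa
        k <- which.min(sc$d_tsa)   # lowest u0 on ties within a TE
        if (sc$d_tsa[k] < best_score) {   # strict: lower TE wins ties
          best_score <- sc$d_tsa[k]
          best_at <- list(cand = cand, u0 = thresholds[k])
        }
      }
      rows[[ri]] <- tab
    }
    if (is.null(best_at))
      stop(sprintf("every %s candidate was degenerate", method),
           call. = FALSE)
    best[[mode]] <- make_outcome(best_at$cand, roi, method, "OP",
                                 best_at$u0, stack, reference)
  }
  mix <- if (best[["1D"]]$d_tsa <= best[["2D"]]$d_tsa) best[["1D"]] else
    best[["2D"]]
  mix$method <- "MIX-FCM"
  candidates <- do.call(rbind, rows)
  n_cand <- length(te_indices) * length(thresholds)
  structure(list(best_1d = best[["1D"]], best_2d = best[["2D"]], mix = mix,
                 candidates = candidates,
                 n_candidates = c(`1D-FCM` = n_cand, `2D-FCM` = n_cand),
                 skipped = skipped),
            class = "op_result")
}

#' @export
print.op_result <- function(x, ...) {
  cat("OP scheme search:\n")
  print(x$best_1d); print(x$best_2d); print(x$mix)
  invisible(x)
}

#' SA scheme: RNR-driven echo choice plus a user-selected threshold
#'
#' The semi-automatic scheme fixes the echo automatically at the maximum of
#' the signal-range-to-noise ratio (RNR) profile, then produces the full
#' 50-threshold outcome gallery for each FCM mode from which the user picks
#' one. Two selection modes are supported: `"interactive-export"` writes an
#' indexed PNG contact sheet (when `out_dir` is given) and honours an
#' explicit `choice`; `"reference-auto"` emulates the user by picking the
#' minimum-D_TSA candidate across both modes, which requires a reference
#' mask and exists to make the scheme comparable to OP on phantoms.
#'
#' @param stack A [multi_echo_stack()].
#' @param lic A `lic_map`.
#' @param roi Logical ROI matrix.
#' @param reference Optional `segmentation_mask`; required for
#'   `selection = "reference-auto"`, and used to annotate candidates with
#'   D_TSA whenever present.
#' @param selection `"reference-auto"` or `"interactive-export"`.
#' @param choice Optional explicit pick, a list `list(mode = "1D",
#'   index = 12)` indexing into the threshold gallery.
#' @param thresholds Threshold gallery (default [threshold_grid()]).
#' @param params [fcm_params()].
#' @param noise_mask Optional noise region forwarded to [compute_rnr()].
#' @param out_dir Optional directory for the PNG gallery.
#'
#' @return A list of class `sa_result`: `te_index`, `te_ms`, `rnr`
#'   (the profile), `candidates_1d` and `candidates_2d` (50-row score
#'   tables), `chosen` (a `scheme_outcome` with `method = "MIX-FCM"`, or the
#'   explicit choice; `NULL` when interactive and no choice given), and
#'   `gallery_files`.
#' @export
sa_run <- function(stack, lic, roi, reference = NULL,
                   selection = c("reference-auto", "interactive-export"),
                   choice = NULL, thresholds = threshold_grid(),
                   params = fcm_params(), noise_mask = NULL,
                   out_dir = NULL) {
  selection <- match.arg(selection)
  roi <- check_roi(stack, roi)
  if (selection == "reference-auto" && is.null(reference))
    stop("reference-auto selection requires a reference mask", call. = FALSE)
  profile <- compute_rnr(stack, roi, noise_mask = noise_mask)
  te <- select_te_rnr_max(profile)

  cands <- list(); tabs <- list()
  for (mode in c("1D", "2D")) {
    cand <- cluster_candidate(stack, lic, roi, mode, te, params)
    if (is.null(cand))
      stop(sprintf("%s-FCM clustering is degenerate at the RNR-selected echo",
                   mode), call. = FALSE)
    tab <- data.frame(mode = paste0(mode, "-FCM"), te_index = te,
                      te_ms = stack$te_ms[te], u0 = thresholds,
                      tsa_parenchyma = NA_real_, tsa_vessels = NA_real_,
                      d_tsa = NA_real_)
    if (!is.null(reference)) {
      sc <- score_thresholds(cand$result$memberships[cand$vessel_idx, ],
                             cand$features$pixel_index, roi, reference,
                             thresholds)
      tab$tsa_parenchyma <- sc$tsa_parenchyma
      tab$tsa_vessels <- sc$tsa_vessels
      tab$d_tsa <- sc$d_tsa
    }
    cands[[mode]] <- cand
    tabs[[mode]] <- tab
  }

  gallery_files <- character(0)
  if (selection == "interactive-export" && !is.null(out_dir))
    gallery_files <- write_sa_gallery(cands, roi, thresholds, stack, out_dir)

  chosen <- NULL
  if (!is.null(choice)) {
    mode <- match.arg(choice$mode, c("1D", "2D"))
    idx <- as.integer(choice$index)
    if (idx < 1L || idx > length(thresholds))
      stop("gallery index out of range", call. = FALSE)
    chosen <- make_outcome(cands[[mode]], roi, "MIX-FCM", "SA",
                           thresholds[idx], stack, reference)
  } else if (selection == "reference-auto") {
    both <- rbind(tabs[["1D"]], tabs[["2D"]])
    k <- which.min(both$d_tsa)   # row order breaks ties: 1D first, low u0
    mode <- if (k <= length(thresholds)) "1D" else "2D"
    chosen <- make_outcome(cands[[mode]], roi, "MIX-FCM", "SA",
                           both$u0[k], stack, reference)
  }
  structure(list(te_index = te, te_ms = stack$te_ms[te], rnr = profile,
                 candidates_1d = tabs[["1D"]], candidates_2d = tabs[["2D"]],
                 chosen = chosen, gallery_files = gallery_files),
            class = "sa_result")
}

#' @export
print.sa_result <- function(x, ...) {
  cat(sprintf("SA scheme: RNR-selected echo %d (%.2f ms), %d+%d candidates\n",
              x$te_index, x$te_ms, nrow(x$candidates_1d),
              nrow(x$candidates_2d)))
  if (!is.null(x$chosen)) print(x$chosen)
  invisible(x)
}
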