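#' Tissue segmentation accuracy (dice coefficient, percent)
#'
#' \deqn{TSA(\%) = \frac{2 N_{cs} \cdot 100}{N_{ts} + N_{tr}}}
#' where `N_cs` is the number of pixels correctly assigned to the class,
#' and `N_ts`, `N_tr` are the class sizes in the prediction and reference.
#' Equivalently, 100 times the dice coefficient. When both masks are empty
#' the two segmentations agree on the absence of the class and TSA is
#' defined as 100.
#'
#' @param pred,ref Logical matrices (or 0/1) of the same shape selecting the
#'   class in the predicted and reference segmentation.
#' @return TSA in percent, in `[0, 100]`. Symmetric in its arguments.
#' @export
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' tsa(a, a)
tsa <- function(pred, ref) {
  pred <- as_logical_mask(pred)
  ref <- as_logical_mask(ref)
  if (!identical(dim(pred), dim(ref)))
    stop(sprintf("mask shapes differ: %s vs %s",
                 paste(dim(pred), collapse = "x"),
                 paste(dim(ref), collapse = "x")), call. = FALSE)
  n_ts <- sum(pred); n_tr <- sum(ref)
  if (n_ts + n_tr == 0L) return(100)
  2 * sum(pred & ref) * 100 / (n_ts + n_tr)
}

as_logical_mask <- function(m) {
  if (inherits(m, "segmentation_mask"))
    stop("pass a single class mask (see class_mask()), not a segmentation",
         call. = FALSE)
  if (is.logical(m)) m else m != 0
}

#' Distance of a (parenchyma, vessel) TSA pair from perfect segmentation
#'
#' \deqn{D_{TSA}(\%) = \sqrt{(100 - TSA_{liver})^2 + (100 - TSA_{vessels})^2}}
#' Zero means both classes match the reference exactly; the maximum,
#' attained when both TSAs are 0, is \eqn{100\sqrt{2}}.
#'
#' @param tsa_liver,tsa_vessels TSA percentages in `[0, 100]`.
#' @return D_TSA in percent.
#' @export
#' @examples
#' d_tsa(98, 94)
d_tsa <- function(tsa_liver, tsa_vessels) {
  if (any(!is.finite(c(tsa_liver, tsa_vessels))) ||
      any(c(tsa_liver, tsa_vessels) < 0) ||
      any(c(tsa_liver, tsa_vessels) > 100))
    stop("TSA values must lie in [0, 100]", call. = FALSE)
  sqrt((100 - tsa_liver)^2 + (100 - tsa_vessels)^2)
}

#' Segmentation accuracy report for both anatomical classes
#'
#' Computes parenchyma and vessel TSA of a predicted segmentation against a
#' reference, their D_TSA, and the per-class confusion counts.
#'
#' @param pred,ref `segmentation_mask` objects on the same grid (labels 0
#'   outside, 1 parenchyma, 2 vessel).
#' @return A list of class `accuracy_report`: `tsa_parenchyma`,
#'   `tsa_vessels`, `d_tsa` (all percent) and `confusion`, a list with
#'   `TP`, `FP`, `FN`, `TN` for each class.
#' @export
accuracy_report <- function(pred, ref) {
  stopifnot(inherits(pred, "segmentation_mask"),
            inherits(ref, "segmentation_mask"))
  confusion <- lapply(c(parenchyma = "parenchyma", vessel = "vessel"),
                      function(cl) {
    p <- class_mask(pred, cl); r <- class_mask(ref, cl)
    list(TP = sum(p & r), FP = sum(p & !r), FN = sum(!p & r),
         TN = sum(!p & !r))
  })
  tp <- tsa(class_mask(pred, "parenchyma"), class_mask(ref, "parenchyma"))
  tv <- tsa(class_mask(pred, "vessel"), class_mask(ref, "vessel"))
  structure(list(tsa_parenchyma = tp, tsa_vessels = tv,
                 d_tsa = d_tsa(tp, tv), confusion = confusion),
            class = "accuracy_report")
}

#' Robust summary of a LIC map over a pixel class
#'
#' Median, quartiles, IQR and the normalised interquartile range
#' \deqn{nIQR(\%) = \frac{(Q_3 - Q_1) \cdot 100}{median}}
#' of the liver iron concentration over either the parenchyma pixels of a
#' segmentation or the whole ROI. Quartiles use linear interpolation
#' between order statistics (R's default quantile type 7). Pixels with an
#' invalid fit are excluded.
#'
#' @param lic A `lic_map` from [r2star_to_lic()].
#' @param mask A `segmentation_mask`; ignored when `klass = "roi-all"`.
#' @param klass `"parenchyma"` (segmented summary) or `"roi-all"`
#'   (unsegmented summary over every valid ROI pixel).
#' @return A list of class `lic_summary`: `median`, `q1`, `q3`, `iqr`
#'   (mg/g dry weight), `niqr` (percent), `level` (iron-overload band of the
#'   median), and `n_pixels`.
#' @export
lic_summary <- function(lic, mask = NULL, klass = c("parenchyma", "roi-all")) {
  klass <- match.arg(klass)
  sel <- lic$valid & lic$roi
  if (klass == "parenchyma") {
    if (is.null(mask))
      stop("parenchyma summary requires a segmentation mask", call. = FALSE)
    sel <- sel & class_mask(mask, "parenchyma")
  }
  v <- lic$values[sel]
  if (length(v) < 4L)
    stop(sprintf("need at least 4 valid pixels, got %d", length(v)),
         call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  med <- q[2L]
  if (med == 0)
    stop_degenerate("nIQR is undefined for a zero median")
  structure(list(median = med, q1 = q[1L], q3 = q[3L], iqr = q[3L] - q[1L],
                 niqr = (q[3L] - q[1L]) * 100 / med,
                 level = as.character(classify_lic_level(max(med, 0))),
                 n_pixels = length(v)),
            class = "lic_summary")
}

#' @export
print.lic_summary <- function(x, ...) {
  cat(sprintf(
    "LIC summary (%d px): median %.2f [Q1 %.2f, Q3 %.2f] mg/g dw, nIQR %.1f%%, %s\n",
    x$n_pixels, x$median, x$q1, x$q3, x$niqr, x$level))
  invisible(x)
}

#' Coefficient of variation of paired differences (agreement)
#'
#' Agreement between two paired measurement series, expressed as
#' `1.96 * SD(a - b) / mean(c(a, b)) * 100` (percent), with the bias
#' `mean(a - b)` reported alongside. The SD uses the sample (n-1)
#' denominator.
#'
#' @param a,b Numeric vectors of equal length (>= 2) holding paired
#'   measurements of the same quantity by two methods.
#' @return A list with `cv` (percent), `bias`, `sd_diff`, and `n`.
#' @export
cv_agreement <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("paired series must have equal length", call. = FALSE)
  if (length(a) < 2L)
    stop("need at least 2 pairs", call. = FALSE)
  grand_mean <- mean(c(a, b))
  if (grand_mean == 0)
    stop("CV is undefined when the grand mean is zero", call. = FALSE)
  d <- a - b
  list(cv = 1.96 * stats::sd(d) / grand_mean * 100,
       bias = mean(d), sd_diff = stats::sd(d), n = length(a))
}
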