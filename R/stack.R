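#' Multi-echo gradient-echo image stack
#'
#' Container for a single-slice multi-echo T2*-weighted acquisition: one 2D
#' intensity image per echo plus the echo-time list. All downstream R2*
#' fitting and segmentation operates on this object.
#'
#' @param echoes Either a list of 2D numeric matrices (one per echo, all the
#'   same dimensions) or a 3D numeric array with the echo index on the third
#'   axis. Intensities must be finite and non-negative (magnitude images).
#' @param te_ms Numeric vector of echo times in milliseconds, strictly
#'   increasing, one per echo. At least 3 echoes are required for the
#'   three-parameter C-EXP fit.
#'
#' @return An object of class `multi_echo_stack` with elements `echoes`
#'   (list of matrices), `te_ms`, and `shape` (`c(rows, cols)`).
#' @export
#' @examples
#' te <- default_te_grid()
#' img <- matrix(100, 8, 8)
#' stk <- multi_echo_stack(replicate(20, img, simplify = FALSE), te)
#' stk$shape
multi_echo_stack <- function(echoes, te_ms) {
  if (is.array(echoes) && length(dim(echoes)) == 3L) {
    echoes <- lapply(seq_len(dim(echoes)[3L]), function(e) echoes[, , e])
  }
  if (!is.list(echoes) || length(echoes) < 3L)
    stop("`echoes` must be a list of >= 3 echo images", call. = FALSE)
  te_ms <- as.numeric(te_ms)
  if (length(echoes) != length(te_ms))
    stop(sprintf("number of echo images (%d) != number of echo times (%d)",
                 length(echoes), length(te_ms)), call. = FALSE)
  if (any(!is.finite(te_ms)) || any(diff(te_ms) <= 0))
    stop("`te_ms` must be finite and strictly increasing", call. = FALSE)
  shape <- dim(echoes[[1L]])
  for (e in seq_along(echoes)) {
    img <- echoes[[e]]
    if (!is.matrix(img) || !identical(dim(img), shape))
      stop(sprintf("echo %d has dimensions %s; expected %s", e,
                   paste(dim(img), collapse = "x"),
                   paste(shape, collapse = "x")), call. = FALSE)
    if (any(!is.finite(img)))
      stop(sprintf("echo %d contains non-finite intensities", e),
           call. = FALSE)
    if (any(img < 0))
      stop(sprintf("echo %d contains negative intensities", e), call. = FALSE)
  }
  structure(list(echoes = echoes, te_ms = te_ms, shape = shape),
            class = "multi_echo_stack")
}

#' @export
print.multi_echo_stack <- function(x, ...) {
  cat(sprintf("multi_echo_stack: %d echoes, %dx%d pixels, TE %.2f-%.2f ms\n",
              length(x$echoes), x$shape[1L], x$shape[2L],
              x$te_ms[1L], x$te_ms[length(x$te_ms)]))
  invisible(x)
}

#' Default 20-echo acquisition grid
#'
#' Echo times of the breath-hold multi-echo gradient-recalled-echo protocol
#' this package targets: 20 echoes starting at 1.07 ms with 0.8 ms
#' increments (1.07, 1.87, ..., 16.27 ms).
#'
#' @return Numeric vector of 20 echo times in milliseconds.
#' @export
default_te_grid <- function() {
  1.07 + 0.8 * (0:19)
}

#' Stack a multi-echo object into a 3D array
#'
#' @param stack A [multi_echo_stack()].
#' @return Numeric array of dimension `c(rows, cols, n_echoes)`.
#' @export
stack_as_array <- function(stack) {
  stopifnot(inherits(stack, "multi_echo_stack"))
  array(unlist(stack$echoes, use.names = FALSE),
        dim = c(stack$shape, length(stack$echoes)))
}

# Signal a degenerate-computation condition (CLI exit code 3), as opposed
# to a plain input error (exit code 2).
stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("liverfcm_degenerate", "error")))
}

# Validate an ROI mask against a stack; returns a logical matrix.
check_roi <- function(stack, roi, allow_empty = FALSE) {
  if (is.numeric(roi)) roi <- roi != 0
  if (!is.matrix(roi) || !identical(dim(roi), stack$shape))
    stop(sprintf("ROI dimensions %s do not match stack dimensions %s",
                 paste(dim(roi), collapse = "x"),
                 paste(stack$shape, collapse = "x")), call. = FALSE)
  roi[is.na(roi)] <- FALSE
  if (!allow_empty && !any(roi))
    stop("ROI mask is empty", call. = FALSE)
  roi
}
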