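#' Read a multi-echo study from disk
#'
#' Loads a study from a NIfTI stack (echo on the third axis), an echo-time
#' sidecar (YAML or JSON list of echo times in milliseconds), an ROI label
#' map, and optionally a reference segmentation label map (0 outside,
#' 1 parenchyma, 2 vessel). All shapes are validated against each other.
#'
#' @param stack Path to the multi-echo NIfTI file.
#' @param tes Path to the echo-time sidecar (`.yaml`/`.yml` or `.json`);
#'   either a bare list of times or a mapping with a `te_ms` key.
#' @param roi Path to the ROI NIfTI (non-zero = inside).
#' @param reference Optional path to a reference segmentation NIfTI.
#' @return A list with `stack` (a [multi_echo_stack()]), `roi` (logical
#'   matrix), and `reference` (a `segmentation_mask` or `NULL`).
#' @export
read_study <- function(stack, tes, roi, reference = NULL) {
  for (p in c(stack, tes, roi, reference))
    if (!file.exists(p))
      stop(sprintf("file not found: %s", p), call. = FALSE)
  vol <- drop(as.array(RNifti::readNifti(stack)))
  if (length(dim(vol)) != 3L)
    stop(sprintf("expected a 3D stack (echo as 3rd axis), got %s in %s",
                 paste(dim(vol), collapse = "x"), stack), call. = FALSE)
  te_ms <- read_te_sidecar(tes)
  if (length(te_ms) != dim(vol)[3L])
    stop(sprintf("TE sidecar lists %d echo times but stack has %d echoes",
                 length(te_ms), dim(vol)[3L]), call. = FALSE)
  stk <- multi_echo_stack(vol, te_ms)
  roi_img <- read_mask_2d(roi)
  roi_mask <- check_roi(stk, roi_img)
  ref <- NULL
  if (!is.null(reference)) {
    lab <- read_mask_2d(reference)
    if (!identical(dim(lab), stk$shape))
      stop(sprintf("reference shape %s does not match stack shape %s",
                   paste(dim(lab), collapse = "x"),
                   paste(stk$shape, collapse = "x")), call. = FALSE)
    ref <- segmentation_mask(matrix(as.integer(round(lab)), nrow(lab)),
                             source = "manual")
  }
  list(stack = stk, roi = roi_mask, reference = ref)
}

read_te_sidecar <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop(sprintf("unsupported TE sidecar format: .%s", ext),
                     call. = FALSE))
  te <- if (is.list(obj) && !is.null(obj$te_ms)) obj$te_ms else obj
  te <- as.numeric(unlist(te))
  if (length(te) < 3L || any(!is.finite(te)) || any(diff(te) <= 0))
    stop("TE sidecar must list >= 3 finite, strictly increasing echo times",
         call. = FALSE)
  te
}

read_mask_2d <- function(path) {
  img <- drop(as.array(RNifti::readNifti(path)))
  if (length(dim(img)) != 2L)
    stop(sprintf("expected a single-slice 2D image in %s, got %s",
                 path, paste(dim(img), collapse = "x")), call. = FALSE)
  matrix(as.numeric(img), nrow(img))
}

#' Write a phantom study to disk in the package's input formats
#'
#' Writes `stack.nii.gz`, `tes.yaml`, `roi.nii.gz`, `truth.nii.gz`
#' (0/1/2 label map), and `truth.json` (configuration echo plus the true
#' parenchyma parameters), so that a phantom round-trips through
#' [read_study()].
#'
#' @param study A `phantom_study`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_phantom_study <- function(study, dir) {
  stopifnot(inherits(study, "phantom_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stack = file.path(dir, "stack.nii.gz"),
             tes = file.path(dir, "tes.yaml"),
             roi = file.path(dir, "roi.nii.gz"),
             truth = file.path(dir, "truth.nii.gz"),
             meta = file.path(dir, "truth.json"))
  RNifti::writeNifti(stack_as_array(study$stack), paths[["stack"]])
  yaml::write_yaml(list(te_ms = as.numeric(study$stack$te_ms)),
                   paths[["tes"]])
  RNifti::writeNifti(study$roi * 1, paths[["roi"]])
  RNifti::writeNifti(study$truth$labels * 1, paths[["truth"]])
  cfg <- study$config
  cfg$calibration <- unclass(cfg$calibration)
  jsonlite::write_json(
    list(config = unclass(cfg),
         n_roi_pixels = sum(study$roi),
         n_vessel_pixels = sum(study$truth$labels == 2L),
         true_parenchyma_r2star =
           round(stats::median(study$true_r2star[study$truth$labels == 1L]),
                 4)),
    paths[["meta"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Write a machine-readable segmentation report
#'
#' Writes, into `dir`: `report.json` (configuration echo, best outcomes,
#' optional LIC summaries; floating point rounded to 4 decimals so repeated
#' runs are byte-identical), `candidates.csv` (the full per-candidate score
#' table: 1,000 rows per mode for an OP run, 50 per mode for SA), one NIfTI
#' label map per best outcome (0 outside, 1 parenchyma, 2 vessel; encoding
#' recorded in the report header), and `report_raw.rds` with the unrounded
#' object. Existing files are overwritten.
#'
#' @param result An `op_result` or `sa_result`.
#' @param dir Output directory.
#' @param summaries Optional named list of `lic_summary` objects to embed.
#' @param config Optional configuration echo (calibration, seeds, paths).
#' @return Invisibly, the path of `report.json`.
#' @export
write_report <- function(result, dir, summaries = NULL, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_op <- inherits(result, "op_result")
  if (!is_op && !inherits(result, "sa_result"))
    stop("result must be an op_result or sa_result", call. = FALSE)

  outcome_row <- function(o) list(
    method = o$method, scheme = o$scheme, te_index = o$te_index,
    te_ms = round(o$te_ms, 4), u0 = round(o$u0, 4),
    tsa_parenchyma_pct = round4_or_null(o$tsa_parenchyma),
    tsa_vessels_pct = round4_or_null(o$tsa_vessels),
    d_tsa_pct = round4_or_null(o$d_tsa))

  if (is_op) {
    candidates <- result$candidates
    best <- list(best_1d = result$best_1d, best_2d = result$best_2d,
                 mix = result$mix)
    scheme <- "OP"
    extra <- list(n_candidates = as.list(result$n_candidates),
                  n_skipped = length(result$skipped))
  } else {
    candidates <- rbind(result$candidates_1d, result$candidates_2d)
    best <- if (is.null(result$chosen)) list() else
      list(chosen = result$chosen)
    scheme <- "SA"
    extra <- list(rnr_selected_te_index = result$te_index,
                  rnr_selected_te_ms = round(result$te_ms, 4),
                  rnr = round(result$rnr$rnr, 4),
                  noise_sd = round(result$rnr$noise_sd, 4))
  }
  num <- vapply(candidates, is.numeric, logical(1L))
  candidates[num] <- lapply(candidates[num], round, digits = 4)
  csv_path <- file.path(dir, "candidates.csv")
  utils::write.csv(candidates, csv_path, row.names = FALSE)

  mask_files <- character(0)
  for (nm in names(best)) {
    f <- file.path(dir, sprintf("mask_%s.nii.gz", nm))
    RNifti::writeNifti(best[[nm]]$mask$labels * 1, f)
    mask_files[nm] <- basename(f)
  }
  report <- c(list(
    scheme = scheme,
    label_encoding = list(outside = 0, parenchyma = 1, vessel = 2),
    config = config,
    best = lapply(best, outcome_row),
    candidates_csv = basename(csv_path),
    mask_files = as.list(mask_files)),
    extra)
  if (!is.null(summaries))
    report$lic_summaries <- lapply(summaries, function(s) list(
      median_lic = round(s$median, 4), q1 = round(s$q1, 4),
      q3 = round(s$q3, 4), niqr_pct = round(s$niqr, 4),
      level = s$level, n_pixels = s$n_pixels))
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  saveRDS(list(result = result, summaries = summaries, config = config),
          file.path(dir, "report_raw.rds"))
  invisible(json_path)
}

round4_or_null <- function(x) if (is.na(x)) NULL else round(x, 4)

# PNG contact sheet for the SA gallery: one panel per (mode, threshold).
write_sa_gallery <- function(cands, roi, thresholds, stack, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (mode in names(cands)) {
    cand <- cands[[mode]]
    for (t in seq_along(thresholds)) {
      mask <- defuzzify(cand$result, cand$vessel_idx, thresholds[t],
                        cand$features, roi, source = paste0(mode, "-FCM"))
      f <- file.path(out_dir, sprintf("sa_%s_%02d_u%.2f.png", mode, t,
                                      thresholds[t]))
      grDevices::png(f, width = 256, height = 256)
      graphics::par(mar = c(0, 0, 2, 0))
      graphics::image(mask$labels, col = c("black", "grey40", "red"),
                      zlim = c(0, 2), axes = FALSE, useRaster = TRUE,
                      main = sprintf("%s  u0=%.2f  [%02d]", mode,
                                     thresholds[t], t))
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  files
}
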