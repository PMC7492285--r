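# NIfTI + JSON-sidecar input/output for acquisition series, truth maps and
# masks, and the study's on-disk layout.

#' Write an acquisition series as NIfTI plus JSON sidecar
#'
#' @param series an [acq_series()].
#' @param prefix file path prefix (without extension); writes
#'   `<prefix>.nii.gz` and `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
write_series <- function(series, prefix) {
  stopifnot(inherits(series, "acq_series"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  img <- RNifti::asNifti(series$stack,
                         pixdim = c(series$pixel_spacing, series$pixel_spacing, 1))
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  sidecar <- c(list(modality = series$modality, times_ms = series$times,
                    pixel_spacing_mm = series$pixel_spacing),
               series$meta)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read an acquisition series written by [write_series()]
#'
#' Validates the sidecar against the stack: matching frame count,
#' non-negative strictly increasing times.
#'
#' @param prefix file path prefix (without extension) or the `.nii.gz` path.
#' @return An [acq_series()].
#' @export
read_series <- function(prefix) {
  prefix <- sub("\\.nii(\\.gz)?$", "", prefix)
  nii <- paste0(prefix, ".nii.gz")
  side <- paste0(prefix, ".json")
  if (!file.exists(nii)) qc_format_error(sprintf("missing image file: %s", nii))
  if (!file.exists(side)) qc_format_error(sprintf("missing JSON sidecar: %s", side))
  img <- RNifti::readNifti(nii)
  stack <- array(as.vector(img), dim = dim(img))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  times <- as.numeric(meta$times_ms)
  if (length(dim(stack)) != 3L || dim(stack)[3] != length(times)) {
    qc_format_error(sprintf("%s: sidecar lists %d times but stack has %d frames",
                            side, length(times), dim(stack)[3]))
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    qc_format_error(sprintf("%s: times must be non-negative and strictly increasing", side))
  }
  acq_series(stack = stack, times = times, modality = meta$modality,
             pixel_spacing = meta$pixel_spacing_mm,
             meta = meta[setdiff(names(meta),
                                 c("modality", "times_ms", "pixel_spacing_mm"))])
}

#' Write a fitted parameter map as NIfTI layers plus JSON provenance
#'
#' Layers: fitted value (ms), adjusted R-squared, validity (0/1).
#'
#' @param map a `parameter_map`.
#' @param prefix file path prefix.
#' @return The prefix, invisibly.
#' @export
write_parameter_map <- function(map, prefix) {
  stopifnot(inherits(map, "parameter_map"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  stack <- array(c(map$value, map$adj_r2, map$valid * 1),
                 dim = c(nrow(map$value), ncol(map$value), 3))
  RNifti::writeNifti(RNifti::asNifti(stack), paste0(prefix, ".nii.gz"))
  prov <- list(modality = map$modality, layers = c("value_ms", "adj_r2", "valid"),
               r2_threshold = map$options$r2_threshold,
               cutoff_ms = map$options$cutoff,
               tau_bounds_ms = map$options$tau_bounds, meta = map$meta)
  jsonlite::write_json(prov, paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Write an ROI partition as a labelled NIfTI plus JSON legend
#'
#' @param partition an [partition_rois()] result.
#' @param prefix file path prefix.
#' @return The prefix, invisibly.
#' @export
write_roi_labels <- function(partition, prefix) {
  stopifnot(inherits(partition, "roi_partition"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(partition$labels + 0), paste0(prefix, ".nii.gz"))
  jsonlite::write_json(
    list(legend = list(`1` = "SPA_upper", `2` = "SPA_lower",
                       `3` = "PPA_upper", `4` = "PPA_lower"),
         counts = as.list(partition$counts)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

# Write every series, truth field and mask of a study bundle; returns the
# manifest augmented with file paths.
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (id in names(study$samples)) {
    smp <- study$samples[[id]]
    for (ses in names(smp$series)) {
      for (lv in names(smp$series[[ses]])) {
        truth <- smp$truths[[ses]][[lv]]
        mdir <- file.path(out_dir, id, ses, lv)
        RNifti::writeNifti(RNifti::asNifti(truth$mask * 1),
                           file.path(mdir, "mask.nii.gz"))
        tstack <- array(unlist(truth$params, use.names = FALSE),
                        dim = c(nrow(truth$mask), ncol(truth$mask), 4))
        dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
        RNifti::writeNifti(RNifti::asNifti(tstack),
                           file.path(mdir, "truth.nii.gz"))
        for (mod in names(smp$series[[ses]][[lv]])) {
          prefix <- file.path(mdir, mod)
          write_series(smp$series[[ses]][[lv]][[mod]], prefix)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample_id = id, arm = smp$spec$arm, seed = smp$spec$seed,
            session = ses, load_level = lv, modality = mod,
            path = paste0(prefix, ".nii.gz"))
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
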