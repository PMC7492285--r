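#' Segmentation mask container
#'
#' A binary cartilage segmentation on the acquisition raster together with
#' the piston geometry needed to build regional ROIs.
#'
#' @param mask logical matrix (rows x cols), at least one `TRUE` pixel.
#' @param pixel_spacing mm per pixel edge.
#' @param piston_center_col column index of the piston centre.
#' @param piston_width piston diameter in mm.
#' @param spa_width width of the sub-pistonal band in mm (must not exceed
#'   the piston width).
#' @param load_level,session metadata tags.
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(mask, pixel_spacing, piston_center_col,
                     piston_width = 10.0, spa_width = 8.0,
                     load_level = "delta0", session = "pre") {
  if (!is.logical(mask) || !is.matrix(mask)) qc_validation_error("mask must be a logical matrix")
  if (!any(mask)) qc_validation_error("mask must contain at least one pixel")
  if (piston_center_col < 1 || piston_center_col > ncol(mask)) {
    qc_validation_error("piston_center_col outside the grid")
  }
  sample_width <- sum(colSums(mask) > 0) * pixel_spacing
  if (spa_width > piston_width) {
    qc_validation_error("spa_width must not exceed piston_width")
  }
  if (piston_width > sample_width + pixel_spacing / 2) {
    qc_validation_error("piston_width must not exceed the sample width")
  }
  structure(list(mask = mask, pixel_spacing = pixel_spacing,
                 piston_center_col = as.integer(piston_center_col),
                 piston_width = piston_width, spa_width = spa_width,
                 load_level = load_level, session = session),
            class = "seg_mask")
}

#' Segmentation mask from a phantom truth
#' @param truth a `truth_fields` object.
#' @param spa_width sub-pistonal band width in mm.
#' @param piston_width piston diameter in mm.
#' @return A [seg_mask()].
#' @export
mask_from_truth <- function(truth, spa_width = 8.0, piston_width = 10.0) {
  seg_mask(truth$mask, truth$pixel_spacing, truth$piston_center_col,
           piston_width = piston_width, spa_width = spa_width,
           load_level = truth$load_level, session = truth$session)
}

#' Per-column cartilage heights
#'
#' @param sm a [seg_mask()].
#' @return Numeric vector (one entry per column) of `pixel count *
#'   pixel_spacing` in mm; empty columns give 0.
#' @export
column_heights <- function(sm) {
  stopifnot(inherits(sm, "seg_mask"))
  colSums(sm$mask) * sm$pixel_spacing
}

#' Caliper-style three-position height measurement
#'
#' Measures the column height at the piston centre and at the columns
#' nearest to +/- 2 mm laterally (offset `round(2 / pixel_spacing)` columns),
#' mimicking a digital caliper with single-pixel resolution.
#'
#' @param sm a [seg_mask()].
#' @return List of class `height_measurement` with `heights` (named vector:
#'   `minus2mm`, `center`, `plus2mm`, in mm) and their `mean`.
#' @export
caliper_heights <- function(sm) {
  stopifnot(inherits(sm, "seg_mask"))
  off <- round(2 / sm$pixel_spacing)
  cols <- c(minus2mm = sm$piston_center_col - off,
            center = sm$piston_center_col,
            plus2mm = sm$piston_center_col + off)
  ch <- column_heights(sm)
  h <- numeric(3)
  for (i in seq_along(cols)) {
    j <- cols[i]
    if (j < 1 || j > ncol(sm$mask) || ch[j] == 0) {
      qc_measurement_error(sprintf("caliper position '%s' (column %d) is empty",
                                   names(cols)[i], j))
    }
    h[i] <- ch[j]
  }
  names(h) <- names(cols)
  structure(list(heights = h, mean = mean(h)), class = "height_measurement")
}

#' Remove boundary pixels at the articular surface and the deep interface
#'
#' Per non-empty column, the topmost (towards piston or bathing medium) and
#' lowermost (towards the subchondral lamella) in-mask pixels are removed to
#' limit partial-volume effects. Columns of height <= 2 become empty; their
#' count is attached as attribute `n_emptied`.
#'
#' @param sm a [seg_mask()].
#' @return A [seg_mask()] with the eroded mask.
#' @export
exclude_boundaries <- function(sm) {
  stopifnot(inherits(sm, "seg_mask"))
  m <- sm$mask
  emptied <- 0L
  for (j in seq_len(ncol(m))) {
    rows <- which(m[, j])
    if (!length(rows)) next
    m[min(rows), j] <- FALSE
    m[max(rows), j] <- FALSE
    if (!any(m[, j])) emptied <- emptied + 1L
  }
  out <- sm
  out$mask <- m
  attr(out, "n_emptied") <- emptied
  out
}

#' Partition a mask into the seven zonal/regional ROIs
#'
#' The sub-pistonal area (SPA) is the band of `round(spa_width /
#' pixel_spacing)` columns centred on the piston centre (for an even band
#' width the extra column goes to the right); the peri-pistonal area (PPA)
#' merges all remaining in-mask pixels on both sides. Each region is split
#' into an upper (superficial) and lower (deep) half per column, the upper
#' half holding the `ceiling(h/2)` shallowest pixels. The seven ROIs are the
#' entire cartilage sample (ECS), SPA, PPA and the four half-thickness
#' leaves.
#'
#' @param sm a [seg_mask()], typically after [exclude_boundaries()].
#' @return An object of class `roi_partition` with `rois` (named list of
#'   logical matrices), `counts` (named integer vector) and `labels`
#'   (integer matrix coding SPA_upper = 1, SPA_lower = 2, PPA_upper = 3,
#'   PPA_lower = 4).
#' @export
partition_rois <- function(sm) {
  stopifnot(inherits(sm, "seg_mask"))
  if (!any(sm$mask)) qc_validation_error("mask is empty")
  n_band <- as.integer(round(sm$spa_width / sm$pixel_spacing))
  band <- spa_band_columns(sm$piston_center_col, n_band, ncol(sm$mask))
  if (!any(sm$mask[, band])) {
    qc_geometry_error("sub-pistonal band lies fully outside the mask")
  }
  lab <- leaf_labels(sm$mask, sm$piston_center_col, n_band)
  rois <- list(
    ECS = sm$mask,
    SPA = lab == 1L | lab == 2L,
    PPA = lab == 3L | lab == 4L,
    SPA_upper = lab == 1L, SPA_lower = lab == 2L,
    PPA_upper = lab == 3L, PPA_lower = lab == 4L
  )
  counts <- vapply(rois, sum, integer(1))
  structure(list(rois = rois, counts = counts, labels = lab,
                 spa_columns = band, pixel_spacing = sm$pixel_spacing,
                 load_level = sm$load_level, session = sm$session),
            class = "roi_partition")
}

#' ROI names in reporting order
#' @return Character vector of the seven ROI names.
#' @export
roi_names <- function() c("ECS", "SPA", "SPA_upper", "SPA_lower",
                          "PPA", "PPA_upper", "PPA_lower")
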