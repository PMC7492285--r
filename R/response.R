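#' Mean parameter value over an ROI
#'
#' Arithmetic mean of the fitted time constant over the quality-valid pixels
#' of the ROI (pixels failing the adjusted-R-squared gate are skipped).
#'
#' @param map a `parameter_map` from [fit_map()].
#' @param roi logical matrix selecting the ROI's pixels.
#' @return List with `mean` (ms) and `n_valid` (pixels contributing).
#' @export
roi_mean <- function(map, roi) {
  stopifnot(inherits(map, "parameter_map"))
  if (!any(roi)) qc_empty_roi_error("ROI contains no pixels")
  sel <- roi & map$valid
  n <- sum(sel)
  if (n == 0) qc_empty_roi_error("ROI contains no valid pixels")
  list(mean = mean(map$value[sel]), n_valid = n)
}

#' Summarize a parameter map over the seven ROIs
#'
#' @param map a `parameter_map`.
#' @param partition an [partition_rois()] result.
#' @param meta named list of identifiers (sample_id, arm, session,
#'   load_level) merged into each row.
#' @return A tibble with one row per ROI: identifiers, `modality`, `roi`,
#'   `mean`, `n_valid` and `n_roi` (ROI pixel count). ROIs without valid
#'   pixels yield `NA` means.
#' @export
roi_summaries <- function(map, partition, meta = list()) {
  stopifnot(inherits(partition, "roi_partition"))
  rows <- lapply(roi_names(), function(rn) {
    roi_px <- partition$rois[[rn]]
    res <- tryCatch(roi_mean(map, roi_px),
                    qc_empty_roi_error = function(e) list(mean = NA_real_, n_valid = 0L))
    tibble::tibble(roi = rn, mean = res$mean, n_valid = as.integer(res$n_valid),
                   n_roi = as.integer(sum(roi_px)))
  })
  out <- dplyr::bind_rows(rows)
  out$modality <- map$modality
  out$parameter <- modality_parameter(map$modality)
  for (nm in rev(names(meta))) out[[nm]] <- meta[[nm]]
  dplyr::relocate(out, dplyr::any_of(c("sample_id", "arm", "session",
                                       "load_level", "modality", "parameter")))
}

#' Relative change in percent
#'
#' `((value / reference) - 1) * 100`, the definition used for all response
#' statistics (post vs pre at rest, and loaded vs unloaded within a session).
#'
#' @param value,reference numeric vectors (reference must be positive).
#' @return Percent change.
#' @examples
#' delta_pct(87.9, 100) # -12.1
#' @export
delta_pct <- function(value, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    qc_validation_error("reference must be positive")
  }
  (value / reference - 1) * 100
}

#' Build per-sample response records from ROI summaries
#'
#' For every sample x modality x ROI: `delta_0` compares the unloaded
#' post-exposure mean with the unloaded pre-exposure mean; `delta_1_pre`,
#' `delta_2_pre`, `delta_1_post` and `delta_2_post` compare each session's
#' loaded means with that session's own unloaded mean. A delta is computed
#' only when both operand means exist; missing combinations are listed in
#' the `skipped` attribute rather than raised.
#'
#' @param summaries tibble from [roi_summaries()] rows (columns `sample_id`,
#'   `arm`, `session`, `load_level`, `modality`, `roi`, `mean`).
#' @return Tibble with one row per sample x modality x ROI and the five
#'   delta columns (percent), with attribute `skipped`.
#' @export
build_delta_records <- function(summaries) {
  need <- c("sample_id", "arm", "session", "load_level", "modality", "roi", "mean")
  if (!all(need %in% names(summaries))) {
    qc_validation_error("summaries must carry sample_id, arm, session, load_level, modality, roi, mean")
  }
  wide <- summaries |>
    dplyr::mutate(cfg = paste(.data$session, .data$load_level, sep = ".")) |>
    dplyr::select(dplyr::all_of(c("sample_id", "arm", "modality", "roi", "cfg", "mean"))) |>
    tidyr::pivot_wider(names_from = "cfg", values_from = "mean")
  col <- function(nm) if (nm %in% names(wide)) wide[[nm]] else rep(NA_real_, nrow(wide))
  safe_delta <- function(v, r) {
    ok <- is.finite(v) & is.finite(r) & r > 0
    out <- rep(NA_real_, length(v))
    out[ok] <- delta_pct(v[ok], r[ok])
    out
  }
  d0_pre <- col("pre.delta0"); d0_post <- col("post.delta0")
  rec <- tibble::tibble(
    sample_id = wide$sample_id, arm = wide$arm,
    modality = wide$modality, roi = wide$roi,
    delta_0 = safe_delta(d0_post, d0_pre),
    delta_1_pre = safe_delta(col("pre.delta1"), d0_pre),
    delta_2_pre = safe_delta(col("pre.delta2"), d0_pre),
    delta_1_post = safe_delta(col("post.delta1"), d0_post),
    delta_2_post = safe_delta(col("post.delta2"), d0_post)
  )
  dcols <- c("delta_0", "delta_1_pre", "delta_2_pre", "delta_1_post", "delta_2_post")
  skipped <- rec |>
    tidyr::pivot_longer(dplyr::all_of(dcols), names_to = "delta", values_to = "value") |>
    dplyr::filter(!is.finite(.data$value)) |>
    dplyr::select(-"value")
  attr(rec, "skipped") <- skipped
  rec
}

#' Mankin histological score
#'
#' Semi-quantitative cartilage degeneration score: tissue structure (0-6),
#' cellularity (0-3), proteoglycan staining intensity (0-4) and tidemark
#' integrity (0-1). The sum (0-14) maps to grades MG0 (0-4), MGI (5-8),
#' MGII (9-10) and MGIII (11-14).
#'
#' @param structure,cellularity,staining,tidemark integer subscores.
#' @return List of class `mankin_score` with the subscores, `sum`, `grade`
#'   (factor MG0-MGIII) and `grade_int` (0-3).
#' @examples
#' mankin(1, 1, 0, 0)$grade # MG0
#' @export
mankin <- function(structure, cellularity, staining, tidemark) {
  chk <- function(x, lo, hi, nm) {
    if (!is_scalar_number(x) || x != round(x) || x < lo || x > hi) {
      qc_validation_error(sprintf("%s must be an integer in [%d, %d]", nm, lo, hi))
    }
    as.integer(x)
  }
  structure_s <- chk(structure, 0, 6, "structure")
  cellularity <- chk(cellularity, 0, 3, "cellularity")
  staining <- chk(staining, 0, 4, "staining")
  tidemark <- chk(tidemark, 0, 1, "tidemark")
  s <- structure_s + cellularity + staining + tidemark
  structure(list(structure = structure_s, cellularity = cellularity,
                 staining = staining, tidemark = tidemark, sum = s,
                 grade = mankin_grade(s),
                 grade_int = match(mankin_grade(s), c("MG0", "MGI", "MGII", "MGIII")) - 1L),
            class = "mankin_score")
}

#' Mankin grade from a sum score
#'
#' @param sum integer Mankin sum score in 0-14.
#' @return `"MG0"` (0-4), `"MGI"` (5-8), `"MGII"` (9-10) or `"MGIII"` (11-14).
#' @export
mankin_grade <- function(sum) {
  if (!is_scalar_number(sum) || sum != round(sum) || sum < 0 || sum > 14) {
    qc_validation_error("sum must be an integer in [0, 14]")
  }
  if (sum <= 4) "MG0" else if (sum <= 8) "MGI" else if (sum <= 10) "MGII" else "MGIII"
}
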