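#' Study report tables
#'
#' Builds the two study-style report tables from ROI summaries and delta
#' records:
#'
#' * `table1` — per arm x modality x ROI the group mean and SD of `delta_0`
#'   (post- vs pre-exposure change at rest) with the Wilcoxon matched-pairs
#'   p value comparing the unloaded pre- and post-exposure ROI means;
#' * `table2` — per arm x modality x ROI the group means and SDs of
#'   `delta_1`/`delta_2` in both sessions with paired t p values for
#'   pre- vs post-exposure loading responses.
#'
#' Both raw and Holm-adjusted p values are reported; the adjustment family
#' defaults to one family per modality per table (configurable). Cells with
#' fewer than two samples report the mean with a missing SD.
#'
#' @param summaries ROI summary tibble (see [roi_summaries()]).
#' @param deltas delta record tibble from [build_delta_records()].
#' @param alpha family-wise significance level (default 0.01).
#' @param family Holm family definition: `"modality"` (default), `"table"`
#'   (one family per table) or `"none"`.
#' @return List of class `study_tables` with `table1`, `table2`, `alpha`,
#'   `family`.
#' @export
study_tables <- function(summaries, deltas, alpha = 0.01,
                         family = c("modality", "table", "none")) {
  family <- match.arg(family)
  if (alpha <= 0 || alpha >= 1) qc_config_error("alpha must lie in (0, 1)")

  msd <- function(v) {
    v <- v[is.finite(v)]
    tibble::tibble(mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) >= 2) sd(v) else NA_real_,
                   n = length(v))
  }

  # table1: delta_0 cells + Wilcoxon on paired unloaded ROI means.
  d0_pairs <- summaries |>
    dplyr::filter(.data$load_level == "delta0") |>
    dplyr::select(dplyr::all_of(c("sample_id", "arm", "modality", "roi",
                                  "session", "mean"))) |>
    tidyr::pivot_wider(names_from = "session", values_from = "mean")
  t1 <- deltas |>
    dplyr::group_by(.data$arm, .data$modality, .data$roi) |>
    dplyr::reframe(msd(.data$delta_0)) |>
    dplyr::rowwise() |>
    dplyr::mutate(p_raw = {
      pr <- d0_pairs[d0_pairs$arm == .data$arm & d0_pairs$modality == .data$modality &
                       d0_pairs$roi == .data$roi, ]
      if (!all(c("pre", "post") %in% names(pr)) || nrow(pr) < 2) NA_real_
      else wilcoxon_matched(pr$pre, pr$post)$p_value
    }) |>
    dplyr::ungroup()

  # table2: loading-response cells + paired t on pre vs post deltas.
  t2 <- deltas |>
    dplyr::group_by(.data$arm, .data$modality, .data$roi) |>
    dplyr::summarise(
      delta_1_pre_mean = mean(.data$delta_1_pre[is.finite(.data$delta_1_pre)]),
      delta_1_pre_sd = sd(.data$delta_1_pre[is.finite(.data$delta_1_pre)]),
      delta_2_pre_mean = mean(.data$delta_2_pre[is.finite(.data$delta_2_pre)]),
      delta_2_pre_sd = sd(.data$delta_2_pre[is.finite(.data$delta_2_pre)]),
      delta_1_post_mean = mean(.data$delta_1_post[is.finite(.data$delta_1_post)]),
      delta_1_post_sd = sd(.data$delta_1_post[is.finite(.data$delta_1_post)]),
      delta_2_post_mean = mean(.data$delta_2_post[is.finite(.data$delta_2_post)]),
      delta_2_post_sd = sd(.data$delta_2_post[is.finite(.data$delta_2_post)]),
      n = dplyr::n(),
      p_raw_delta1 = tryCatch(
        paired_t(.data$delta_1_pre, .data$delta_1_post)$p_value,
        error = function(e) NA_real_),
      p_raw_delta2 = tryCatch(
        paired_t(.data$delta_2_pre, .data$delta_2_post)$p_value,
        error = function(e) NA_real_),
      .groups = "drop"
    )

  adjust_by <- function(tab, p_cols) {
    key <- switch(family,
                  modality = tab$modality,
                  table = rep("all", nrow(tab)),
                  none = NULL)
    for (pc in p_cols) {
      ac <- sub("p_raw", "p_holm", pc)
      sc <- sub("p_raw", "significant", pc)
      if (is.null(key)) {
        tab[[ac]] <- tab[[pc]]
      } else {
        tab[[ac]] <- NA_real_
        for (k in unique(key)) {
          i <- which(key == k)
          tab[[ac]][i] <- holm_adjust(tab[[pc]][i], alpha)$adjusted
        }
      }
      tab[[sc]] <- !is.na(tab[[ac]]) & tab[[ac]] <= alpha
    }
    tab
  }
  t1 <- adjust_by(t1, "p_raw")
  t2 <- adjust_by(t2, c("p_raw_delta1", "p_raw_delta2"))

  ord <- function(tab) {
    tab$roi <- factor(tab$roi, levels = roi_names())
    tab$modality <- factor(tab$modality, levels = qmri_modalities())
    dplyr::arrange(tab, .data$modality, .data$arm, .data$roi)
  }
  structure(list(table1 = ord(t1), table2 = ord(t2), alpha = alpha,
                 family = family),
            class = "study_tables")
}
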