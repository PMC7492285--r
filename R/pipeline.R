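#' Study configuration
#'
#' Collects every tunable of an end-to-end phantom study run. Can also be
#' built from a YAML or JSON file via [read_study_config()].
#'
#' @param arms named sample counts per exposure arm.
#' @param seed master seed; every downstream random draw derives from it.
#' @param modalities,sessions,loads design subsets.
#' @param spec_args [phantom_spec()] overrides (grid size, noise, ...).
#' @param r2_threshold adjusted-R-squared validity gate.
#' @param te_cutoff echo-time cutoff (ms) for T2/T2*.
#' @param alpha family-wise significance level.
#' @param holm_family Holm family definition (see [study_tables()]).
#' @param out_dir output directory for CSV results (`NULL`: nothing written).
#' @param write_series also write all NIfTI series under `out_dir`.
#' @return A list of class `study_config`.
#' @export
study_config <- function(arms = c(control = 9, LT = 10, HT = 10),
                         seed = 1L,
                         modalities = qmri_modalities(),
                         sessions = c("pre", "post"),
                         loads = c("delta0", "delta1", "delta2"),
                         spec_args = list(),
                         r2_threshold = 0.95, te_cutoff = 60,
                         alpha = 0.01, holm_family = "modality",
                         out_dir = NULL, write_series = FALSE) {
  if (alpha <= 0 || alpha >= 1) qc_config_error("alpha must lie in (0, 1)")
  if (!is_scalar_number(seed) || seed != round(seed)) {
    qc_config_error("seed must be an integer")
  }
  structure(list(arms = arms, seed = as.integer(seed), modalities = modalities,
                 sessions = sessions, loads = loads, spec_args = spec_args,
                 r2_threshold = r2_threshold, te_cutoff = te_cutoff,
                 alpha = alpha, holm_family = holm_family,
                 out_dir = out_dir, write_series = write_series),
            class = "study_config")
}

#' Read a study configuration from YAML or JSON
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) qc_format_error(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$arms)) raw$arms <- unlist(raw$arms)
  do.call(study_config, raw)
}

#' Fit, partition and summarize a simulated study
#'
#' For every sample x session x load: builds the segmentation mask from the
#' truth, removes boundary pixels, partitions the seven ROIs, fits each
#' requested modality and aggregates per-ROI means of quality-valid pixels.
#' Also collects the three-position caliper heights per configuration.
#'
#' @param study a study bundle from [generate_study()].
#' @param r2_threshold,te_cutoff quality-control settings (see
#'   [fit_options()]).
#' @return List with `summaries` (ROI means, one row per sample x session x
#'   load x modality x ROI) and `heights` (one row per sample x session x
#'   load: caliper mean, in mm).
#' @export
summarize_study <- function(study, r2_threshold = 0.95, te_cutoff = 60) {
  sum_rows <- list(); h_rows <- list()
  for (id in names(study$samples)) {
    smp <- study$samples[[id]]
    for (ses in names(smp$series)) {
      for (lv in names(smp$series[[ses]])) {
        truth <- smp$truths[[ses]][[lv]]
        sm <- mask_from_truth(truth, spa_width = smp$spec$spa_width,
                              piston_width = smp$spec$piston_width)
        cal <- caliper_heights(sm)
        h_rows[[length(h_rows) + 1L]] <- tibble::tibble(
          sample_id = id, arm = smp$spec$arm, session = ses, load_level = lv,
          height_mm = cal$mean, height_true_mm = truth$height_true_mm)
        eroded <- exclude_boundaries(sm)
        part <- partition_rois(eroded)
        for (mod in names(smp$series[[ses]][[lv]])) {
          opts <- fit_options(mod, cutoff = te_cutoff,
                              r2_threshold = r2_threshold)
          map <- tryCatch(
            fit_map(smp$series[[ses]][[lv]][[mod]], eroded$mask, opts),
            error = function(e) qc_stop(
              sprintf("fit stage failed for sample %s (%s %s %s): %s",
                      id, ses, lv, mod, conditionMessage(e)),
              "qc_pipeline_error"))
          sum_rows[[length(sum_rows) + 1L]] <- roi_summaries(
            map, part, meta = list(sample_id = id, arm = smp$spec$arm,
                                   session = ses, load_level = lv))
        }
      }
    }
  }
  list(summaries = dplyr::bind_rows(sum_rows),
       heights = dplyr::bind_rows(h_rows))
}

#' Run the end-to-end phantom study pipeline
#'
#' Simulate -> fit -> ROIs -> response deltas -> statistics -> report
#' tables. Deterministic given the master seed; with `out_dir` set, writes
#' `manifest.csv`, `summaries.csv`, `heights.csv`, `deltas.csv`,
#' `table1.csv`, `table2.csv` and `log.json` (package version, seed,
#' options).
#'
#' @param config a [study_config()] or a path to a YAML/JSON config file.
#' @return List with the study bundle's `manifest`, `summaries`, `heights`,
#'   `deltas`, `tables` (a [study_tables()] result) and `height_anova`
#'   (repeated-measures ANOVA of caliper heights across load levels, per
#'   session).
#' @export
run_pipeline <- function(config = study_config()) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  out_dir <- config$out_dir
  study <- generate_study(arms = config$arms, seed = config$seed,
                          modalities = config$modalities,
                          sessions = config$sessions, loads = config$loads,
                          spec_args = config$spec_args,
                          out_dir = if (isTRUE(config$write_series)) out_dir else NULL)
  res <- summarize_study(study, r2_threshold = config$r2_threshold,
                         te_cutoff = config$te_cutoff)
  deltas <- build_delta_records(res$summaries)
  tables <- study_tables(res$summaries, deltas, alpha = config$alpha,
                         family = config$holm_family)
  height_anova <- list()
  if (length(config$loads) >= 2) {
    for (ses in config$sessions) {
      wide <- res$heights |>
        dplyr::filter(.data$session == ses) |>
        dplyr::select(dplyr::all_of(c("sample_id", "load_level", "height_mm"))) |>
        tidyr::pivot_wider(names_from = "load_level", values_from = "height_mm")
      m <- as.matrix(wide[, -1, drop = FALSE])
      height_anova[[ses]] <- tryCatch(rm_anova(m), error = function(e) NULL)
    }
  }
  out <- list(manifest = study$manifest, summaries = res$summaries,
              heights = res$heights, deltas = deltas, tables = tables,
              height_anova = height_anova, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(x, nm) utils::write.csv(
      as.data.frame(x), file.path(out_dir, nm), row.names = FALSE, na = "")
    wcsv(study$manifest, "manifest.csv")
    wcsv(res$summaries, "summaries.csv")
    wcsv(res$heights, "heights.csv")
    wcsv(deltas, "deltas.csv")
    wcsv(tables$table1, "table1.csv")
    wcsv(tables$table2, "table2.csv")
    jsonlite::write_json(
      list(package = "qmricart",
           version = as.character(utils::packageVersion("qmricart")),
           seed = config$seed, alpha = config$alpha,
           r2_threshold = config$r2_threshold, te_cutoff = config$te_cutoff,
           arms = as.list(config$arms), modalities = config$modalities),
      file.path(out_dir, "log.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
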