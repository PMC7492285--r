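#' Phantom specification
#'
#' Describes one synthetic cartilage-on-bone cross-section and everything
#' needed to simulate its serial acquisition: raster geometry, truth height
#' distribution, depth-dependent relaxation profiles, exposure arm and its
#' multiplicative effects, the loading model, noise level and seed.
#'
#' Depth profiles are linear from a surface value (adjacent to the piston,
#' row 1) to a deep value (adjacent to the subchondral interface); defaults
#' are plausible 3.0 T cartilage magnitudes. Rician noise defaults to
#' sigma = s0/50, i.e. SNR 50 relative to the equilibrium signal.
#'
#' @param arm study arm: `"control"`, `"LT"` (low-dose trypsin) or `"HT"`
#'   (high-dose trypsin).
#' @param grid_rows,grid_cols raster size in pixels (each >= 16).
#' @param pixel_spacing pixel edge length in mm.
#' @param sample_width cartilage sample width in mm.
#' @param height_mean,height_sd truth cartilage thickness distribution (mm);
#'   defaults are arm-specific.
#' @param depth_profiles named list per parameter with `surface` and `deep`
#'   values (ms).
#' @param s0 equilibrium signal amplitude (arbitrary units).
#' @param ir_b inversion-efficiency factor of the inversion-recovery truth
#'   signal, in (0, 2].
#' @param exposure_multipliers per parameter x leaf-ROI multiplicative
#'   post-exposure factors; default [default_exposure_multipliers()].
#' @param load_model per load level strain fractions and session-specific
#'   loading multipliers; default [default_load_model()].
#' @param piston_width,spa_width piston diameter and sub-pistonal band width
#'   (mm).
#' @param noise_sigma Rician noise sigma in signal units.
#' @param seed integer seed for this sample.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(arm = c("control", "LT", "HT"),
                         grid_rows = 64, grid_cols = 128,
                         pixel_spacing = 0.232,
                         sample_width = 12.0,
                         height_mean = NULL, height_sd = NULL,
                         depth_profiles = list(
                           T1 = c(surface = 1200, deep = 900),
                           T1rho = c(surface = 60, deep = 40),
                           T2 = c(surface = 55, deep = 30),
                           T2star = c(surface = 35, deep = 20)
                         ),
                         s0 = 1000, ir_b = 1.95,
                         exposure_multipliers = NULL,
                         load_model = NULL,
                         piston_width = 10.0, spa_width = 8.0,
                         noise_sigma = s0 / 50,
                         seed = 1L) {
  arm <- match.arg(arm)
  hd <- default_height_distribution(arm)
  height_mean <- height_mean %||% unname(hd["mean"])
  height_sd <- height_sd %||% unname(hd["sd"])
  exposure_multipliers <- exposure_multipliers %||% default_exposure_multipliers(arm)
  load_model <- load_model %||% default_load_model(arm)

  spec <- structure(
    list(arm = arm, grid_rows = as.integer(grid_rows),
         grid_cols = as.integer(grid_cols),
         pixel_spacing = pixel_spacing, sample_width = sample_width,
         height_mean = height_mean, height_sd = height_sd,
         depth_profiles = depth_profiles, s0 = s0, ir_b = ir_b,
         exposure_multipliers = exposure_multipliers,
         load_model = load_model,
         piston_width = piston_width, spa_width = spa_width,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$grid_rows < 16 || spec$grid_cols < 16) {
    qc_config_error("grid_rows/grid_cols: grid dimensions must be at least 16 x 16")
  }
  if (!is_scalar_number(spec$pixel_spacing) || spec$pixel_spacing <= 0) {
    qc_config_error("pixel_spacing: must be a positive number (mm)")
  }
  if (spec$height_mean <= 4 * spec$pixel_spacing) {
    qc_config_error("height_mean: must exceed 4 * pixel_spacing")
  }
  if (spec$height_sd < 0) qc_config_error("height_sd: must be non-negative")
  if (spec$noise_sigma < 0) qc_config_error("noise_sigma: must be non-negative")
  if (spec$s0 <= 0) qc_config_error("s0: must be positive")
  if (spec$ir_b <= 0 || spec$ir_b > 2) qc_config_error("ir_b: must lie in (0, 2]")
  for (p in .qc_params) {
    pr <- spec$depth_profiles[[p]]
    if (is.null(pr) || any(pr <= 0)) {
      qc_config_error(sprintf("depth_profiles$%s: surface and deep values must be positive", p))
    }
    em <- spec$exposure_multipliers[[p]]
    if (is.null(em) || any(em <= 0)) {
      qc_config_error(sprintf("exposure_multipliers$%s: multipliers must be positive", p))
    }
  }
  lm_names <- names(spec$load_model)
  if ("delta0" %in% lm_names) {
    l0 <- spec$load_model$delta0
    if (any(c(l0$strain_spa, l0$strain_ppa) != 0)) {
      qc_config_error("load_model$delta0: the unloaded configuration cannot carry nonzero strain")
    }
  }
  for (lv in intersect(c("delta1", "delta2"), lm_names)) {
    l <- spec$load_model[[lv]]
    if (l$strain_spa <= 0 || l$strain_spa >= 1 || l$strain_ppa <= 0 || l$strain_ppa >= 1) {
      qc_config_error(sprintf("load_model$%s: strain fractions must lie in (0, 1)", lv))
    }
    for (ses in c("pre", "post")) {
      for (p in .qc_params) {
        if (any(l$multipliers[[ses]][[p]] <= 0)) {
          qc_config_error(sprintf("load_model$%s$multipliers$%s$%s: multipliers must be positive", lv, ses, p))
        }
      }
    }
  }
  invisible(spec)
}

# Leaf ROI label matrix shared by the phantom (where effects are injected)
# and the geometry module (where ROIs are measured): 1 SPA_upper, 2 SPA_lower,
# 3 PPA_upper, 4 PPA_lower, 0 background. Per column, the upper zone holds
# the ceil(h/2) shallowest in-mask pixels.
leaf_labels <- function(mask, piston_center_col, spa_cols_n) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  band <- spa_band_columns(piston_center_col, spa_cols_n, ncol(mask))
  for (j in seq_len(ncol(mask))) {
    rows <- which(mask[, j])
    h <- length(rows)
    if (h == 0L) next
    n_up <- ceiling(h / 2)
    upper <- rows[seq_len(n_up)]
    lower <- if (h > n_up) rows[(n_up + 1L):h] else integer(0)
    if (j %in% band) {
      lab[upper, j] <- 1L
      lab[lower, j] <- 2L
    } else {
      lab[upper, j] <- 3L
      lab[lower, j] <- 4L
    }
  }
  lab
}

# Columns of the sub-pistonal band, centred on the piston centre column.
# For an even band width the extra column goes to the right.
spa_band_columns <- function(center, n, ncol_grid) {
  if (n %% 2 == 1) {
    cols <- (center - (n - 1L) / 2):(center + (n - 1L) / 2)
  } else {
    cols <- (center - n / 2 + 1L):(center + n / 2)
  }
  cols[cols >= 1L & cols <= ncol_grid]
}

# Core field constructor: rebuilds all truth fields for given per-column
# pixel heights, exposure state and load level.
build_fields <- function(spec, heights_px, load_level, session) {
  nr <- spec$grid_rows; nc <- spec$grid_cols
  mask <- matrix(FALSE, nr, nc)
  params <- lapply(setNames(.qc_params, .qc_params), function(p) matrix(NA_real_, nr, nc))
  for (j in seq_len(nc)) {
    h <- heights_px[j]
    if (h <= 0L) next
    h <- min(h, nr)
    mask[seq_len(h), j] <- TRUE
    for (p in .qc_params) {
      pr <- spec$depth_profiles[[p]]
      v <- if (h == 1L) pr[["surface"]] else
        pr[["surface"]] + (pr[["deep"]] - pr[["surface"]]) * (0:(h - 1L)) / (h - 1L)
      params[[p]][seq_len(h), j] <- v
    }
  }
  center <- piston_center(spec)
  lab <- leaf_labels(mask, center, spa_cols_n(spec))
  if (session == "post") {
    for (p in .qc_params) {
      m <- spec$exposure_multipliers[[p]]
      for (k in 1:4) {
        idx <- lab == k
        params[[p]][idx] <- params[[p]][idx] * m[[.qc_leaves[k]]]
      }
    }
  }
  if (load_level != "delta0") {
    lm <- spec$load_model[[load_level]]$multipliers[[session]]
    for (p in .qc_params) {
      for (k in 1:4) {
        idx <- lab == k
        params[[p]][idx] <- params[[p]][idx] * lm[[p]][[.qc_leaves[k]]]
      }
    }
  }
  s0 <- matrix(0, nr, nc)
  s0[mask] <- spec$s0
  list(mask = mask, params = params, s0 = s0)
}

piston_center <- function(spec) as.integer(ceiling(spec$grid_cols / 2))
spa_cols_n <- function(spec) as.integer(round(spec$spa_width / spec$pixel_spacing))

#' Build the unloaded pre-exposure ground truth
#'
#' Draws the sample's truth thickness from `N(height_mean, height_sd^2)`,
#' rasterises a flat cartilage slab of `round(sample_width/pixel_spacing)`
#' columns centred under the piston (fractional pixel heights are floored,
#' matching a conservative segmentation), and fills each column with linear
#' surface-to-deep relaxation profiles.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @param sample_id optional sample identifier carried through metadata.
#' @return An object of class `truth_fields` with per-pixel parameter maps,
#'   the binary cartilage mask, per-column pixel heights, the continuous
#'   truth height (mm), piston geometry and session/load metadata.
#' @export
build_truth <- function(spec, seed = spec$seed, sample_id = "sample") {
  validate_phantom_spec(spec)
  set.seed(seed)
  h_mm <- rnorm(1, spec$height_mean, spec$height_sd)
  h_mm <- max(h_mm, 4 * spec$pixel_spacing)
  h_px <- max(4L, as.integer(floor(h_mm / spec$pixel_spacing)))
  n_cols <- as.integer(round(spec$sample_width / spec$pixel_spacing))
  center <- piston_center(spec)
  cols <- spa_band_columns(center, n_cols, spec$grid_cols)
  heights_px <- integer(spec$grid_cols)
  heights_px[cols] <- h_px
  f <- build_fields(spec, heights_px, "delta0", "pre")
  structure(
    list(params = f$params, s0 = f$s0, mask = f$mask,
         heights_px = heights_px, height_true_mm = h_mm,
         piston_center_col = center, pixel_spacing = spec$pixel_spacing,
         load_level = "delta0", session = "pre", arm = spec$arm,
         sample_id = sample_id, ir_b = spec$ir_b, seed = as.integer(seed)),
    class = "truth_fields"
  )
}

#' Apply indentation loading to an unloaded truth
#'
#' Sub-pistonal columns are compressed by the level's SPA strain fraction and
#' peri-pistonal columns by the PPA fraction (compressed heights floored to
#' whole pixels); fields are rebuilt over the compressed geometry and the
#' session-specific loading multipliers are applied per zone x region.
#'
#' @param truth a `truth_fields` object at load level `delta0`.
#' @param level `"delta0"` (identity), `"delta1"` or `"delta2"`.
#' @param spec the originating [phantom_spec()].
#' @return A `truth_fields` object at the requested load level.
#' @export
apply_load <- function(truth, level = c("delta0", "delta1", "delta2"), spec) {
  level <- match.arg(level)
  if (truth$load_level != "delta0") {
    qc_validation_error("apply_load expects an unloaded (delta0) truth")
  }
  if (level == "delta0") return(truth)
  lm <- spec$load_model[[level]]
  if (is.null(lm)) qc_config_error(sprintf("load_model has no entry for %s", level))
  band <- spa_band_columns(piston_center(spec), spa_cols_n(spec), spec$grid_cols)
  strain <- ifelse(seq_len(spec$grid_cols) %in% band, lm$strain_spa, lm$strain_ppa)
  heights_px <- as.integer(floor(truth$heights_px * (1 - strain)))
  f <- build_fields(spec, heights_px, level, truth$session)
  out <- truth
  out$params <- f$params
  out$s0 <- f$s0
  out$mask <- f$mask
  out$heights_px <- heights_px
  out$load_level <- level
  out
}

#' Apply the arm-specific exposure effect
#'
#' Turns the unloaded pre-exposure truth into the unloaded post-exposure
#' truth by multiplying each parameter field by the arm's exposure
#' multipliers per zone x region. Geometry is unchanged.
#'
#' @param truth a `truth_fields` object at `delta0`, session `"pre"`.
#' @param spec the originating [phantom_spec()].
#' @return A `truth_fields` object with `session = "post"`.
#' @export
apply_exposure <- function(truth, spec) {
  if (truth$session != "pre" || truth$load_level != "delta0") {
    qc_validation_error("apply_exposure expects the pre-exposure delta0 truth")
  }
  f <- build_fields(spec, truth$heights_px, "delta0", "post")
  out <- truth
  out$params <- f$params
  out$s0 <- f$s0
  out$mask <- f$mask
  out$session <- "post"
  out
}

#' Synthesize a noisy acquisition series from a ground truth
#'
#' Evaluates the forward signal model of the protocol's modality at every
#' in-mask pixel and adds Rician noise (the magnitude of a complex Gaussian
#' perturbation with standard deviation `noise_sigma` per channel).
#' Out-of-mask pixels contain noise only. Identical inputs and seed yield
#' bit-identical output.
#'
#' @param truth a `truth_fields` object.
#' @param protocol a [qmri_protocol()].
#' @param noise_sigma Rician sigma in signal units.
#' @param seed integer seed.
#' @return An object of class `acq_series` (see [acq_series()]).
#' @export
synthesize_series <- function(truth, protocol, noise_sigma, seed) {
  if (!inherits(protocol, "qmri_protocol")) qc_validation_error("protocol must be a qmri_protocol")
  if (!is_scalar_number(noise_sigma) || noise_sigma < 0) {
    qc_validation_error("noise_sigma must be non-negative")
  }
  par <- protocol$parameter
  tau <- truth$params[[par]]
  s0 <- truth$s0
  nr <- nrow(s0); nc <- ncol(s0); nt <- length(protocol$times)
  stack <- array(0, dim = c(nr, nc, nt))
  tau0 <- ifelse(is.na(tau), 1, tau) # out-of-mask: s0 = 0, value irrelevant
  for (k in seq_len(nt)) {
    t_k <- protocol$times[k]
    if (protocol$modality == "T1_IR") {
      stack[, , k] <- abs(s0 * (1 - truth$ir_b * exp(-t_k / tau0)))
    } else {
      stack[, , k] <- s0 * exp(-t_k / tau0)
    }
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    n <- length(stack)
    stack <- array(sqrt((as.vector(stack) + noise_sigma * rnorm(n))^2 +
                          (noise_sigma * rnorm(n))^2), dim = dim(stack))
  }
  acq_series(stack = stack, times = protocol$times, modality = protocol$modality,
             pixel_spacing = truth$pixel_spacing,
             meta = list(sample_id = truth$sample_id, session = truth$session,
                         load_level = truth$load_level, arm = truth$arm,
                         seed = as.integer(seed)))
}

#' Simulate one sample's full serial acquisition
#'
#' Builds the pre-exposure truth, derives post-exposure and loaded truths,
#' and synthesizes one acquisition series per session x load x modality.
#'
#' @param spec a [phantom_spec()].
#' @param sample_id sample identifier.
#' @param seed integer seed for this sample.
#' @param modalities modality tags to synthesize.
#' @param sessions subset of `c("pre", "post")`.
#' @param loads subset of `c("delta0", "delta1", "delta2")`.
#' @return A list with `spec`, `truths[[session]][[load]]` and
#'   `series[[session]][[load]][[modality]]`.
#' @export
simulate_sample <- function(spec, sample_id, seed = spec$seed,
                            modalities = qmri_modalities(),
                            sessions = c("pre", "post"),
                            loads = c("delta0", "delta1", "delta2")) {
  truth0 <- build_truth(spec, seed = seed, sample_id = sample_id)
  base <- list(pre = truth0)
  if ("post" %in% sessions) base$post <- apply_exposure(truth0, spec)
  truths <- list(); series <- list()
  stream <- 0L
  for (ses in sessions) {
    truths[[ses]] <- list(); series[[ses]] <- list()
    for (lv in loads) {
      tr <- apply_load(base[[ses]], lv, spec)
      truths[[ses]][[lv]] <- tr
      series[[ses]][[lv]] <- list()
      for (mod in modalities) {
        stream <- stream + 1L
        series[[ses]][[lv]][[mod]] <- synthesize_series(
          tr, qmri_protocol(mod), spec$noise_sigma,
          seed = derive_seed(seed, stream))
      }
    }
  }
  list(spec = spec, sample_id = sample_id, truths = truths, series = series)
}

#' Generate a multi-arm phantom study
#'
#' Emulates the serial study design: `arms` samples per exposure arm, each
#' imaged pre and post exposure at up to three load levels with up to four
#' mapping modalities. Per-sample seeds are derived deterministically from
#' the master seed. With `out_dir` set, series, truth maps and masks are
#' written as NIfTI files with JSON sidecars plus a CSV manifest.
#'
#' @param arms named integer vector of sample counts, e.g.
#'   `c(control = 9, LT = 10, HT = 10)`.
#' @param seed master seed.
#' @param modalities,sessions,loads design subsets (defaults: full design).
#' @param spec_args named list of [phantom_spec()] overrides applied to every
#'   arm.
#' @param out_dir optional output directory for the on-disk layout.
#' @return A study bundle: list with `samples` (named list from
#'   [simulate_sample()]) and `manifest` (tibble of sample id, arm, seed and
#'   any file paths).
#' @export
generate_study <- function(arms = c(control = 9, LT = 10, HT = 10),
                           seed = 1L,
                           modalities = qmri_modalities(),
                           sessions = c("pre", "post"),
                           loads = c("delta0", "delta1", "delta2"),
                           spec_args = list(),
                           out_dir = NULL) {
  if (is.null(names(arms)) || any(!names(arms) %in% .qc_arms)) {
    qc_config_error("arms must be a named vector with names among control/LT/HT")
  }
  ids <- unlist(lapply(names(arms), function(a) {
    sprintf("%s_%02d", a, seq_len(arms[[a]]))
  }))
  if (anyDuplicated(ids)) qc_config_error("duplicate sample identifiers")
  samples <- list()
  rows <- list()
  i <- 0L
  for (a in names(arms)) {
    for (s in seq_len(arms[[a]])) {
      i <- i + 1L
      id <- sprintf("%s_%02d", a, s)
      sample_seed <- derive_seed(seed, i)
      spec <- do.call(phantom_spec, c(list(arm = a, seed = sample_seed), spec_args))
      samples[[id]] <- simulate_sample(spec, id, seed = sample_seed,
                                       modalities = modalities,
                                       sessions = sessions, loads = loads)
      rows[[id]] <- tibble::tibble(sample_id = id, arm = a, seed = sample_seed)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  study <- list(samples = samples, manifest = manifest, seed = as.integer(seed))
  if (!is.null(out_dir)) {
    study$manifest <- write_study(study, out_dir)
    utils::write.csv(study$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  study
}
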