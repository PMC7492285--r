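# Default phantom effect sizes.
#
# The generator emulates a three-arm degradation study: untreated controls,
# low-concentration trypsin (LT, 0.1 mg/mL) and high-concentration trypsin
# (HT, 1.0 mg/mL). Exposure and loading effects are expressed as
# multiplicative factors on the ground-truth relaxation-time fields, one per
# parameter x zone (upper/lower half) x region (sub-/peri-pistonal). The
# default percentages are the group-mean relative changes observed in the
# underlying indentation-loading experiment; a percentage d becomes the
# multiplier 1 + d/100.

.qc_params <- c("T1", "T1rho", "T2", "T2star")
.qc_arms <- c("control", "LT", "HT")
.qc_leaves <- c("SPA_upper", "SPA_lower", "PPA_upper", "PPA_lower")
.qc_loads <- c("delta0", "delta1", "delta2")

# Post- vs pre-exposure percent change at rest (delta0), leaf ROIs in the
# order SPA_upper, SPA_lower, PPA_upper, PPA_lower.
.qc_exposure_pct <- list(
  control = list(
    T1     = c(-1.2,  -1.1,  -0.8,  -1.4),
    T1rho  = c(-11.8, -12.7, -12.1, -12.8),
    T2     = c(-11.2, -14.6, -9.9,  -16.4),
    T2star = c(-7.8,  -9.8,  -6.3,  -8.2)
  ),
  LT = list(
    T1     = c(-0.1, -0.7, 2.1, 0.7),
    T1rho  = c(0.6,  0.2,  0.5, -1.6),
    T2     = c(5.6,  2.5,  6.0,  4.1),
    T2star = c(6.5,  4.7,  6.3,  4.9)
  ),
  HT = list(
    T1     = c(4.0,  -0.4, 4.6, -2.6),
    T1rho  = c(5.6,  2.9,  4.1, -1.8),
    T2     = c(10.9, 8.7,  10.6, 8.5),
    T2star = c(9.7,  8.5,  7.5,  8.4)
  )
)

# Loaded vs unloaded percent change within one session, per load level and
# session. Leaf order as above.
.qc_load_pct <- list(
  control = list(
    pre = list(
      delta1 = list(T1 = c(-7.7, -2.1, -3.9, -0.9), T1rho = c(14.8, 6.7, 5.2, 3.2),
                    T2 = c(0.8, -1.6, 2.9, 0.5),    T2star = c(0.8, 1.9, 5.6, 7.5)),
      delta2 = list(T1 = c(-13.9, -4.1, -8.7, -2.1), T1rho = c(13.4, 9.6, 5.3, 2.8),
                    T2 = c(-5.8, -0.9, -0.5, -1.1),  T2star = c(-3.3, 1.1, 0.8, 6.2))
    ),
    post = list(
      delta1 = list(T1 = c(-8.8, -1.7, -3.5, 0.2),  T1rho = c(19.3, 11.4, 11.5, 4.9),
                    T2 = c(-1.4, -3.2, 3.6, 0.3),   T2star = c(-2.7, 1.1, 3.8, 3.7)),
      delta2 = list(T1 = c(-14.8, -2.6, -9.0, -1.2), T1rho = c(20.8, 14.9, 12.9, 9.7),
                    T2 = c(-5.9, -2.0, 0.2, 1.4),    T2star = c(-7.2, 0.8, 0.2, 3.2))
    )
  ),
  LT = list(
    pre = list(
      delta1 = list(T1 = c(-8.6, -2.6, -0.9, 0.2),  T1rho = c(21.3, 9.4, 12.6, 5.4),
                    T2 = c(5.1, 4.9, 8.0, 4.2),     T2star = c(5.1, 12.7, 8.6, 8.8)),
      delta2 = list(T1 = c(-15.5, -3.5, -4.7, -1.5), T1rho = c(20.9, 12.8, 15.8, 9.1),
                    T2 = c(1.4, 5.9, 7.1, 6.2),      T2star = c(2.5, 11.9, 7.7, 11.2))
    ),
    post = list(
      delta1 = list(T1 = c(-8.0, -0.9, -1.8, 0.4),  T1rho = c(18.8, 8.7, 13.6, 5.5),
                    T2 = c(0.0, 3.6, 4.9, 2.1),     T2star = c(-0.1, 10.7, 5.4, 7.9)),
      delta2 = list(T1 = c(-15.4, -3.8, -4.3, -0.5), T1rho = c(16.7, 10.3, 14.3, 7.9),
                    T2 = c(-4.3, 6.3, 5.7, 5.1),     T2star = c(-2.6, 8.8, 4.9, 8.0))
    )
  ),
  HT = list(
    pre = list(
      delta1 = list(T1 = c(-9.6, -2.0, -4.0, -1.7),  T1rho = c(18.2, 13.8, 9.1, 6.9),
                    T2 = c(-0.5, 0.2, 4.7, 1.7),     T2star = c(0.3, 5.3, 4.7, 8.9)),
      delta2 = list(T1 = c(-17.2, -6.7, -8.4, -4.3), T1rho = c(17.3, 18.4, 11.6, 11.1),
                    T2 = c(-7.4, 3.7, 3.8, 3.0),     T2star = c(-6.8, 7.4, 4.5, 8.3))
    ),
    post = list(
      delta1 = list(T1 = c(-15.1, -0.8, -4.8, 2.4),  T1rho = c(15.0, 14.0, 7.2, 10.1),
                    T2 = c(-4.9, 0.2, 1.3, 0.2),     T2star = c(-2.9, 7.2, 2.2, 8.4)),
      delta2 = list(T1 = c(-23.0, -4.6, -9.0, -0.2), T1rho = c(17.1, 24.6, 7.4, 15.8),
                    T2 = c(-15.2, -0.9, 0.0, 3.1),   T2star = c(-16.3, -4.1, -1.3, 1.0))
    )
  )
)

# Pre-exposure cartilage thickness distribution per arm (mm).
.qc_heights <- list(
  control = c(mean = 2.77, sd = 0.19),
  LT      = c(mean = 2.59, sd = 0.32),
  HT      = c(mean = 2.40, sd = 0.41)
)

pct_to_mult <- function(pct) {
  lapply(pct, function(v) setNames(1 + v / 100, .qc_leaves))
}

#' Default post-exposure multipliers for a study arm
#'
#' One multiplicative factor per relaxation parameter and leaf ROI
#' (SPA_upper, SPA_lower, PPA_upper, PPA_lower), applied to the ground-truth
#' fields of the unloaded post-exposure configuration. Defaults encode the
#' arm-typical group-mean percent changes (controls: global decreases;
#' trypsin arms: predominantly superficial increases).
#'
#' @param arm `"control"`, `"LT"` or `"HT"`.
#' @return Named list (per parameter) of named numeric vectors (per leaf ROI).
#' @export
default_exposure_multipliers <- function(arm) {
  arm <- match.arg(arm, .qc_arms)
  pct_to_mult(.qc_exposure_pct[[arm]])
}

#' Default loading model for a study arm
#'
#' Per load level (`delta1` = 15.1 N, `delta2` = 28.6 N): the sub-pistonal
#' and peri-pistonal height-strain fractions and, per session, multiplicative
#' loading factors per parameter and leaf ROI. Session-specific multipliers
#' let the phantom reproduce exposure-dependent changes in the loading
#' response (e.g. larger sub-pistonal T1/T2 decreases after high-dose
#' trypsin).
#'
#' @param arm `"control"`, `"LT"` or `"HT"`.
#' @param strain_spa strain fractions (height loss) under the piston at
#'   delta1 and delta2.
#' @param strain_ppa peri-pistonal strain fractions at delta1 and delta2.
#' @return Named list with elements `delta1` and `delta2`, each carrying
#'   `strain_spa`, `strain_ppa` and `multipliers$pre` / `multipliers$post`.
#' @export
default_load_model <- function(arm, strain_spa = c(0.08, 0.15),
                               strain_ppa = c(0.02, 0.04)) {
  arm <- match.arg(arm, .qc_arms)
  lvl <- function(i) {
    list(
      strain_spa = strain_spa[i],
      strain_ppa = strain_ppa[i],
      multipliers = list(
        pre  = pct_to_mult(.qc_load_pct[[arm]]$pre[[paste0("delta", i)]]),
        post = pct_to_mult(.qc_load_pct[[arm]]$post[[paste0("delta", i)]])
      )
    )
  }
  list(delta1 = lvl(1), delta2 = lvl(2))
}

#' Default per-arm truth height distribution (mm)
#' @param arm `"control"`, `"LT"` or `"HT"`.
#' @return Named vector with `mean` and `sd` in mm.
#' @export
default_height_distribution <- function(arm) {
  .qc_heights[[match.arg(arm, .qc_arms)]]
}

# Unit multipliers (all 1) in the same shape, for null phantoms.
unit_multipliers <- function() {
  pct_to_mult(lapply(setNames(.qc_params, .qc_params), function(p) rep(0, 4)))
}
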