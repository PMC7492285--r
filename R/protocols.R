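#' Acquisition timing protocols
#'
#' The four mapping modalities and their timing vectors: inversion times for
#' inversion-recovery T1, spin-lock durations for T1rho, and echo times for
#' multi-spin-echo T2 and multi-gradient-echo T2*. The default timing vectors
#' reproduce the clinical 3.0 T protocol the pipeline is designed around:
#' TI = 150, 300, 500, 800, 1000, 1500 ms; TSL = 0, 10, 20, 30, 40 ms;
#' T2 echoes n x 8.4 ms (n = 1..12); T2* echoes 3.3 + n x 5.2 ms (n = 0..14).
#'
#' @param modality one of `"T1_IR"`, `"T1rho_SL"`, `"T2_SE"`, `"T2star_GRE"`.
#' @param times optional custom timing vector (ms), strictly increasing,
#'   non-negative, at least 3 points.
#' @return An object of class `qmri_protocol` with fields `modality`,
#'   `times` (ms) and `parameter` (the time constant the series encodes).
#' @examples
#' qmri_protocol("T2_SE")$times
#' @export
qmri_protocol <- function(modality, times = NULL) {
  modality <- match.arg(modality, qmri_modalities())
  if (is.null(times)) {
    times <- switch(modality,
      T1_IR      = c(150, 300, 500, 800, 1000, 1500),
      T1rho_SL   = c(0, 10, 20, 30, 40),
      T2_SE      = 8.4 * (1:12),
      T2star_GRE = 3.3 + 5.2 * (0:14)
    )
  }
  if (!is.numeric(times) || length(times) < 3L) {
    qc_validation_error("protocol requires at least 3 timing points")
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    qc_validation_error("protocol times must be non-negative and strictly increasing")
  }
  structure(
    list(modality = modality, times = as.numeric(times),
         parameter = modality_parameter(modality)),
    class = "qmri_protocol"
  )
}

#' Supported acquisition modalities
#' @return Character vector of modality tags.
#' @export
qmri_modalities <- function() c("T1_IR", "T1rho_SL", "T2_SE", "T2star_GRE")

#' Map a modality tag to the relaxation parameter it measures
#' @param modality modality tag.
#' @return One of `"T1"`, `"T1rho"`, `"T2"`, `"T2star"`.
#' @export
modality_parameter <- function(modality) {
  switch(match.arg(modality, qmri_modalities()),
    T1_IR = "T1", T1rho_SL = "T1rho", T2_SE = "T2", T2star_GRE = "T2star")
}

#' In-plane pixel size of a reconstruction
#'
#' @param fov_mm field of view in mm.
#' @param matrix_size reconstruction matrix size (pixels along the FOV).
#' @return Pixel edge length in mm.
#' @examples
#' pixel_size(62, 256) # 0.242 mm, the proton-density-weighted raster
#' @export
pixel_size <- function(fov_mm, matrix_size) {
  if (!is_scalar_number(fov_mm) || fov_mm <= 0) qc_validation_error("fov_mm must be a positive number")
  if (!is_scalar_number(matrix_size) || matrix_size <= 0) qc_validation_error("matrix_size must be a positive number")
  fov_mm / matrix_size
}
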