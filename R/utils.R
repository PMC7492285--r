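# Internal helpers: classed conditions and seed derivation.

qc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "qmricart_error", "error", "condition")))
}

qc_config_error <- function(msg) qc_stop(msg, "qc_config_error")
qc_format_error <- function(msg) qc_stop(msg, "qc_format_error")
qc_degenerate_error <- function(msg) qc_stop(msg, "qc_degenerate_error")
qc_geometry_error <- function(msg) qc_stop(msg, "qc_geometry_error")
qc_measurement_error <- function(msg) qc_stop(msg, "qc_measurement_error")
qc_validation_error <- function(msg) qc_stop(msg, "qc_validation_error")
qc_empty_roi_error <- function(msg) qc_stop(msg, "qc_empty_roi_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministic 32-bit-safe seed derivation so that every source of
#' randomness in a study flows from one master seed.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index), length(master) == 1L)
  m <- 2147483647
  s <- (abs(master) %% m)
  for (i in seq_len(5)) s <- (s * 48271 + index * 7919 + i) %% m
  as.integer(s)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
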