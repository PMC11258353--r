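#' @keywords internal
"_PACKAGE"

# Internal validation helper: stop with a classed condition so callers can
# distinguish user errors from programming errors.
abort_gbas <- function(msg, class = "gbas_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_that <- function(cond, msg, class = "gbas_invalid_input") {
  if (!isTRUE(cond)) abort_gbas(msg, class = class)
  invisible(TRUE)
}

# Run an expression under a local, restorable RNG state.
with_seed_local <- function(seed, expr) {
  check_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
             "`seed` must be a single finite number")
  withr::with_seed(as.integer(seed), expr)
}

#' Percent change between a reference and a modulated value
#'
#' Computes `100 * (reference - modulated) / reference`, the convention used
#' throughout sensor characterisation to express attenuation: the fractional
#' drop of a signal relative to its unmodulated reference, in percent.
#'
#' @param reference Reference (unmodulated) value; must be non-zero.
#' @param modulated Value observed under modulation (e.g. with ligand).
#' @return Percent change (positive when the signal is attenuated).
#' @examples
#' percent_change(112, 92)  # ~18% kinetic attenuation
#' percent_change(3.9, 3.2) # ~18% blood-current reduction
#' @export
percent_change <- function(reference, modulated) {
  check_that(is.numeric(reference) && is.numeric(modulated),
             "inputs must be numeric")
  check_that(all(reference != 0), "`reference` must be non-zero")
  100 * (reference - modulated) / reference
}

# Gas constant (J mol^-1 K^-1) and Faraday constant (C mol^-1)
#' Physical constants used in the fuel-cell model
#'
#' @return Named list with `R` (8.314 J mol^-1 K^-1) and `F` (96485 C mol^-1).
#' @export
physical_constants <- function() {
  list(R = 8.314, F = 96485)
}
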