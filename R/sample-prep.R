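#' Concentration from absorbance (Beer-Lambert law)
#'
#' Converts an absorbance reading into a molar concentration via
#' \eqn{A = \epsilon l c}, i.e. \eqn{c = A/(\epsilon l)}. Used e.g. to assay a
#' calf-thymus DNA stock at 260 nm with the single-strand extinction
#' coefficient 6600 L mol^-1 cm^-1.
#'
#' @param absorbance Dimensionless absorbance, >= 0.
#' @param epsilon Molar extinction coefficient in L mol^-1 cm^-1, > 0.
#' @param path_cm Optical path length in cm, > 0 (default 1).
#' @return Concentration in mol/L.
#' @examples
#' concentration_from_absorbance(0.4752, 6600)  # 7.2e-05 mol/L, i.e. 72 uM
#' @export
concentration_from_absorbance <- function(absorbance, epsilon, path_cm = 1) {
  if (any(!is.finite(epsilon)) || any(epsilon <= 0))
    stop_bindkit("bad_parameter", "epsilon must be > 0")
  if (any(!is.finite(path_cm)) || any(path_cm <= 0))
    stop_bindkit("bad_parameter", "path_cm must be > 0")
  if (any(absorbance < 0))
    stop_bindkit("bad_parameter", "absorbance must be >= 0")
  absorbance / (epsilon * path_cm)
}

#' Nucleic-acid purity ratio (A260/A280)
#'
#' Computes the absorbance ratio A260/A280 and flags whether it falls inside
#' the protein-free window (default 1.8-1.9) used to decide whether a DNA
#' preparation needs purification.
#'
#' @param a260,a280 Absorbances at 260 and 280 nm; `a280` must be > 0.
#' @param window Length-2 numeric `c(low, high)` acceptance window.
#' @return A list with `ratio` and logical `pass`.
#' @examples
#' purity_ratio(1.85, 1.0)
#' @export
purity_ratio <- function(a260, a280, window = c(1.8, 1.9)) {
  if (a280 <= 0)
    stop_bindkit("division_error", "a280 must be > 0")
  if (length(window) != 2L || window[1L] >= window[2L])
    stop_bindkit("bad_parameter", "window must be c(low, high) with low < high")
  ratio <- a260 / a280
  list(ratio = ratio, pass = ratio >= window[1L] && ratio <= window[2L])
}
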