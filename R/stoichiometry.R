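#' Build a Job's (continuous-variation) curve
#'
#' Takes a table of continuous-variation records - mixtures of ligand and
#' macromolecule at a fixed total concentration - and returns the corrected
#' absorbance versus ligand mole fraction. When per-component blank
#' absorbances are supplied, the correction subtracts the mole-fraction
#' weighted free-component contributions,
#' \deqn{A_{corr}(x) = A_{mix}(x) - (1-x) A_{macro} - x A_{ligand},}
#' so a non-interacting mixture gives an identically zero curve. When blanks
#' are absent the mixture absorbances are taken as already corrected.
#'
#' @param records Data frame with columns `mole_fraction_ligand`,
#'   `absorbance_mix`, `total_conc` (mol/L, constant across rows) and
#'   optionally `absorbance_ligand_only`, `absorbance_macro_only`.
#' @return An object of class `job_curve`: list with `mole_fractions`,
#'   `corrected_absorbance`, `blank_corrected` (logical), `total_conc`.
#' @export
build_job_curve <- function(records) {
  need <- c("mole_fraction_ligand", "absorbance_mix", "total_conc")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop_bindkit("missing_column",
                 paste("missing column(s):", paste(missing, collapse = ", ")))
  if (nrow(records) < 5L)
    stop_bindkit("insufficient_data", "need at least 5 continuous-variation records")
  x <- records$mole_fraction_ligand
  if (any(x < 0 | x > 1))
    stop_bindkit("bad_parameter", "mole fractions must lie in [0, 1]")
  tc <- records$total_conc
  if (max(tc) - min(tc) > 1e-9 * max(abs(tc)))
    stop_bindkit("varying_total_conc",
                 "total concentration must be constant across a Job's set")
  has_blanks <- all(c("absorbance_ligand_only", "absorbance_macro_only") %in%
                      names(records)) &&
    !anyNA(records$absorbance_ligand_only) &&
    !anyNA(records$absorbance_macro_only)
  corrected <- if (has_blanks) {
    records$absorbance_mix -
      (1 - x) * records$absorbance_macro_only -
      x * records$absorbance_ligand_only
  } else {
    records$absorbance_mix
  }
  ord <- order(x)
  structure(list(mole_fractions = x[ord],
                 corrected_absorbance = corrected[ord],
                 blank_corrected = has_blanks,
                 total_conc = tc[1L]),
            class = "job_curve")
}

#' Locate the maximum of a Job's curve
#'
#' Returns the ligand mole fraction at which the corrected absorbance peaks.
#' The `"argmax"` method returns the grid maximiser; the default
#' `"quadratic"` method refines it by fitting a parabola through the grid
#' maximiser and its two neighbours and returning the vertex, clipped to the
#' neighbour interval (the measurement grid quantises the raw argmax). A
#' maximum on the grid boundary skips refinement and attaches a boundary
#' warning.
#'
#' @param curve A [build_job_curve()] result.
#' @param method `"quadratic"` (default) or `"argmax"`.
#' @return A list with `x_max`, `method` actually used, and logical
#'   `boundary`.
#' @export
job_maximum <- function(curve, method = c("quadratic", "argmax")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "job_curve"))
  x <- curve$mole_fractions
  a <- curve$corrected_absorbance
  if (length(x) < 5L)
    stop_bindkit("insufficient_data", "need at least 5 points to locate a maximum")
  i <- which.max(a)
  if (i == 1L || i == length(x)) {
    warning("Job's-curve maximum lies on the grid boundary; vertex refinement skipped",
            call. = FALSE)
    return(list(x_max = x[i], method = "argmax", boundary = TRUE))
  }
  if (method == "argmax")
    return(list(x_max = x[i], method = "argmax", boundary = FALSE))
  xs <- x[(i - 1L):(i + 1L)]
  ys <- a[(i - 1L):(i + 1L)]
  co <- stats::coef(stats::lm(ys ~ xs + I(xs^2)))
  x_max <- if (is.na(co[3L]) || co[3L] >= 0) x[i] else unname(-co[2L] / (2 * co[3L]))
  x_max <- min(max(x_max, xs[1L]), xs[3L])
  list(x_max = x_max, method = "quadratic", boundary = FALSE)
}

#' Snap a Job's-plot maximum to a small-integer stoichiometry
#'
#' In the method of continuous variation an m:n (ligand:macromolecule)
#' complex peaks at ligand mole fraction m/(m+n). This searches all integer
#' pairs with 1 <= m, n <= 3, picks the pair minimising |x_max - m/(m+n)|
#' (ties broken toward the smallest m+n, so 0.5 snaps to 1:1 rather than
#' 2:2), and accepts it only if the residual is within `tolerance`.
#'
#' @param x_max Mole fraction of the curve maximum, in (0, 1).
#' @param tolerance Maximum acceptable |x_max - m/(m+n)| (default 0.08).
#' @return A list with `ratio_ligand`, `ratio_macromolecule`, `residual`, and
#'   logical `determinate` (FALSE when no candidate ratio is close enough, in
#'   which case the ratios are NA).
#' @examples
#' stoichiometry_from_xmax(0.5)    # 1:1
#' stoichiometry_from_xmax(2 / 3)  # 2:1
#' @export
stoichiometry_from_xmax <- function(x_max, tolerance = 0.08) {
  if (!is.finite(x_max) || x_max <= 0 || x_max >= 1)
    stop_bindkit("bad_parameter", "x_max must lie strictly inside (0, 1)")
  grid <- expand.grid(m = 1:3, n = 1:3)
  grid$x <- grid$m / (grid$m + grid$n)
  grid$residual <- abs(x_max - grid$x)
  grid <- grid[order(grid$residual, grid$m + grid$n), ]
  best <- grid[1L, ]
  if (best$residual <= tolerance) {
    list(ratio_ligand = best$m, ratio_macromolecule = best$n,
         residual = best$residual, determinate = TRUE)
  } else {
    list(ratio_ligand = NA_integer_, ratio_macromolecule = NA_integer_,
         residual = best$residual, determinate = FALSE)
  }
}
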