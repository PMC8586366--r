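#' Stern-Volmer fit of a fluorescence quenching titration
#'
#' Fits the linear Stern-Volmer relation
#' \deqn{F_0/F = 1 + K_{sv}[Q] = 1 + k_q \tau_0 [Q]}
#' by ordinary least squares of \eqn{y = F_0/F} against \eqn{x = [Q]} over all
#' points, including the zero-concentration reference (a measured datum, not a
#' constraint). The slope is the Stern-Volmer constant Ksv (L/mol); dividing
#' by the unquenched lifetime `tau0` gives the bimolecular quenching constant
#' Kq (L mol^-1 s^-1).
#'
#' The intercept is fitted free rather than pinned at 1; a deviation of the
#' fitted intercept from 1 by more than 0.05 attaches a warning (it usually
#' points at inner-filter artefacts). A diagnostic quadratic refit with a
#' significantly positive curvature term attaches a "possible mixed quenching"
#' warning but never alters the reported Ksv.
#'
#' @param series A [titration_series].
#' @param tau0 Unquenched fluorophore lifetime in seconds (default 1e-8).
#' @return An object of class `sv_fit` with fields `ksv`, `ksv_se`,
#'   `intercept`, `intercept_se`, `kq`, `r_squared`, `temperature`,
#'   `n_points`, `degenerate` and a character vector `warnings`.
#' @examples
#' q <- c(0, 8, 16, 24, 32, 40, 48) * 1e-6
#' ts <- titration_series(q, 1000 / (1 + 5000 * q))
#' stern_volmer_fit(ts)$ksv
#' @export
stern_volmer_fit <- function(series, tau0 = 1e-8) {
  stopifnot(inherits(series, "titration_series"))
  if (tau0 <= 0) stop_bindkit("bad_parameter", "tau0 must be > 0")
  f0 <- series$signal[1L]
  if (any(series$signal <= 0))
    stop_bindkit("nonpositive_signal", "all signals must be > 0")
  y <- f0 / series$signal
  x <- series$quencher_conc
  warnings <- character()
  if (all(series$signal == f0)) {
    res <- list(ksv = 0, ksv_se = 0, intercept = 1, intercept_se = 0,
                kq = 0, r_squared = NA_real_, temperature = series$temperature,
                n_points = length(x), degenerate = TRUE,
                warnings = "degenerate: constant signal, r-squared undefined")
    return(structure(res, class = "sv_fit"))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ksv <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (abs(intercept - 1) > 0.05)
    warnings <- c(warnings, sprintf(
      "intercept %.4f deviates from 1 by more than 0.05 (possible inner-filter artefact)",
      intercept))
  # curvature diagnostic: positive significant quadratic term suggests
  # simultaneous static + dynamic quenching
  if (length(x) >= 4L) {
    qfit <- summary(stats::lm(y ~ x + I(x^2)))$coefficients
    if (nrow(qfit) == 3L && !is.na(qfit[3L, 4L]) &&
        qfit[3L, 1L] > 0 && qfit[3L, 4L] < 0.05)
      warnings <- c(warnings,
                    "possible mixed quenching: significant upward curvature")
  }
  res <- list(ksv = ksv,
              ksv_se = sm$coefficients[2L, 2L],
              intercept = intercept,
              intercept_se = sm$coefficients[1L, 2L],
              kq = ksv / tau0,
              r_squared = sm$r.squared,
              temperature = series$temperature,
              n_points = length(x),
              degenerate = FALSE,
              warnings = warnings)
  structure(res, class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("<sv_fit>  Ksv = %.4g +/- %.2g L/mol,  Kq = %.4g L/mol/s\n",
              x$ksv, x$ksv_se, x$kq))
  cat(sprintf("  intercept = %.4f, r^2 = %.4f, T = %.2f K, n = %d\n",
              x$intercept, x$r_squared, x$temperature, x$n_points))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Bimolecular quenching constant from Ksv
#'
#' Kq = Ksv / tau0. With the conventional biopolymer lifetime tau0 = 1e-8 s,
#' Ksv of order 1e4 L/mol maps to Kq of order 1e12 L mol^-1 s^-1, far above
#' the diffusion-controlled limit of ~1e10 - the signature of static
#' (ground-state complex) quenching.
#'
#' @param ksv Stern-Volmer constant in L/mol.
#' @param tau0 Fluorophore lifetime in seconds, > 0.
#' @return Kq in L mol^-1 s^-1.
#' @examples
#' quenching_constant(4.2e4, 1e-8)  # 4.2e12
#' @export
quenching_constant <- function(ksv, tau0 = 1e-8) {
  if (any(tau0 <= 0)) stop_bindkit("bad_parameter", "tau0 must be > 0")
  ksv / tau0
}

#' Classify the quenching mechanism across temperatures
#'
#' Applies the standard two-pronged diagnostic: the magnitude of Kq relative
#' to the diffusion (scattering) limit, and the temperature trend of Ksv.
#' \itemize{
#'   \item \strong{static}: every Kq exceeds the diffusion limit AND (only one
#'     temperature was measured, or Ksv is non-increasing with temperature) -
#'     ground-state complexes dissociate on heating;
#'   \item \strong{dynamic}: Ksv strictly increases with temperature AND every
#'     Kq stays within twice the diffusion limit - collisional quenching is
#'     faster in hotter solution;
#'   \item \strong{mixed}: Kq above the limit but Ksv rising;
#'   \item \strong{indeterminate}: anything else (including a single
#'     temperature with sub-limit Kq, which is insufficient evidence).
#' }
#' Ties or plateaus in the temperature trend count as non-increasing, so
#' measurement noise does not flip a static call.
#'
#' @param results List of [stern_volmer_fit()] results ordered by strictly
#'   increasing temperature.
#' @param diffusion_limit Diffusion-controlled quenching limit in
#'   L mol^-1 s^-1 (default 1e10).
#' @return A list with `mechanism` (one of "static", "dynamic", "mixed",
#'   "indeterminate") and a character vector `reasons`.
#' @export
classify_quenching <- function(results, diffusion_limit = 1e10) {
  if (length(results) < 1L)
    stop_bindkit("bad_parameter", "need at least one Stern-Volmer result")
  temps <- vapply(results, `[[`, numeric(1), "temperature")
  if (length(temps) > 1L && is.unsorted(temps, strictly = TRUE))
    stop_bindkit("unsorted_temperatures",
                 "results must be ordered by strictly increasing temperature")
  ksv <- vapply(results, `[[`, numeric(1), "ksv")
  kq <- vapply(results, `[[`, numeric(1), "kq")
  reasons <- character()
  all_above <- all(kq > diffusion_limit)
  non_increasing <- length(ksv) == 1L || all(diff(ksv) <= 0)
  strictly_increasing <- length(ksv) > 1L && all(diff(ksv) > 0)
  within_2x <- all(kq <= 2 * diffusion_limit)
  if (all_above && non_increasing) {
    reasons <- c(sprintf("every Kq (min %.3g) exceeds the diffusion limit %.3g L/mol/s",
                         min(kq), diffusion_limit),
                 if (length(ksv) > 1L)
                   "Ksv non-increasing with temperature (complex dissociates on heating)"
                 else "single temperature: magnitude criterion alone applied")
    mech <- "static"
  } else if (strictly_increasing && within_2x) {
    reasons <- c("Ksv strictly increasing with temperature",
                 sprintf("every Kq (max %.3g) within 2x the diffusion limit", max(kq)))
    mech <- "dynamic"
  } else if (any(kq > diffusion_limit) && strictly_increasing) {
    reasons <- c("Kq above the diffusion limit yet Ksv rising with temperature")
    mech <- "mixed"
  } else {
    mech <- "indeterminate"
    if (!all_above)
      reasons <- c(reasons, sprintf(
        "some Kq (min %.3g) at or below the diffusion limit %.3g without a usable temperature trend",
        min(kq), diffusion_limit))
    if (length(ksv) == 1L)
      reasons <- c(reasons, "single temperature: trend criterion unavailable")
  }
  list(mechanism = mech, reasons = reasons)
}
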