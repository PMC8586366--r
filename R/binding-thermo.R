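#' Double-log (modified Stern-Volmer) binding-site fit
#'
#' Fits the double-logarithmic binding relation
#' \deqn{\log_{10}\frac{F_0 - F}{F} = n \log_{10}[Q] + \log_{10} K_b}
#' by ordinary least squares over the eligible titration points. The slope is
#' the apparent number of binding sites `n`, the intercept is `log10(Kb)`.
#' Base-10 logarithms are used throughout; the natural log appears only inside
#' the Gibbs free energy.
#'
#' The zero-concentration reference point and any point with \eqn{F \ge F_0}
#' (log of a non-positive quench is undefined) are excluded rather than
#' clipped, and every exclusion is listed with its reason.
#'
#' @param series A [titration_series].
#' @return An object of class `msv_fit` with fields `log10_kb`, `log10_kb_se`,
#'   `kb`, `n_sites`, `n_sites_se`, `r_squared`, `temperature`,
#'   `n_points_used`, and a data frame `excluded_points` (`index`, `reason`).
#' @examples
#' q <- c(0, 8, 16, 24, 32, 40, 48) * 1e-6
#' ts <- titration_series(q, 1000 / (1 + 1e4 * q))
#' fit <- modified_stern_volmer_fit(ts)
#' c(fit$log10_kb, fit$n_sites)  # 4, 1: the 1:1 static model is exact
#' @export
modified_stern_volmer_fit <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  f0 <- series$signal[1L]
  q <- series$quencher_conc
  f <- series$signal
  excluded <- data.frame(index = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  eligible <- rep(TRUE, length(q))
  eligible[1L] <- FALSE
  excluded <- rbind(excluded, data.frame(index = 1L,
                                         reason = "zero-concentration reference",
                                         stringsAsFactors = FALSE))
  bad <- which(q > 0 & f >= f0)
  if (length(bad)) {
    eligible[bad] <- FALSE
    excluded <- rbind(excluded, data.frame(index = bad,
                                           reason = "non-quenched point",
                                           stringsAsFactors = FALSE))
  }
  if (sum(eligible) < 3L)
    stop_bindkit("insufficient_data", sprintf(
      "series '%s': only %d eligible points ([Q] > 0 and F < F0); need >= 3",
      series$series_id, sum(eligible)))
  x <- log10(q[eligible])
  y <- log10((f0 - f[eligible]) / f[eligible])
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  log10_kb <- unname(stats::coef(fit)[1L])
  res <- list(log10_kb = log10_kb,
              log10_kb_se = sm$coefficients[1L, 2L],
              kb = 10^log10_kb,
              n_sites = unname(stats::coef(fit)[2L]),
              n_sites_se = sm$coefficients[2L, 2L],
              r_squared = sm$r.squared,
              temperature = series$temperature,
              n_points_used = sum(eligible),
              excluded_points = excluded)
  structure(res, class = "msv_fit")
}

#' @export
print.msv_fit <- function(x, ...) {
  cat(sprintf("<msv_fit>  log10(Kb) = %.3f +/- %.2g  (Kb = %.4g L/mol),  n = %.3f +/- %.2g\n",
              x$log10_kb, x$log10_kb_se, x$kb, x$n_sites, x$n_sites_se))
  cat(sprintf("  r^2 = %.4f, T = %.2f K, %d points used, %d excluded\n",
              x$r_squared, x$temperature, x$n_points_used,
              nrow(x$excluded_points)))
  invisible(x)
}

#' Gibbs free energy of binding
#'
#' \deqn{\Delta G^\circ = -RT \ln K_b}
#' With R = 1.9872e-3 kcal mol^-1 K^-1 the result is in kcal/mol; any Kb > 1
#' gives a negative (spontaneous) free energy.
#'
#' @param kb Association constant in L/mol, > 0.
#' @param temperature Temperature in kelvin, > 0.
#' @param gas_constant_kcal R in kcal mol^-1 K^-1.
#' @return Free energy in kcal/mol.
#' @examples
#' gibbs_free_energy(3.9e3, 298.15)  # about -4.9 kcal/mol
#' @export
gibbs_free_energy <- function(kb, temperature, gas_constant_kcal = 1.9872e-3) {
  if (any(kb <= 0)) stop_bindkit("bad_parameter", "kb must be > 0")
  if (any(temperature <= 0)) stop_bindkit("bad_parameter", "temperature must be > 0")
  -gas_constant_kcal * temperature * log(kb)
}

#' Temperature trend of binding affinity
#'
#' Labels the direction of the association constant across a temperature
#' series: "decreasing" if Kb strictly decreases (typical of static complexes
#' that dissociate on heating), "increasing" if strictly increases, "flat"
#' otherwise.
#'
#' @param results List of [modified_stern_volmer_fit()] results ordered by
#'   strictly increasing temperature (at least two).
#' @return One of "decreasing", "increasing", "flat".
#' @export
affinity_trend <- function(results) {
  if (length(results) < 2L)
    stop_bindkit("insufficient_data", "need at least two temperatures for a trend")
  temps <- vapply(results, `[[`, numeric(1), "temperature")
  if (is.unsorted(temps, strictly = TRUE))
    stop_bindkit("unsorted_temperatures",
                 "results must be ordered by strictly increasing temperature")
  kb <- vapply(results, `[[`, numeric(1), "kb")
  d <- diff(kb)
  if (all(d < 0)) "decreasing" else if (all(d > 0)) "increasing" else "flat"
}

#' Full per-temperature binding table
#'
#' Convenience wrapper running both the Stern-Volmer and the double-log fits
#' plus the Gibbs free energy on a list of titration series, returning one row
#' per series with the columns practitioners tabulate: Ksv, Kq, log10(Kb), Kb,
#' n and dG (kcal/mol).
#'
#' @param series_list List of [titration_series] (one per temperature).
#' @param config An [analysis_config()].
#' @return A data frame with columns `series_id`, `temperature_K`, `ksv`,
#'   `ksv_se`, `kq`, `log10_kb`, `kb`, `n_sites`, `delta_g_kcal`,
#'   `spontaneous`.
#' @export
binding_table <- function(series_list, config = analysis_config()) {
  if (inherits(series_list, "titration_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    sv <- stern_volmer_fit(s, tau0 = config$tau0_s)
    msv <- modified_stern_volmer_fit(s)
    dg <- gibbs_free_energy(msv$kb, s$temperature, config$gas_constant_kcal)
    data.frame(series_id = s$series_id, temperature_K = s$temperature,
               ksv = sv$ksv, ksv_se = sv$ksv_se, kq = sv$kq,
               log10_kb = msv$log10_kb, kb = msv$kb, n_sites = msv$n_sites,
               delta_g_kcal = dg, spontaneous = dg < 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
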