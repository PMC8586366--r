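#' Assess hyper/hypochromism and wavelength shift between two spectra
#'
#' Compares the absorption peak of the ligand-bound spectrum against the free
#' macromolecule: an intensity increase (hyperchromism) or red shift of the
#' band hints at groove binding, while hypochromism or a blue shift hints at
#' intercalation. Changes below the thresholds classify as "none".
#'
#' Each scan is a list/data frame with numeric `wavelength_nm` (strictly
#' increasing) and `value` (absorbance or intensity); the peak must lie in the
#' interior of the scanned range.
#'
#' @param free,bound Spectral scans of the free and ligand-saturated
#'   macromolecule.
#' @param intensity_threshold Minimum |fractional peak-height change| to call
#'   hyper/hypochromism (default 0.02).
#' @param shift_threshold_nm Minimum |peak shift| in nm to call a red/blue
#'   shift (default 1).
#' @return A list with `intensity_change` ("hyperchromic"/"hypochromic"/
#'   "none"), `wavelength_shift` ("red"/"blue"/"none"),
#'   `delta_intensity_fraction`, `delta_lambda_nm`, and `mode_hint`
#'   ("groove"/"intercalative"/"none").
#' @export
assess_absorbance_shift <- function(free, bound, intensity_threshold = 0.02,
                                    shift_threshold_nm = 1) {
  peak <- function(scan, label) {
    wl <- scan$wavelength_nm
    v <- scan$value
    if (is.unsorted(wl, strictly = TRUE))
      stop_bindkit("unsorted_wavelengths",
                   sprintf("%s scan: wavelengths must be strictly increasing", label))
    i <- which.max(v)
    if (i == 1L || i == length(v))
      stop_bindkit("boundary_peak",
                   sprintf("%s scan: peak lies on the range boundary", label))
    c(lambda = wl[i], height = v[i])
  }
  pf <- peak(free, "free")
  pb <- peak(bound, "bound")
  d_int <- (pb[["height"]] - pf[["height"]]) / pf[["height"]]
  d_lam <- pb[["lambda"]] - pf[["lambda"]]
  intensity_change <- if (d_int >= intensity_threshold) "hyperchromic"
    else if (d_int <= -intensity_threshold) "hypochromic" else "none"
  wavelength_shift <- if (d_lam >= shift_threshold_nm) "red"
    else if (d_lam <= -shift_threshold_nm) "blue" else "none"
  groove <- intensity_change == "hyperchromic" || wavelength_shift == "red"
  inter <- intensity_change == "hypochromic" || wavelength_shift == "blue"
  mode_hint <- if (groove && !inter) "groove"
    else if (inter && !groove) "intercalative" else "none"
  list(intensity_change = intensity_change,
       wavelength_shift = wavelength_shift,
       delta_intensity_fraction = unname(d_int),
       delta_lambda_nm = unname(d_lam),
       mode_hint = mode_hint)
}

#' Competitive dye-displacement analysis
#'
#' Analyses the fluorescence of a dye-DNA complex titrated with the test
#' ligand. Ethidium bromide reports intercalation (it stacks between base
#' pairs), Hoechst 33258 reports minor-groove binding; a ligand that shares
#' the dye's binding mode displaces it, quenching the complex emission. The
#' dye counts as displaced when the maximum fractional intensity decrease
#' reaches `threshold` AND the decrease trends monotonically with ligand
#' concentration (Spearman sign check, which guards against single-point
#' dips).
#'
#' @param series A [titration_series]; the signal at zero ligand is the
#'   dye-DNA complex intensity.
#' @param dye `"hoechst_33258"` or `"ethidium_bromide"`.
#' @param threshold Minimum fractional decrease (default 0.05).
#' @return A list with `dye`, `dye_mode` ("groove_binder" for Hoechst,
#'   "intercalator" for EtBr), `max_fractional_decrease`, `monotone`, and
#'   logical `displaced`.
#' @export
displacement_analysis <- function(series, dye = c("hoechst_33258", "ethidium_bromide"),
                                  threshold = 0.05) {
  dye <- match.arg(dye)
  stopifnot(inherits(series, "titration_series"))
  f0 <- series$signal[1L]
  decrease <- (f0 - min(series$signal)) / f0
  rho <- suppressWarnings(
    stats::cor(series$quencher_conc, series$signal, method = "spearman"))
  monotone <- is.finite(rho) && rho < 0
  list(dye = dye,
       dye_mode = if (dye == "hoechst_33258") "groove_binder" else "intercalator",
       max_fractional_decrease = decrease,
       monotone = monotone,
       displaced = decrease >= threshold && monotone)
}

#' Relative viscosity from flow times
#'
#' From Ubbelohde viscometer flow times of buffer, DNA solution and
#' DNA-ligand mixture the relative viscosity is
#' \deqn{\eta/\eta_0 = \frac{(t_{complex}-t_0)/t_0}{(t_{DNA}-t_0)/t_0}
#'   = \frac{t_{complex}-t_0}{t_{DNA}-t_0},}
#' the buffer-time denominators cancelling.
#'
#' @param t_complex Flow time of the DNA-ligand mixture (s).
#' @param t_dna Flow time of the DNA-only solution (s); must exceed
#'   `t_buffer`.
#' @param t_buffer Flow time of the pure buffer (s), > 0.
#' @return Dimensionless eta/eta0.
#' @examples
#' relative_viscosity(160, 150, 100)  # 1.2
#' @export
relative_viscosity <- function(t_complex, t_dna, t_buffer) {
  if (any(t_buffer <= 0))
    stop_bindkit("bad_parameter", "buffer flow time must be > 0")
  if (any(t_dna <= t_buffer))
    stop_bindkit("degenerate_solvent",
                 "DNA flow time must exceed the buffer flow time")
  if (any(t_complex <= t_buffer))
    stop_bindkit("bad_parameter",
                 "complex flow time must exceed the buffer flow time")
  (t_complex - t_buffer) / (t_dna - t_buffer)
}

#' Viscosity profile and intercalation test
#'
#' Averages replicate flow times per sample, converts each ligand/DNA mixing
#' ratio into a relative viscosity, and regresses the cube root
#' \eqn{(\eta/\eta_0)^{1/3}} (proportional to DNA contour length) against the
#' mixing ratio. A flat profile (|slope| <= `slope_threshold`) is consistent
#' with groove binding; a rising one indicates intercalation (helix
#' lengthening); a significantly negative slope is left indeterminate.
#'
#' @param records Data frame with columns `sample_type` (one of "buffer",
#'   "dna_only", "complex"), `ligand_to_dna_ratio` (0 for buffer/dna_only),
#'   `flow_time_s` (> 0) and `replicate`.
#' @param slope_threshold Flatness threshold on the cube-root slope per unit
#'   ratio (default 0.05).
#' @return An object of class `viscosity_profile`: list with `ratios`,
#'   `relative_viscosity`, `cube_roots`, `slope`, `slope_se`,
#'   `classification` ("groove_consistent"/"intercalative"/"indeterminate").
#' @export
viscosity_profile <- function(records, slope_threshold = 0.05) {
  need <- c("sample_type", "ligand_to_dna_ratio", "flow_time_s", "replicate")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop_bindkit("missing_column",
                 paste("missing column(s):", paste(missing, collapse = ", ")))
  if (any(records$flow_time_s <= 0))
    stop_bindkit("bad_parameter", "flow times must be > 0")
  if (!any(records$sample_type == "buffer") ||
      !any(records$sample_type == "dna_only"))
    stop_bindkit("missing_reference_rows",
                 "records must include buffer and dna_only flow times")
  t_buffer <- mean(records$flow_time_s[records$sample_type == "buffer"])
  t_dna <- mean(records$flow_time_s[records$sample_type == "dna_only"])
  cx <- records[records$sample_type == "complex", ]
  ratios <- sort(unique(cx$ligand_to_dna_ratio))
  if (length(ratios) < 3L)
    stop_bindkit("insufficient_data", "need at least 3 distinct ligand/DNA ratios")
  t_complex <- vapply(ratios, function(r)
    mean(cx$flow_time_s[cx$ligand_to_dna_ratio == r]), numeric(1))
  rel <- relative_viscosity(t_complex, t_dna, t_buffer)
  cr <- rel^(1 / 3)
  fit <- summary(stats::lm(cr ~ ratios))
  slope <- fit$coefficients[2L, 1L]
  slope_se <- fit$coefficients[2L, 2L]
  classification <- if (abs(slope) <= slope_threshold) "groove_consistent"
    else if (slope > slope_threshold) "intercalative" else "indeterminate"
  structure(list(ratios = ratios, relative_viscosity = rel, cube_roots = cr,
                 slope = slope, slope_se = slope_se,
                 classification = classification),
            class = "viscosity_profile")
}

#' @export
print.viscosity_profile <- function(x, ...) {
  cat(sprintf("<viscosity_profile>  %d ratios, slope = %.4f +/- %.2g  ->  %s\n",
              length(x$ratios), x$slope, x$slope_se, x$classification))
  invisible(x)
}

#' Combine binding-mode evidence into a verdict
#'
#' Each evidence source casts one vote:
#' \itemize{
#'   \item UV shift assessment: its `mode_hint`;
#'   \item dye displacement: Hoechst displaced votes groove, EtBr displaced
#'     votes intercalative, an undisplaced dye abstains;
#'   \item viscosity profile: groove_consistent votes groove, intercalative
#'     votes intercalative;
#'   \item circular-dichroism flag: unperturbed base-stacking/helicity bands
#'     (`cd_bands_perturbed = FALSE`) vote groove, perturbed bands vote
#'     intercalative.
#' }
#' The verdict is "groove" only with at least two groove votes and zero
#' intercalative votes (symmetrically for "intercalative"); anything else is
#' "indeterminate". This mirrors how such studies triangulate several
#' orthogonal assays before committing to a mode.
#'
#' @param shift Optional [assess_absorbance_shift()] result.
#' @param displacements List (possibly empty) of [displacement_analysis()]
#'   results.
#' @param viscosity Optional [viscosity_profile()] result.
#' @param cd_bands_perturbed Optional logical CD evidence flag.
#' @return A list with `verdict`, named character vector `votes`
#'   (evidence source -> "groove"/"intercalative"/"none"), and `rationale`.
#' @export
combine_evidence <- function(shift = NULL, displacements = list(),
                             viscosity = NULL, cd_bands_perturbed = NULL) {
  votes <- character()
  rationale <- character()
  if (!is.null(shift)) {
    votes["uv_shift"] <- shift$mode_hint
    rationale <- c(rationale, sprintf(
      "UV: %s / %s shift -> %s", shift$intensity_change,
      shift$wavelength_shift, shift$mode_hint))
  }
  for (d in displacements) {
    v <- if (!d$displaced) "none"
      else if (d$dye_mode == "groove_binder") "groove" else "intercalative"
    votes[d$dye] <- v
    rationale <- c(rationale, sprintf(
      "%s (%s probe): %sdisplaced (%.1f%% decrease) -> %s",
      d$dye, d$dye_mode, if (d$displaced) "" else "not ",
      100 * d$max_fractional_decrease, v))
  }
  if (!is.null(viscosity)) {
    v <- switch(viscosity$classification,
                groove_consistent = "groove",
                intercalative = "intercalative",
                "none")
    votes["viscosity"] <- v
    rationale <- c(rationale, sprintf(
      "viscosity: cube-root slope %.3f (%s) -> %s",
      viscosity$slope, viscosity$classification, v))
  }
  if (!is.null(cd_bands_perturbed)) {
    v <- if (isTRUE(cd_bands_perturbed)) "intercalative" else "groove"
    votes["circular_dichroism"] <- v
    rationale <- c(rationale, sprintf(
      "CD bands %s -> %s",
      if (isTRUE(cd_bands_perturbed)) "perturbed" else "unperturbed", v))
  }
  if (length(votes) < 2L)
    stop_bindkit("insufficient_evidence",
                 "need at least two evidence sources for a verdict")
  n_groove <- sum(votes == "groove")
  n_inter <- sum(votes == "intercalative")
  verdict <- if (n_groove >= 2L && n_inter == 0L) "groove"
    else if (n_inter >= 2L && n_groove == 0L) "intercalative"
    else "indeterminate"
  list(verdict = verdict, votes = votes, rationale = rationale)
}
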