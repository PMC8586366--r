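#' @title Seeded synthetic-data generators
#' @description Every assay the package analyses can be emulated with known
#'   ground truth: static-quenching and binding-site titrations, Job's
#'   continuous-variation mixtures, viscometer flow times, dye-displacement
#'   series and UV titration spectra. All generators are deterministic
#'   functions of their parameters including the seed; noise is multiplicative
#'   Gaussian with a stated coefficient of variation, truncated at 4 sigma so
#'   signals stay positive, and the zero-concentration reference point is
#'   never noised (its role is to define F0 exactly).
#' @name simulate
NULL

# multiplicative CV noise, truncated at +/- 4 sigma; leaves values positive
# for cv < 0.25
mult_noise <- function(x, cv) {
  if (cv == 0) return(x)
  z <- stats::rnorm(length(x))
  z <- pmin(pmax(z, -4), 4)
  x * (1 + cv * z)
}

default_conc_grid <- function() c(0, 8, 16, 24, 32, 40, 48) * 1e-6

#' Simulate a static-quenching fluorescence titration
#'
#' Generates F([Q]) = f0 / (1 + ksv_true [Q]) - the fluorescence of a
#' fluorophore forming a 1:1 ground-state complex with the quencher, for
#' which the Stern-Volmer plot F0/F vs [Q] is exactly linear with slope
#' ksv_true - then applies multiplicative noise to every point except [Q]=0.
#'
#' @param ksv_true Ground-truth Stern-Volmer constant (L/mol).
#' @param f0 Unquenched intensity (arbitrary units, default 1000).
#' @param conc_grid Quencher concentrations in mol/L starting at 0; defaults
#'   to 0-48 uM in 8 uM steps, the grid of a typical ligand titration.
#' @param noise_cv Fractional coefficient of variation (default 0).
#' @param temperature Kelvin (default 298.15).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param series_id Label for the series.
#' @return A [titration_series].
#' @export
simulate_static_quenching <- function(ksv_true, f0 = 1000,
                                      conc_grid = default_conc_grid(),
                                      noise_cv = 0, temperature = 298.15,
                                      seed = 1L, series_id = "sim_quench") {
  stopifnot(f0 > 0, noise_cv >= 0, conc_grid[1L] == 0)
  f <- f0 / (1 + ksv_true * conc_grid)
  withr::with_seed(seed, {
    f[-1L] <- mult_noise(f[-1L], noise_cv)
  })
  titration_series(conc_grid, f, temperature = temperature,
                   series_id = series_id)
}

#' Simulate a titration following the double-log binding model
#'
#' Generates F solving (f0 - F)/F = kb_true [Q]^n_true, i.e.
#' F = f0 / (1 + kb_true [Q]^n_true). At n_true = 1 this coincides with
#' [simulate_static_quenching()] at ksv_true = kb_true.
#'
#' @param kb_true Ground-truth association constant (L/mol), > 0.
#' @param n_true Ground-truth site number, > 0.
#' @inheritParams simulate_static_quenching
#' @return A [titration_series].
#' @export
simulate_binding_site <- function(kb_true, n_true, f0 = 1000,
                                  conc_grid = default_conc_grid(),
                                  noise_cv = 0, temperature = 298.15,
                                  seed = 1L, series_id = "sim_binding") {
  stopifnot(kb_true > 0, n_true > 0, f0 > 0, conc_grid[1L] == 0)
  f <- f0 / (1 + kb_true * conc_grid^n_true)
  withr::with_seed(seed, {
    f[-1L] <- mult_noise(f[-1L], noise_cv)
  })
  titration_series(conc_grid, f, temperature = temperature,
                   series_id = series_id)
}

#' Equilibrium complex concentration in a two-component mixture
#'
#' For a 1:1 complex with association constant K, total ligand L and total
#' macromolecule P, the complex concentration is the smaller root of
#' \deqn{C^2 - (P + L + 1/K) C + P L = 0,}
#' which respects both mass balances (C <= min(L, P)).
#'
#' @param ligand_total,macro_total Total concentrations in mol/L.
#' @param k_assoc Association constant in L/mol, > 0.
#' @return Complex concentration in mol/L.
#' @export
complex_concentration_1to1 <- function(ligand_total, macro_total, k_assoc) {
  stopifnot(k_assoc > 0)
  b <- ligand_total + macro_total + 1 / k_assoc
  disc <- b^2 - 4 * ligand_total * macro_total
  cc <- (b - sqrt(disc)) / 2
  bad <- cc < -1e-15 | cc > pmin(ligand_total, macro_total) * (1 + 1e-9)
  if (any(bad))
    stop_bindkit("nonphysical_root", "equilibrium root violates mass balance")
  pmax(cc, 0)
}

#' Simulate a Job's continuous-variation series
#'
#' At each ligand mole fraction x of the grid, the totals are L = x C_T and
#' P = (1-x) C_T at fixed total concentration C_T. For 1:1 stoichiometry the
#' complex concentration comes from the mass-action quadratic
#' ([complex_concentration_1to1()]); for a general m:n complex the
#' strong-binding limiting-reagent approximation min(L/m, P/n) is used. The
#' corrected absorbance is `response_coefficient` times the complex
#' concentration, plus multiplicative noise.
#'
#' @param k_assoc Association constant (L/mol); used only for 1:1.
#' @param total_conc Fixed total concentration C_T in mol/L (default 20 uM,
#'   a typical continuous-variation working concentration).
#' @param m,n Ligand:macromolecule stoichiometry (small integers, default
#'   1:1).
#' @param mole_fraction_grid Ligand mole fractions in (0,1); default
#'   0.1-0.9 in steps of 0.1.
#' @param response_coefficient Absorbance per mol/L of complex (default 2e4).
#' @param noise_cv Fractional CV of the absorbance noise (default 0).
#' @param seed Integer seed.
#' @return A data frame of Job records suitable for [build_job_curve()]
#'   (columns `mole_fraction_ligand`, `absorbance_mix`, `total_conc`), with
#'   the ground-truth complex concentrations in attribute `complex_conc`.
#' @export
simulate_job <- function(k_assoc = 1e6, total_conc = 20e-6, m = 1L, n = 1L,
                         mole_fraction_grid = seq(0.1, 0.9, by = 0.1),
                         response_coefficient = 2e4, noise_cv = 0, seed = 1L) {
  stopifnot(total_conc > 0, all(mole_fraction_grid > 0),
            all(mole_fraction_grid < 1), m >= 1, n >= 1)
  x <- mole_fraction_grid
  lig <- x * total_conc
  mac <- (1 - x) * total_conc
  cc <- if (m == 1L && n == 1L) {
    complex_concentration_1to1(lig, mac, k_assoc)
  } else {
    pmin(lig / m, mac / n)  # strong-binding limiting-reagent approximation
  }
  a <- response_coefficient * cc
  withr::with_seed(seed, {
    a <- mult_noise(a, noise_cv)
  })
  out <- data.frame(mole_fraction_ligand = x, absorbance_mix = a,
                    total_conc = total_conc)
  attr(out, "complex_conc") <- cc
  out
}

#' Simulate viscometer flow-time records
#'
#' Inverts the relative-viscosity relation: the target profile is
#' \eqn{(\eta/\eta_0)^{1/3} = 1 + s \cdot ratio} with cube-root slope s = 0
#' for a groove binder (no helix lengthening) and s > 0 for an intercalator;
#' flow times are back-computed as
#' t_complex = t_buffer + (eta/eta0) (t_dna - t_buffer), with three noisy
#' replicates per ratio plus buffer and DNA-only reference rows.
#'
#' @param mode `"groove"` or `"intercalator"`.
#' @param cube_root_slope Slope of the cube-root profile per unit ratio;
#'   defaults to 0 for groove mode and 0.1 for an intercalator.
#' @param ratio_grid Ligand/DNA mixing ratios (default 0.2-1.0 by 0.2).
#' @param t_buffer,t_dna Reference flow times in seconds (defaults 100 and
#'   150 s); `t_dna > t_buffer`.
#' @param noise_cv Fractional CV applied to individual flow-time replicates.
#' @param replicates Replicates per sample (default 3).
#' @param seed Integer seed.
#' @return Data frame with columns `sample_type`, `ligand_to_dna_ratio`,
#'   `flow_time_s`, `replicate`, suitable for [viscosity_profile()].
#' @export
simulate_viscosity <- function(mode = c("groove", "intercalator"),
                               cube_root_slope = NULL,
                               ratio_grid = seq(0.2, 1, by = 0.2),
                               t_buffer = 100, t_dna = 150,
                               noise_cv = 0, replicates = 3L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(cube_root_slope))
    cube_root_slope <- if (mode == "groove") 0 else 0.1
  stopifnot(t_dna > t_buffer, t_buffer > 0, noise_cv >= 0)
  rel <- (1 + cube_root_slope * ratio_grid)^3
  t_complex <- t_buffer + rel * (t_dna - t_buffer)
  withr::with_seed(seed, {
    ref <- data.frame(
      sample_type = rep(c("buffer", "dna_only"), each = replicates),
      ligand_to_dna_ratio = 0,
      flow_time_s = mult_noise(rep(c(t_buffer, t_dna), each = replicates), noise_cv),
      replicate = rep(seq_len(replicates), 2L))
    cx <- data.frame(
      sample_type = "complex",
      ligand_to_dna_ratio = rep(ratio_grid, each = replicates),
      flow_time_s = mult_noise(rep(t_complex, each = replicates), noise_cv),
      replicate = rep(seq_len(replicates), length(ratio_grid)))
  })
  rbind(ref, cx)
}

#' Simulate a dye-displacement titration
#'
#' A dye whose DNA-binding mode matches the ligand's is displaced, so its
#' complex emission decays like a static-quenching curve with constant
#' `ksv_true`; a mismatched dye stays bound and its emission is flat at `f0`
#' (plus noise). Hoechst 33258 is the groove probe, ethidium bromide the
#' intercalation probe.
#'
#' @param dye `"hoechst_33258"` or `"ethidium_bromide"`.
#' @param mode Ligand binding mode, `"groove"` or `"intercalative"`.
#' @param ksv_true Displacement decay constant when dye and mode match
#'   (default 2e4 L/mol).
#' @inheritParams simulate_static_quenching
#' @return A [titration_series] of the dye-DNA complex emission.
#' @export
simulate_displacement <- function(dye = c("hoechst_33258", "ethidium_bromide"),
                                  mode = c("groove", "intercalative"),
                                  ksv_true = 2e4, f0 = 1000,
                                  conc_grid = default_conc_grid(),
                                  noise_cv = 0, seed = 1L) {
  dye <- match.arg(dye)
  mode <- match.arg(mode)
  matched <- (dye == "hoechst_33258" && mode == "groove") ||
    (dye == "ethidium_bromide" && mode == "intercalative")
  f <- if (matched) f0 / (1 + ksv_true * conc_grid) else rep(f0, length(conc_grid))
  withr::with_seed(seed, {
    f[-1L] <- mult_noise(f[-1L], noise_cv)
  })
  titration_series(conc_grid, f, series_id = paste(dye, mode, sep = "_"))
}

#' Simulate a UV titration spectral series
#'
#' Produces a sequence of Gaussian absorption bands for increasing ligand
#' additions: in groove mode the band height grows 2% per step with no
#' shift (hyperchromism); in intercalative mode it shrinks 2% per step and
#' shifts -0.5 nm per step (hypochromism with a blue shift). The first scan
#' is the free macromolecule.
#'
#' @param mode `"groove"` or `"intercalative"`.
#' @param peak_nm Band centre of the free macromolecule (default 278 nm, the
#'   aromatic protein band).
#' @param n_steps Number of scans including the free spectrum (>= 2).
#' @param growth_per_step Fractional height change per step (default 0.02,
#'   signed by mode).
#' @param shift_per_step_nm Band shift per step in intercalative mode
#'   (default -0.5 nm).
#' @param band_sd_nm Gaussian band width (default 20 nm).
#' @param seed Integer seed (reserved; the default generator is noiseless).
#' @return A list of scans, each a data frame with `wavelength_nm`, `value`,
#'   and attribute `condition_label`.
#' @export
simulate_uv_titration <- function(mode = c("groove", "intercalative"),
                                  peak_nm = 278, n_steps = 5L,
                                  growth_per_step = 0.02,
                                  shift_per_step_nm = -0.5,
                                  band_sd_nm = 20, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_steps >= 2L)
  wl <- seq(peak_nm - 60, peak_nm + 60, by = 1)
  lapply(seq_len(n_steps) - 1L, function(step) {
    h <- if (mode == "groove") 1 + growth_per_step * step
         else 1 - growth_per_step * step
    centre <- if (mode == "groove") peak_nm else peak_nm + shift_per_step_nm * step
    scan <- data.frame(wavelength_nm = wl,
                       value = h * exp(-(wl - centre)^2 / (2 * band_sd_nm^2)))
    attr(scan, "condition_label") <- sprintf("addition_%d", step)
    scan
  })
}
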