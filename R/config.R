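#' Analysis configuration
#'
#' Bundles the physical constants and decision thresholds shared across the
#' analysis stages. Defaults reflect common practice for protein/DNA optical
#' binding studies:
#' \describe{
#'   \item{tau0_s}{Unquenched fluorophore lifetime in seconds (1e-8 s), used
#'     to convert the Stern-Volmer constant Ksv into the bimolecular quenching
#'     constant Kq = Ksv/tau0.}
#'   \item{diffusion_limit}{Maximum diffusion-controlled (scattering) quenching
#'     constant, 1e10 L mol^-1 s^-1; Kq above it indicates ground-state complex
#'     formation (static quenching).}
#'   \item{gas_constant_kcal}{R in kcal mol^-1 K^-1 (1.9872e-3) so Gibbs free
#'     energies land in kcal/mol.}
#'   \item{epsilon_dna}{Single-strand ct-DNA extinction coefficient at 260 nm,
#'     6600 L mol^-1 cm^-1.}
#'   \item{path_length_cm}{Cuvette path length, 1 cm.}
#'   \item{purity_window}{A260/A280 acceptance window, c(1.8, 1.9).}
#'   \item{viscosity_slope_threshold}{Absolute slope of (eta/eta0)^(1/3) vs
#'     mixing ratio below which a profile counts as flat (0.05).}
#'   \item{displacement_threshold}{Minimum fractional intensity decrease for a
#'     dye to count as displaced (0.05).}
#'   \item{random_seed}{Seed handed to the synthetic-data generators.}
#' }
#'
#' @param ... Named overrides of the fields above.
#' @return An object of class `analysis_config`.
#' @examples
#' cfg <- analysis_config(tau0_s = 1e-8)
#' cfg$diffusion_limit
#' @export
analysis_config <- function(...) {
  cfg <- list(tau0_s = 1e-8,
              diffusion_limit = 1e10,
              gas_constant_kcal = 1.9872e-3,
              epsilon_dna = 6600,
              path_length_cm = 1.0,
              purity_window = c(1.8, 1.9),
              viscosity_slope_threshold = 0.05,
              displacement_threshold = 0.05,
              random_seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_bindkit("bad_parameter",
                 paste("unknown config field(s):", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  for (f in c("tau0_s", "diffusion_limit", "gas_constant_kcal", "epsilon_dna",
              "path_length_cm"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop_bindkit("bad_parameter", sprintf("config field '%s' must be > 0", f))
  if (cfg$purity_window[1L] >= cfg$purity_window[2L])
    stop_bindkit("bad_parameter", "purity_window low must be < high")
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' The file holds a flat mapping of [analysis_config()] field names to values;
#' fields not present keep their defaults. Format is chosen by extension
#' (`.json` vs `.yaml`/`.yml`).
#'
#' @param path Path to the configuration file.
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(analysis_config, as.list(vals))
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (f in names(x)) {
    cat(sprintf("  %-26s %s\n", f, paste(format(x[[f]]), collapse = ", ")))
  }
  invisible(x)
}
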