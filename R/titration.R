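#' Fluorescence/absorbance titration series
#'
#' A `titration_series` holds one quencher-concentration versus signal curve
#' recorded at a fixed temperature: the raw input of every quenching and
#' binding fit in the package. The first point must be at zero quencher
#' concentration; its signal defines the reference intensity F0 of the free
#' macromolecule. All concentrations are stored in mol/L and temperatures in
#' kelvin; micromolar and degrees Celsius are accepted only at the I/O
#' boundary.
#'
#' @param quencher_conc Numeric vector of quencher concentrations in mol/L,
#'   strictly increasing, starting at exactly 0.
#' @param signal Numeric vector of positive intensities (arbitrary units),
#'   same length as `quencher_conc`.
#' @param temperature Temperature in kelvin.
#' @param series_id Text label for the series.
#' @param macromolecule_conc Optional macromolecule concentration in mol/L.
#' @param excitation_nm,emission_nm Optional wavelengths in nm.
#'
#' @return An object of class `titration_series`.
#' @examples
#' ts <- titration_series(c(0, 8e-6, 1.6e-5, 2.4e-5), c(1000, 960, 925, 890),
#'                        temperature = 298.15)
#' ts
#' @export
titration_series <- function(quencher_conc, signal, temperature = 298.15,
                             series_id = "series", macromolecule_conc = NA_real_,
                             excitation_nm = NA_real_, emission_nm = NA_real_) {
  quencher_conc <- as.numeric(quencher_conc)
  signal <- as.numeric(signal)
  if (length(quencher_conc) != length(signal))
    stop_bindkit("length_mismatch", sprintf(
      "series '%s': %d concentrations but %d signals",
      series_id, length(quencher_conc), length(signal)))
  if (length(quencher_conc) < 4L)
    stop_bindkit("too_few_points", sprintf(
      "series '%s': need at least 4 titration points, got %d",
      series_id, length(quencher_conc)))
  if (anyNA(quencher_conc) || anyNA(signal))
    stop_bindkit("non_numeric", sprintf("series '%s': NA in data", series_id))
  if (any(duplicated(quencher_conc)))
    stop_bindkit("duplicate_concentration", sprintf(
      "series '%s': duplicate quencher concentrations", series_id))
  if (is.unsorted(quencher_conc, strictly = TRUE))
    stop_bindkit("unsorted_concentration", sprintf(
      "series '%s': concentrations must be strictly increasing", series_id))
  if (quencher_conc[1L] != 0)
    stop_bindkit("missing_zero_row", sprintf(
      "series '%s': first concentration must be exactly 0 (defines F0)",
      series_id))
  if (any(signal <= 0))
    stop_bindkit("nonpositive_signal", sprintf(
      "series '%s': all signals must be > 0", series_id))
  if (!is.finite(temperature) || temperature <= 0)
    stop_bindkit("bad_temperature", sprintf(
      "series '%s': temperature must be a positive kelvin value", series_id))
  structure(
    list(series_id = as.character(series_id),
         temperature = as.numeric(temperature),
         quencher_conc = quencher_conc,
         signal = signal,
         macromolecule_conc = as.numeric(macromolecule_conc),
         excitation_nm = as.numeric(excitation_nm),
         emission_nm = as.numeric(emission_nm)),
    class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series '%s'>  %d points, T = %.2f K\n",
              x$series_id, length(x$signal), x$temperature))
  cat(sprintf("  [Q]: 0 to %.3g mol/L;  F0 = %.6g\n",
              max(x$quencher_conc), x$signal[1L]))
  invisible(x)
}

# classed conditions so callers can distinguish validation failures
stop_bindkit <- function(class, message) {
  stop(structure(class = c(paste0("bindkit_", class), "bindkit_error",
                           "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

#' Read titration series from a delimited text file
#'
#' Reads a comma- or tab-delimited table (auto-detected from the header line)
#' with columns `series_id`, `temperature_C`, and `conc_uM` (or `conc_M`) and
#' `signal`. Rows are grouped by `(series_id, temperature_C)` into one
#' [titration_series] per group, concentrations converted to mol/L and sorted
#' ascending, and each group validated (zero-concentration row present, no
#' duplicates, positive signals).
#'
#' @param path Path to the delimited file.
#' @return A list of [titration_series], ordered by first appearance.
#' @export
read_titration_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("series_id", "temperature_C")
  conc_col <- intersect(c("conc_uM", "conc_M"), names(df))
  if (length(conc_col) == 0L)
    stop_bindkit("missing_column", "need a 'conc_uM' or 'conc_M' column")
  missing <- setdiff(c(need, "signal"), names(df))
  if (length(missing))
    stop_bindkit("missing_column",
                 paste("missing column(s):", paste(missing, collapse = ", ")))
  for (col in c("temperature_C", conc_col[1L], "signal")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && !all(is.na(df[[col]]) == is.na(v)))
      stop_bindkit("non_numeric", sprintf("non-numeric value in column '%s'", col))
    if (anyNA(v))
      stop_bindkit("non_numeric", sprintf("non-numeric value in column '%s'", col))
    df[[col]] <- v
  }
  conv <- if (conc_col[1L] == "conc_uM") 1e-6 else 1
  keys <- unique(df[c("series_id", "temperature_C")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$series_id == keys$series_id[i] &
              df$temperature_C == keys$temperature_C[i], ]
    ord <- order(sub[[conc_col[1L]]])
    out[[i]] <- titration_series(
      quencher_conc = sub[[conc_col[1L]]][ord] * conv,
      signal = sub$signal[ord],
      temperature = keys$temperature_C[i] + 273.15,
      series_id = keys$series_id[i])
  }
  out
}

#' Write titration series to a delimited text file
#'
#' Inverse of [read_titration_table()]: writes one or more series to a CSV
#' with columns `series_id,temperature_C,conc_M,signal`, preserving numeric
#' values at full precision so a read/write round trip is lossless.
#'
#' @param series A [titration_series] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration_table <- function(series, path) {
  if (inherits(series, "titration_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(series_id = s$series_id,
               temperature_C = s$temperature - 273.15,
               conc_M = s$quencher_conc,
               signal = s$signal,
               stringsAsFactors = FALSE)
  }))
  # format() with digits = 17 keeps doubles exact through the round trip
  rows$conc_M <- formatC(rows$conc_M, digits = 17, format = "g")
  rows$signal <- formatC(rows$signal, digits = 17, format = "g")
  rows$temperature_C <- formatC(rows$temperature_C, digits = 17, format = "g")
  utils::write.table(rows, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
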