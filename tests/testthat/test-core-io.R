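test_that("titration tables read, group, convert units and validate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("series_id,temperature_C,conc_uM,signal",
               "bsa,25,0,1000",
               "bsa,25,8,960",
               "bsa,25,16,925",
               "bsa,25,24,890"), path)
  ser <- read_titration_table(path)
  expect_length(ser, 1L)
  expect_equal(ser[[1]]$quencher_conc, c(0, 8e-6, 1.6e-5, 2.4e-5))
  expect_equal(ser[[1]]$temperature, 298.15)

  # interleaved series ids split and sort independently of row order
  writeLines(c("series_id,temperature_C,conc_uM,signal",
               "a,25,16,900", "b,25,0,500", "a,25,0,1000", "b,25,24,420",
               "a,25,24,850", "b,25,8,470", "a,25,8,950", "b,25,16,440"),
             path)
  ser <- read_titration_table(path)
  expect_length(ser, 2L)
  byid <- setNames(ser, vapply(ser, `[[`, "", "series_id"))
  expect_equal(byid$a$quencher_conc, c(0, 8, 16, 24) * 1e-6)
  expect_equal(byid$a$signal, c(1000, 950, 900, 850))
  expect_equal(byid$b$signal, c(500, 470, 440, 420))

  # tab-delimited with conc_M is accepted without rescaling
  writeLines(c("series_id\ttemperature_C\tconc_M\tsignal",
               "a\t25\t0\t1000", "a\t25\t8e-6\t950",
               "a\t25\t1.6e-5\t900", "a\t25\t2.4e-5\t850"), path)
  expect_equal(read_titration_table(path)[[1]]$quencher_conc,
               c(0, 8, 16, 24) * 1e-6)
})

test_that("malformed titration tables raise distinct named errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("series_id,temperature_C,conc_uM,signal",
               "a,25,8,960", "a,25,16,925", "a,25,24,890", "a,25,32,850"),
             path)
  expect_error(read_titration_table(path), class = "bindkit_missing_zero_row")

  writeLines(c("series_id,temperature_C,signal", "a,25,1000"), path)
  expect_error(read_titration_table(path), class = "bindkit_missing_column")

  writeLines(c("series_id,temperature_C,conc_uM,signal",
               "a,25,0,1000", "a,25,8,abc", "a,25,16,925", "a,25,24,890"),
             path)
  expect_error(read_titration_table(path), class = "bindkit_non_numeric")

  writeLines(c("series_id,temperature_C,conc_uM,signal",
               "a,25,0,1000", "a,25,8,960", "a,25,8,955", "a,25,24,890"),
             path)
  expect_error(read_titration_table(path),
               class = "bindkit_duplicate_concentration")
})

test_that("write/read round trip preserves numeric fields exactly", {
  ts <- simulate_static_quenching(ksv_true = 4.2e4, noise_cv = 0.02, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration_table(ts, path)
  back <- read_titration_table(path)[[1]]
  expect_identical(back$quencher_conc, ts$quencher_conc)
  expect_identical(back$signal, ts$signal)
  expect_equal(back$temperature, ts$temperature)
})

test_that("Beer-Lambert concentration is correct and homogeneous in A", {
  expect_equal(concentration_from_absorbance(0, 6600), 0)
  # a ct-DNA stock read at 260 nm: A = 0.4752 over 1 cm -> 72 uM
  expect_equal(concentration_from_absorbance(0.4752, 6600, 1), 7.2e-5)
  expect_equal(concentration_from_absorbance(0.66, 6600, 1), 1e-4)
  a <- c(0.1, 0.3, 0.9)
  expect_equal(concentration_from_absorbance(3 * a, 6600),
               3 * concentration_from_absorbance(a, 6600))
  expect_error(concentration_from_absorbance(0.5, -1),
               class = "bindkit_bad_parameter")
  expect_error(concentration_from_absorbance(0.5, 6600, 0),
               class = "bindkit_bad_parameter")
})

test_that("A260/A280 purity window flags protein-free DNA", {
  expect_true(purity_ratio(1.85, 1.0)$pass)
  expect_equal(purity_ratio(1.85, 1.0)$ratio, 1.85)
  expect_false(purity_ratio(1.0, 1.0)$pass)
  expect_false(purity_ratio(1.95, 1.0)$pass)
  expect_error(purity_ratio(1.8, 0), class = "bindkit_division_error")
})

test_that("config carries defaults, overrides and file round trip", {
  cfg <- analysis_config()
  expect_equal(cfg$tau0_s, 1e-8)
  expect_equal(cfg$diffusion_limit, 1e10)
  expect_equal(cfg$gas_constant_kcal, 1.9872e-3)
  expect_equal(analysis_config(tau0_s = 2e-8)$tau0_s, 2e-8)
  expect_error(analysis_config(bogus = 1), class = "bindkit_bad_parameter")
  expect_error(analysis_config(tau0_s = -1), class = "bindkit_bad_parameter")

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("tau0_s: 5.0e-9", "displacement_threshold: 0.1"), path)
  cfg <- read_analysis_config(path)
  expect_equal(cfg$tau0_s, 5e-9)
  expect_equal(cfg$displacement_threshold, 0.1)
  expect_equal(cfg$epsilon_dna, 6600)

  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines('{"tau0_s": 5e-9}', jpath)
  expect_equal(read_analysis_config(jpath)$tau0_s, 5e-9)
})

test_that("series constructor enforces its invariants", {
  expect_error(titration_series(c(0, 1e-6, 2e-6), c(1, 1, 1)),
               class = "bindkit_too_few_points")
  expect_error(titration_series(c(0, 2e-6, 1e-6, 3e-6), rep(1, 4)),
               class = "bindkit_unsorted_concentration")
  expect_error(titration_series(c(0, 1e-6, 2e-6, 3e-6), c(1, 1, -1, 1)),
               class = "bindkit_nonpositive_signal")
  expect_error(titration_series(c(0, 1e-6, 2e-6, 3e-6), c(1, 1, 1)),
               class = "bindkit_length_mismatch")
})
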