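test_that("absorbance shift assessment follows the hyper/hypo rule table", {
  scans <- simulate_uv_titration("groove", n_steps = 5)
  same <- assess_absorbance_shift(scans[[1]], scans[[1]])
  expect_equal(same$intensity_change, "none")
  expect_equal(same$wavelength_shift, "none")
  expect_equal(same$mode_hint, "none")

  # growing band, unshifted: hyperchromism -> groove hint
  up <- assess_absorbance_shift(scans[[1]], scans[[5]])
  expect_equal(up$intensity_change, "hyperchromic")
  expect_equal(up$wavelength_shift, "none")
  expect_equal(up$mode_hint, "groove")
  expect_gt(up$delta_intensity_fraction, 0.05)

  # shrinking, blue-shifting band: intercalative hint
  iscans <- simulate_uv_titration("intercalative", n_steps = 7)
  down <- assess_absorbance_shift(iscans[[1]], iscans[[7]])
  expect_equal(down$intensity_change, "hypochromic")
  expect_equal(down$wavelength_shift, "blue")
  expect_equal(down$mode_hint, "intercalative")

  # peak on the scan edge is an error
  edge <- data.frame(wavelength_nm = 1:5, value = 5:1)
  expect_error(assess_absorbance_shift(edge, edge),
               class = "bindkit_boundary_peak")
})

test_that("dye displacement needs both magnitude and monotone trend", {
  grid <- c(0, 8, 16, 24, 32, 40) * 1e-6
  drop40 <- titration_series(grid, 1000 * seq(1, 0.6, length.out = 6))
  res <- displacement_analysis(drop40, "hoechst_33258")
  expect_true(res$displaced)
  expect_equal(res$max_fractional_decrease, 0.4)
  expect_equal(res$dye_mode, "groove_binder")

  flat <- titration_series(grid, 1000 * c(1, 1.004, 0.998, 1.002, 0.996, 1.001))
  res <- displacement_analysis(flat, "ethidium_bromide")
  expect_false(res$displaced)
  expect_equal(res$dye_mode, "intercalator")

  # a 3% drop stays below the 5% threshold even when monotone
  small <- titration_series(grid, 1000 * seq(1, 0.97, length.out = 6))
  expect_false(displacement_analysis(small, "hoechst_33258")$displaced)

  # a single-point dip without a trend does not count as displacement
  dip <- titration_series(grid, 1000 * c(1, 1.01, 0.90, 1.02, 1.01, 1.02))
  expect_false(displacement_analysis(dip, "hoechst_33258")$displaced)
})

test_that("relative viscosity ratio and its invariances", {
  expect_equal(relative_viscosity(150, 150, 100), 1)
  expect_equal(relative_viscosity(160, 150, 100), 1.2)
  # homogeneous of degree 0 in the buffer-referenced differences
  expect_equal(relative_viscosity(100 + 5 * 60, 100 + 5 * 50, 100),
               relative_viscosity(160, 150, 100))
  # invariant under a common shift of all times (buffer included)
  expect_equal(relative_viscosity(170, 160, 110), relative_viscosity(160, 150, 100))
  expect_error(relative_viscosity(160, 90, 100),
               class = "bindkit_degenerate_solvent")
})

test_that("viscosity profiles classify flat vs rising cube-root slopes", {
  flat <- simulate_viscosity("groove", noise_cv = 0)
  prof <- viscosity_profile(flat)
  expect_equal(prof$slope, 0, tolerance = 1e-9)
  expect_equal(prof$classification, "groove_consistent")
  expect_equal(prof$relative_viscosity, rep(1, 5), tolerance = 1e-12)

  rising <- simulate_viscosity("intercalator", cube_root_slope = 0.1,
                               noise_cv = 0)
  prof <- viscosity_profile(rising)
  expect_equal(prof$slope, 0.1, tolerance = 1e-9)
  expect_equal(prof$classification, "intercalative")

  expect_error(viscosity_profile(flat[flat$sample_type == "complex", ]),
               class = "bindkit_missing_reference_rows")
})

test_that("viscosity classifier is exact on labelled noisy profiles", {
  correct <- 0L
  for (s in 1:100) {
    g <- viscosity_profile(simulate_viscosity("groove", noise_cv = 0.01,
                                              seed = s))
    i <- viscosity_profile(simulate_viscosity("intercalator",
                                              cube_root_slope = 0.5,
                                              noise_cv = 0.01, seed = s))
    correct <- correct + (g$classification == "groove_consistent") +
      (i$classification == "intercalative")
  }
  expect_equal(correct, 200L)
})

test_that("evidence combiner reproduces the canonical verdict patterns", {
  scans <- simulate_uv_titration("groove", n_steps = 5)
  shift <- assess_absorbance_shift(scans[[1]], scans[[5]])
  hoechst <- displacement_analysis(
    simulate_displacement("hoechst_33258", "groove"), "hoechst_33258")
  etbr <- displacement_analysis(
    simulate_displacement("ethidium_bromide", "groove"), "ethidium_bromide")
  visc <- viscosity_profile(simulate_viscosity("groove"))
  v <- combine_evidence(shift, list(hoechst, etbr), visc,
                        cd_bands_perturbed = FALSE)
  expect_equal(v$verdict, "groove")
  expect_equal(unname(v$votes[c("uv_shift", "hoechst_33258",
                                "ethidium_bromide", "viscosity",
                                "circular_dichroism")]),
               c("groove", "groove", "none", "groove", "groove"))

  # mirrored pattern
  iscans <- simulate_uv_titration("intercalative", n_steps = 5)
  ishift <- assess_absorbance_shift(iscans[[1]], iscans[[5]])
  ietbr <- displacement_analysis(
    simulate_displacement("ethidium_bromide", "intercalative"),
    "ethidium_bromide")
  ivisc <- viscosity_profile(simulate_viscosity("intercalator"))
  v <- combine_evidence(ishift, list(ietbr), ivisc)
  expect_equal(v$verdict, "intercalative")

  # a tie is indeterminate
  v <- combine_evidence(shift, list(ietbr))
  expect_equal(v$verdict, "indeterminate")

  expect_error(combine_evidence(shift), class = "bindkit_insufficient_evidence")
})

test_that("the verdict never contradicts a dissenting vote (exhaustive)", {
  # enumerate all vote patterns over four sources via crafted inputs
  hints <- c("groove", "intercalative", "none")
  fake_shift <- function(h) list(intensity_change = "x", wavelength_shift = "x",
                                 mode_hint = h)
  fake_disp <- function(h) list(dye = "hoechst_33258",
                                dye_mode = "groove_binder",
                                max_fractional_decrease = 0.4,
                                displaced = h == "groove")
  fake_disp2 <- function(h) list(dye = "ethidium_bromide",
                                 dye_mode = "intercalator",
                                 max_fractional_decrease = 0.4,
                                 displaced = h == "intercalative")
  fake_visc <- function(h) structure(list(
    slope = 0, classification = switch(h, groove = "groove_consistent",
                                       intercalative = "intercalative",
                                       "indeterminate")),
    class = "viscosity_profile")
  for (h1 in hints) for (h2 in hints) for (h3 in hints) for (h4 in hints) {
    v <- combine_evidence(fake_shift(h1),
                          list(fake_disp(h2), fake_disp2(h3)),
                          fake_visc(h4))
    votes <- c(h1,
               if (h2 == "groove") "groove" else "none",
               if (h3 == "intercalative") "intercalative" else "none",
               h4)
    # brute-force oracle over the vote pattern
    expected <- if (sum(votes == "groove") >= 2 &&
                    sum(votes == "intercalative") == 0) "groove"
      else if (sum(votes == "intercalative") >= 2 &&
               sum(votes == "groove") == 0) "intercalative"
      else "indeterminate"
    expect_equal(v$verdict, expected)
    if (any(votes == "intercalative")) expect_false(v$verdict == "groove")
  }
})
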