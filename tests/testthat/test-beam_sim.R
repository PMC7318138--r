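# settings with no upstream material, for tests of the bare transport
bare <- function() beam_settings(beamline_wet_mm = 0)

test_that("a zero-spread layer at the surface is a delta at the nominal energy", {
  sp <- depth_energy_spectrum(beam_layer(100, sigma_e = 0), 0, bare())
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$e_mid, 100)
  expect_equal(sum(sp$fluence), 1, tolerance = 1e-9)
})

test_that("the spectrum vanishes beyond the range plus five straggling widths", {
  ly <- beam_layer(62.4)
  R0 <- 10 * csda_range(62.4)  # mm
  sp <- depth_energy_spectrum(ly, 1.2 * R0, bare())
  expect_equal(nrow(sp), 0L)
  expect_equal(sum(depth_dose(beam_config(ly), R0 * 1.2, bare())), 0)
})

test_that("the mean energy at depth matches an independent residual-range root-find", {
  ly <- beam_layer(179.7, sigma_e = 0.5)
  sp <- depth_energy_spectrum(ly, 20, bare())
  e_mean <- weighted.mean(sp$e_mid, sp$fluence)
  # oracle: solve csda_range(E) = csda_range(179.7) - 2 cm
  target <- csda_range(179.7) - 2
  e_oracle <- uniroot(function(e) csda_range(e) - target, c(50, 179.7),
                      tol = 1e-8)$root
  expect_equal(e_mean, e_oracle, tolerance = 2e-3)
})

test_that("energy bins map onto the LET grid with exact bookkeeping", {
  # delta at 5 MeV lands in the bin containing 7.9 keV/um
  d5 <- depth_energy_spectrum(beam_layer(5, sigma_e = 0), 0, bare())
  lsp <- spectrum_to_let(d5)
  occ <- which(lsp$dose_per_bin > 0)
  expect_length(occ, 1L)
  expect_lte(lsp$bin_edges[occ], 7.9)
  expect_gte(lsp$bin_edges[occ + 1], 7.9)

  # conservation of fluence and fluence-weighted Sw under rebinning
  sp <- depth_energy_spectrum(beam_layer(62.4), 28, bare())
  lsp2 <- spectrum_to_let(sp)
  expect_equal(sum(lsp2$fluence_per_bin), sum(sp$fluence), tolerance = 1e-9)
  expect_equal(sum(lsp2$dose_per_bin),
               sum(sp$fluence * stopping_power_water(sp$e_mid)),
               tolerance = 1e-9)

  # two well-separated monoenergetic components occupy exactly two bins
  d1 <- depth_energy_spectrum(beam_layer(5, sigma_e = 0), 0, bare())
  d2 <- depth_energy_spectrum(beam_layer(100, sigma_e = 0), 0, bare())
  lsp3 <- spectrum_to_let(list(d1, d2))
  expect_equal(sum(lsp3$dose_per_bin > 0), 2L)
})

test_that("LET averages obey their defining arithmetic", {
  # single occupied bin: both averages equal the bin centre
  s1 <- single_bin_spectrum(3.1, 1)
  expect_equal(ld_of(s1), lt_of(s1))
  expect_equal(ld_of(s1), bin_centers(s1)[1])

  # equal fluence at S = 1 and S = 3: Lt = 2, Ld = (1+9)/(1+3) = 2.5
  edges <- seq(0.975, 3.025, by = 0.05)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  phi <- numeric(length(mid)); phi[c(1, length(phi))] <- 1
  s2 <- let_spectrum(edges, phi * mid, fluence_per_bin = phi)
  expect_equal(lt_of(s2), 2.0, tolerance = 1e-12)
  expect_equal(ld_of(s2), 2.5, tolerance = 1e-12)

  expect_error(ld_of(let_spectrum(c(1, 1.05), 0)), "all-zero")
})

test_that("dose-averaged LET is never below fluence-averaged LET", {
  specs <- c(
    lapply(c(10, 20, 28, 31), function(z)
      beam_let_spectrum(beam_layer(62.4), z, settings = bare())),
    list(beam_let_spectrum(beam_layer(179.7), 20, settings = bare()),
         cached("b2_spec_33", beam_let_spectrum(
           cached("b2", beam_b2()), 33, settings = beam_settings()))))
  for (sp in specs) {
    expect_gte(ld_of(sp), lt_of(sp))
    if (sum(sp$dose_per_bin > 0) > 1) expect_gt(ld_of(sp), lt_of(sp))
  }
})

test_that("dose-averaged LET rises monotonically through a pristine Bragg peak", {
  ly <- beam_config(beam_layer(62.4))
  pr <- depth_profile(ly, seq(2, 30, by = 2), bare())
  expect_true(all(diff(pr$ld_keV_um) > 0))
  expect_true(all(pr$ld_keV_um >= pr$lt_keV_um))
})

test_that("SOBP weighting solves the plateau to its expected residual", {
  # single layer, single depth: exact scaling
  ly <- beam_layer(64)
  one <- sobp_weights(list(ly), plateau = c(31, 31), target_dose = 2)
  d <- depth_dose(beam_config(ly), 31)
  expect_equal(one$weights * d, 2, tolerance = 1e-9)
  expect_lt(one$flatness, 1e-9)

  # six published layers flatten 30-35 mm to within 2% everywhere
  layers <- lapply(seq(62.4, 67.5, length.out = 6), beam_layer)
  fit <- cached("sobp_fit_b1", sobp_weights(layers))
  expect_true(all(fit$weights >= 0))
  expect_lt(fit$flatness, 0.02)

  # zero target gives zero weights; infeasible plateau errors
  z0 <- sobp_weights(list(ly), plateau = c(31, 31), target_dose = 0)
  expect_equal(z0$weights, 0)
  expect_error(sobp_weights(list(ly), plateau = c(300, 310)), "infeasible")
})

test_that("low-LET superposition preserves plateau dose and weight bookkeeping", {
  b1 <- cached("b1", beam_b1())
  z <- seq(30, 35, by = 0.25)
  d1 <- mean(depth_dose(b1, z))

  # fraction 0 returns the base beam unchanged
  expect_identical(add_low_let_beam(b1, fraction = 0), b1)

  # fluence mode: the high layer carries 50% of the summed weights
  b2 <- cached("b2", beam_b2())
  w <- vapply(b2$layers, `[[`, numeric(1), "weight")
  expect_equal(w[7] / sum(w), 0.5, tolerance = 1e-9)
  expect_equal(mean(depth_dose(b2, z)), d1, tolerance = 1e-3)
  # base layer weight ratios are preserved
  w1 <- vapply(b1$layers, `[[`, numeric(1), "weight")
  expect_equal(w[1:6] / w[1], w1 / w1[1], tolerance = 1e-9)

  # dose mode: the high layer contributes half the plateau dose
  b3 <- cached("b3", beam_b3())
  high <- beam_config(list(b3$layers[[7]]))
  share <- mean(depth_dose(high, z)) / mean(depth_dose(b3, z))
  expect_equal(share, 0.5, tolerance = 0.01)
  expect_equal(mean(depth_dose(b3, z)), d1, tolerance = 1e-3)

  # dose mode with no plateau overlap is infeasible
  short <- beam_layer(30)  # range well short of the plateau
  expect_error(add_low_let_beam(b1, high = short, mode = "dose",
                                fraction = 1), "infeasible")
})

test_that("adding low-LET fluence depresses Lt far more than Ld", {
  b1 <- cached("b1", beam_b1())
  b2 <- cached("b2", beam_b2())
  b3 <- cached("b3", beam_b3())
  z <- 33.4
  s1 <- beam_let_spectrum(b1, z)
  s2 <- beam_let_spectrum(b2, z)
  s3 <- beam_let_spectrum(b3, z)
  expect_true(lt_of(s3) < lt_of(s2) && lt_of(s2) < lt_of(s1))
  expect_true(ld_of(s3) < ld_of(s2) && ld_of(s2) < ld_of(s1))
  # relative depression of Lt exceeds that of Ld
  expect_lt(lt_of(s3) / lt_of(s1), ld_of(s3) / ld_of(s1))
})

test_that("the reference field has the published primary-proton LET at 2 cm", {
  sp <- beam_let_spectrum(beam_reference(), 20, dose_Gy = 1)
  expect_equal(round(ld_of(sp), 1), 0.5)
  expect_equal(total_dose(sp), 1)
})
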