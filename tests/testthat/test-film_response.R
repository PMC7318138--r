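test_that("bimolecular net-OD matches its defining values", {
  ref <- ref_params()
  expect_equal(net_od(0, ref), 0)
  expect_equal(net_od(ref$d_half, ref), ref$o_m / 2, tolerance = 1e-12)
  # direct evaluation with the published reference calibration at 1 Gy
  expect_equal(net_od(1, ref), 0.1318, tolerance = 0.0005 / 0.1318)
  # strictly increasing and bounded by the saturation value
  d <- seq(0, 50, by = 0.5)
  o <- net_od(d, ref)
  expect_true(all(diff(o) > 0))
  expect_true(all(o < ref$o_m))
  expect_error(net_od(-1, ref), "non-negative")
})

test_that("dose decoding is the exact algebraic inverse", {
  ref <- ref_params()
  expect_equal(dose_from_net_od(0, ref), 0)
  expect_equal(dose_from_net_od(ref$o_m / 2, ref), ref$d_half,
               tolerance = 1e-12)
  for (d in c(0.5, 1, 2, 10)) {
    expect_equal(dose_from_net_od(net_od(d, ref), ref), d,
                 tolerance = 1e-9)
  }
  # divergence toward saturation, and the saturation guard
  expect_gt(dose_from_net_od(ref$o_m - 1e-9, ref), 1e6)
  expect_error(dose_from_net_od(ref$o_m, ref), "saturation")
  expect_error(dose_from_net_od(-0.01, ref), "non-negative")
})

test_that("the LET-dependent half-saturation dose has the published limits and values", {
  qp <- qp_published()
  expect_equal(d_half_of_sw(0, qp), 9.0)
  expect_equal(d_half_of_sw(1e6, qp), 24.7, tolerance = 1e-9)
  # direct-evaluation oracle at Sw = 5 keV/um
  expect_equal(d_half_of_sw(5, qp), 9.44, tolerance = 0.01 / 9.44)
  # monotone non-decreasing over a grid
  sw <- seq(0, 60, by = 0.25)
  expect_true(all(diff(d_half_of_sw(sw, qp)) >= 0))
  expect_error(d_half_of_sw(-1, qp), "non-negative")
})

test_that("the spectrum integrator reproduces the closed form for single-quality spectra", {
  qp <- qp_published()
  for (sw in c(0.5, 5, 20)) {
    for (dose in c(0.5, 1, 2)) {
      sp <- single_bin_spectrum(sw, dose)
      dh <- d_half_of_sw(bin_centers(sp), qp)
      expect_equal(integrate_net_od(sp, qp),
                   oracle_net_od(dose, qp$o_m, dh, qp$a),
                   tolerance = 1e-4 / 0.1)
    }
  }
  # zero dose integrates to zero
  empty <- let_spectrum(c(0.95, 1.00), 0)
  expect_equal(integrate_net_od(empty, qp), 0)
  expect_error(
    integrate_net_od(single_bin_spectrum(5, 50), qp,
                     integrator_settings(max_dose = 20)), "max_dose")
})

test_that("a two-quality mixture lies strictly between its single-quality endpoints", {
  qp <- qp_published()
  mix <- two_bin_spectrum(1, 20, 0.5, 0.5)
  o_mix <- integrate_net_od(mix, qp)
  o_lo <- integrate_net_od(single_bin_spectrum(1, 1), qp)
  o_hi <- integrate_net_od(single_bin_spectrum(20, 1), qp)
  expect_gt(o_mix, o_hi)
  expect_lt(o_mix, o_lo)
  # and matches the harmonic-mean closed form
  expect_equal(o_mix, oracle_mixture_od(mix, qp), tolerance = 1e-4)
})

test_that("halving the dose step changes the integral by less than 1e-5 net-OD", {
  qp <- qp_published()
  sp <- two_bin_spectrum(2, 15, 1.2, 0.8)  # 2 Gy total
  o1 <- integrate_net_od(sp, qp, integrator_settings(delta_d = 5e-5))
  o2 <- integrate_net_od(sp, qp, integrator_settings(delta_d = 2.5e-5))
  expect_lt(abs(o1 - o2), 1e-5)
})

test_that("moving dose to higher LET never increases the net optical density", {
  qp <- qp_published()
  for (pair in list(c(1, 8), c(2, 15), c(0.5, 25))) {
    o_prev <- Inf
    for (f in seq(0, 1, by = 0.2)) {
      sp <- if (f == 0) single_bin_spectrum(pair[1], 1)
      else if (f == 1) single_bin_spectrum(pair[2], 1)
      else two_bin_spectrum(pair[1], pair[2], 1 - f, f)
      o <- integrate_net_od(sp, qp)
      expect_lte(o, o_prev + 1e-12)
      o_prev <- o
    }
  }
})

test_that("relative effectiveness is 1 at the reference quality and below 1 under quenching", {
  ref <- ref_params()
  # self-consistency: OD generated by the reference calibration itself
  o <- net_od(1.3, ref)
  pt <- relative_effectiveness(o, 1.3, ref)
  expect_equal(pt$re, 1, tolerance = 1e-6)
  # quenching sign for a pure high-LET spectrum
  qp <- qp_published()
  o_hi <- integrate_net_od(single_bin_spectrum(10, 1), qp)
  pt_hi <- relative_effectiveness(o_hi, 1, ref)
  expect_lt(pt_hi$re, 1)
  # reciprocal invariant
  for (p in list(pt, pt_hi)) expect_equal(p$re * p$g, 1, tolerance = 1e-12)
  # dose validity window
  expect_warning(relative_effectiveness(o, 0.3, ref), "window")
  expect_warning(relative_effectiveness(o, 3, ref), "window")
})

test_that("RE decreases as the high-LET dose fraction grows", {
  ref <- ref_params()
  qp <- qp_published()
  res <- sapply(seq(0, 1, by = 0.25), function(f) {
    sp <- if (f == 0) single_bin_spectrum(1, 1)
    else if (f == 1) single_bin_spectrum(18, 1)
    else two_bin_spectrum(1, 18, 1 - f, f)
    relative_effectiveness(integrate_net_od(sp, qp), 1, ref)$re
  })
  expect_true(all(diff(res) < 0))
})

test_that("calibration fitting recovers the generating parameters", {
  ref <- ref_params()
  doses <- seq(0, 10, length.out = 11)
  cal <- fit_calibration(doses, net_od(doses, ref))
  expect_equal(cal$o_m, ref$o_m, tolerance = 1e-6)
  expect_equal(cal$d_half, ref$d_half, tolerance = 1e-6)
  expect_equal(cal$a, ref$a, tolerance = 1e-6)
})
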