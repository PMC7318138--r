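test_that("the k-relation round trip is the identity", {
  a <- 0.82
  for (dh in c(5, 8.99, 24.7)) {
    expect_equal(d_half_of_k(k_of_d_half(dh, a), a), dh, tolerance = 1e-12)
  }
})

test_that("initial guess recovers exact quench parameters from a noiseless g curve", {
  truth <- qp_published()
  sw <- seq(0.4, 30, length.out = 12)
  ref <- calibration_params(0.93, d_half_of_sw(min(sw), truth), 0.82)
  g <- k_of_d_half(d_half_of_sw(sw, truth), 0.82)  # k proportional to g
  ig <- initial_guess(sw, g, ref)
  expect_equal(ig$c1, truth$c1, tolerance = 1e-6)
  expect_equal(ig$c2, truth$c2, tolerance = 1e-6)
  expect_equal(ig$c3, truth$c3, tolerance = 1e-6)
})

test_that("initial guess rejects degenerate curves", {
  ref <- ref_params()
  expect_error(initial_guess(c(1, 10), c(1, 0.9), ref), "3 distinct")
  expect_error(initial_guess(rep(5, 4), c(1, 0.95, 0.9, 0.85), ref),
               "3 distinct")
})

test_that("initial guess stays within 10% of truth under 1% multiplicative noise", {
  truth <- qp_published()
  sw <- seq(0.4, 30, length.out = 20)
  ref <- calibration_params(0.93, d_half_of_sw(min(sw), truth), 0.82)
  set.seed(1)
  g <- k_of_d_half(d_half_of_sw(sw, truth), 0.82) * (1 + rnorm(20, 0, 0.01))
  ig <- initial_guess(sw, g, ref)
  expect_equal(ig$c1, truth$c1, tolerance = 0.10)
  expect_equal(ig$c2, truth$c2, tolerance = 0.10)
  expect_equal(ig$c3, truth$c3, tolerance = 0.10)
})

test_that("inverse optimisation recovers the generating parameters from noiseless data", {
  ref <- ref_params()
  truth <- qp_selfconsistent()
  training <- cached("training_noiseless", make_training(truth, ref))
  init <- quench_params(truth$o_m * 1.1, 0.82, truth$c1 * 0.9,
                        truth$c2 * 1.15, truth$c3 * 0.9)
  fit <- cached("fit_noiseless", fit_quench(training, ref, init))
  expect_true(fit$converged)
  expect_lt(fit$chi2, 1e-8)
  cf <- coef(fit)
  expect_equal(cf[["o_m"]], truth$o_m, tolerance = 0.01)
  expect_equal(cf[["c1"]], truth$c1, tolerance = 0.01)
  expect_equal(cf[["c2"]], truth$c2, tolerance = 0.01)
  expect_equal(cf[["c3"]], truth$c3, tolerance = 0.01)
})

test_that("starting at the optimum leaves the objective unchanged and converged", {
  ref <- ref_params()
  truth <- qp_selfconsistent()
  training <- cached("training_noiseless", make_training(truth, ref))
  fit <- fit_quench(training, ref, truth)
  expect_true(fit$converged)
  expect_lte(fit$chi2, fit$chi2_init + 1e-15)
  expect_lt(abs(fit$chi2 - fit$chi2_init), 1e-12)
  expect_equal(coef(fit)[["c1"]], truth$c1, tolerance = 1e-6)
})

test_that("the objective never ends above its value at the start", {
  ref <- ref_params()
  truth <- qp_selfconsistent()
  training <- cached("training_noiseless", make_training(truth, ref))
  set.seed(7)
  noisy <- lapply(training, function(tp) {
    tp$g_measured <- tp$g_measured * (1 + rnorm(1, 0, 0.01))
    tp
  })
  init <- quench_params(0.8, 0.82, 10, 20, 10)
  fit <- fit_quench(noisy, ref, init)
  expect_lte(fit$chi2, fit$chi2_init)
  # the logged best-so-far trace is non-increasing
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("refits from perturbed starts agree on the half-saturation curve", {
  ref <- ref_params()
  truth <- qp_selfconsistent()
  training <- cached("training_noiseless", make_training(truth, ref))
  sw_grid <- seq(1, 15, by = 0.5)
  base <- d_half_of_sw(sw_grid, truth)
  set.seed(11)
  for (k in 1:10) {
    f <- 1 + runif(4, -0.2, 0.2)
    init <- quench_params(truth$o_m * f[1], 0.82, truth$c1 * f[2],
                          truth$c2 * f[3], truth$c3 * f[4])
    fit <- fit_quench(training, ref, init)
    curve <- d_half_of_sw(sw_grid, fit$params)
    expect_lt(max(abs(curve / base - 1)), 0.02)
  }
})

test_that("the fit rejects under-determined or inconsistent training input", {
  ref <- ref_params()
  truth <- qp_selfconsistent()
  training <- make_training(truth, ref)
  expect_error(fit_quench(training[1:3], ref, truth), ">= 4 training points")
  expect_error(fit_quench(list(1, 2, 3, 4), ref, truth), "training_point")
  expect_warning(training_point(single_bin_spectrum(5, 1), 1.05, 3),
                 "2.5 Gy")
})

test_that("quench_fit methods are coherent", {
  ref <- ref_params()
  truth <- qp_selfconsistent()
  training <- cached("training_noiseless", make_training(truth, ref))
  fit <- cached("fit_noiseless",
                fit_quench(training, ref,
                           quench_params(truth$o_m * 1.1, 0.82,
                                         truth$c1 * 0.9, truth$c2 * 1.15,
                                         truth$c3 * 0.9)))
  expect_named(coef(fit), c("o_m", "a", "c1", "c2", "c3"))
  expect_length(fitted(fit), fit$n_points)
  expect_equal(unname(predict(fit, 0)), fit$params$c1)
  expect_lt(max(abs(residuals(fit))), 1e-4)
  s <- summary(fit)
  expect_s3_class(s, "summary.quench_fit")
  sim <- simulate(fit, nsim = 3, seed = 5)
  expect_equal(dim(sim), c(fit$n_points, 3L))
  expect_output(print(fit), "quench model")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
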