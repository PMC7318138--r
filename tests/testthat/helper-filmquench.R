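# Shared fixtures: published parameter sets, small spectra and the
# closed-form oracle for the spectrum integrator.

# reference calibration at Q0 (179.7 MeV, 2 cm depth)
ref_params <- function() calibration_params(0.93, 8.99, 0.82)

# published inverse-optimised quench parameters of the film batch
qp_published <- function() quench_params(0.96, 0.82, 9.0, 15.7, 14.8)

# self-consistent set: the quench model reduces to the Q0 calibration at
# Sw -> 0 (c1 = d_half, o_m matching), used wherever RE(reference) = 1 is
# the property under test and as generator ground truth
qp_selfconsistent <- function() quench_params(0.93, 0.82, 8.99, 15.7, 14.8)

# closed-form bimolecular net-OD (independent of the package's net_od)
oracle_net_od <- function(dose, o_m, d_half, a) {
  o_m * dose^a / (d_half^a + dose^a)
}

# independent oracle for the mixed-spectrum integral: simultaneous
# deposition makes the mixture an exact bimolecular curve at the
# dose-weighted harmonic mean of the per-bin half-saturation doses
oracle_mixture_od <- function(spectrum, qp) {
  w <- spectrum$dose_per_bin / sum(spectrum$dose_per_bin)
  s <- bin_centers(spectrum)
  dh <- qp$c1 + qp$c2 * (1 - exp(-s^2 / (2 * qp$c3)^2))
  d_eff <- 1 / sum(w / dh)
  oracle_net_od(sum(spectrum$dose_per_bin), qp$o_m, d_eff, qp$a)
}

# spectrum with dose split between two Sw values on the 0.05 grid
two_bin_spectrum <- function(sw1, sw2, d1, d2, bin_width = 0.05) {
  i1 <- floor(sw1 / bin_width); i2 <- floor(sw2 / bin_width)
  stopifnot(i1 < i2)
  edges <- (i1:(i2 + 1)) * bin_width
  dose <- numeric(i2 - i1 + 1)
  dose[1] <- d1; dose[length(dose)] <- d2
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  flu <- ifelse(dose > 0, dose / mid, 0)
  let_spectrum(edges, dose, fluence_per_bin = flu)
}

# forward-simulated correction factor for a spectrum at a dose
g_forward <- function(spectrum, dose, qp, ref,
                      isett = integrator_settings()) {
  o <- integrate_net_od(rescale_dose(spectrum, dose), qp, isett)
  1 / relative_effectiveness(o, dose, ref, warn_window = FALSE)$re
}

# small synthetic training set spanning low and high Sw, noiseless
make_training <- function(qp, ref, isett = integrator_settings()) {
  specs <- list(single_bin_spectrum(0.5, 1), single_bin_spectrum(2, 1),
                single_bin_spectrum(5, 1), single_bin_spectrum(9, 1),
                single_bin_spectrum(14, 1), single_bin_spectrum(20, 1),
                single_bin_spectrum(0.5, 1), single_bin_spectrum(0.5, 1))
  doses <- c(1, 1, 1, 1, 1, 1, 0.5, 2.5)
  Map(function(sp, d) training_point(sp, g_forward(sp, d, qp, ref, isett), d),
      specs, doses)
}

# memoised heavy objects shared across test files
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}
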