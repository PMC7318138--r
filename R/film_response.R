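# Film dose-response core: bimolecular calibration, LET-dependent
# half-saturation dose, spectrum-resolved net-OD integration and the
# relative effectiveness / beam-quality correction factor.

#' Calibration parameters of the bimolecular film response
#'
#' The bimolecular model relates net optical density o to dose D as
#' o = om * D^a / (D12^a + D^a), with saturation net-OD `o_m`,
#' half-saturation dose `d_half` (Gy) and exponent `a`. The reference EBT3
#' batch calibrated at 2 cm depth in a 179.7 MeV beam has
#' {om, D12, a} = {0.93, 8.99, 0.82}.
#'
#' @param o_m Saturation net optical density, in (0, 3).
#' @param d_half Half-saturation dose in Gy, > 0.
#' @param a Dimensionless exponent, in (0, 2).
#' @return An object of class `calibration_params`.
#' @export
#' @examples
#' ref <- calibration_params(0.93, 8.99, 0.82)
calibration_params <- function(o_m, d_half, a) {
  stopifnot(is.numeric(o_m), length(o_m) == 1, o_m > 0, o_m < 3,
            is.numeric(d_half), length(d_half) == 1, d_half > 0,
            is.numeric(a), length(a) == 1, a > 0, a < 2)
  structure(list(o_m = o_m, d_half = d_half, a = a),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat("Bimolecular film calibration\n")
  cat(sprintf("  o_m    = %.4g (net-OD saturation)\n", x$o_m))
  cat(sprintf("  d_half = %.4g Gy\n", x$d_half))
  cat(sprintf("  a      = %.4g\n", x$a))
  invisible(x)
}

#' Quench parameters: LET dependence of the half-saturation dose
#'
#' Describes film quenching through D12(Sw) = c1 + c2 * (1 - exp(-Sw^2 /
#' (2 c3)^2)): the half-saturation dose rises from `c1` at Sw = 0 towards
#' `c1 + c2` at high LET, with `c3` (keV/um) setting where the rise occurs.
#' The inverse-optimised values for the reference EBT3 batch are
#' om = 0.96, a = 0.82, c1 = 9.0 Gy, c2 = 15.7 Gy, c3 = 14.8 keV/um.
#'
#' @param o_m Saturation net-OD used inside the spectrum integrator, (0, 3).
#' @param a Dimensionless exponent, in (0, 2).
#' @param c1 Low-LET half-saturation dose, Gy, > 0.
#' @param c2 Asymptotic rise of the half-saturation dose, Gy, >= 0.
#' @param c3 LET scale of the rise, keV/um, > 0.
#' @return An object of class `quench_params`.
#' @export
#' @examples
#' qp <- quench_params(0.96, 0.82, 9.0, 15.7, 14.8)
#' d_half_of_sw(c(0, 5, 30), qp)
quench_params <- function(o_m, a, c1, c2, c3) {
  stopifnot(is.numeric(o_m), length(o_m) == 1, o_m > 0, o_m < 3,
            is.numeric(a), length(a) == 1, a > 0, a < 2,
            is.numeric(c1), length(c1) == 1, c1 > 0,
            is.numeric(c2), length(c2) == 1, c2 >= 0,
            is.numeric(c3), length(c3) == 1, c3 > 0)
  structure(list(o_m = o_m, a = a, c1 = c1, c2 = c2, c3 = c3),
            class = "quench_params")
}

#' @export
print.quench_params <- function(x, ...) {
  cat("LET-dependent quench parameters (D1/2 of Sw)\n")
  cat(sprintf("  o_m = %.4g, a = %.4g\n", x$o_m, x$a))
  cat(sprintf("  c1 = %.4g Gy, c2 = %.4g Gy, c3 = %.4g keV/um\n",
              x$c1, x$c2, x$c3))
  cat(sprintf("  D1/2: %.3g Gy at Sw=0 -> %.3g Gy at high LET\n",
              x$c1, x$c1 + x$c2))
  invisible(x)
}

#' Net optical density of the bimolecular model
#'
#' @param dose Absorbed dose to water in Gy (vectorised, >= 0).
#' @param params A [calibration_params()] object.
#' @return Net optical density in `[0, o_m)`.
#' @export
#' @examples
#' net_od(1, calibration_params(0.93, 8.99, 0.82)) # 0.1318
net_od <- function(dose, params) {
  stopifnot(inherits(params, "calibration_params") ||
              inherits(params, "quench_params"))
  if (!is.numeric(dose) || any(!is.finite(dose)) || any(dose < 0))
    stop("'dose' must be finite and non-negative")
  dh <- if (inherits(params, "calibration_params")) params$d_half else params$c1
  da <- dose^params$a
  params$o_m * da / (dh^params$a + da)
}

#' Dose from net optical density (inverse calibration)
#'
#' Exact algebraic inverse of [net_od()]:
#' D = d_half * (o / (o_m - o))^(1/a).
#'
#' @param o Net optical density (vectorised), `0 <= o < o_m`.
#' @param params A [calibration_params()] object.
#' @return Dose in Gy.
#' @export
dose_from_net_od <- function(o, params) {
  stopifnot(inherits(params, "calibration_params"))
  if (!is.numeric(o) || any(!is.finite(o)) || any(o < 0))
    stop("net optical density must be finite and non-negative")
  if (any(o >= params$o_m))
    stop(sprintf("net optical density >= saturation o_m = %g", params$o_m))
  params$d_half * (o / (params$o_m - o))^(1 / params$a)
}

#' LET-dependent half-saturation dose
#'
#' D12(Sw) = c1 + c2 * (1 - exp(-Sw^2 / (2 c3)^2)). Monotonically
#' non-decreasing in Sw, with limits c1 at Sw = 0 and c1 + c2 at infinity.
#'
#' @param sw_keV_um Stopping power in water, keV/um (vectorised, >= 0).
#' @param qp A [quench_params()] object.
#' @return Half-saturation dose in Gy.
#' @export
d_half_of_sw <- function(sw_keV_um, qp) {
  stopifnot(inherits(qp, "quench_params"))
  if (!is.numeric(sw_keV_um) || any(!is.finite(sw_keV_um)) ||
        any(sw_keV_um < 0))
    stop("'sw_keV_um' must be finite and non-negative")
  qp$c1 + qp$c2 * (1 - exp(-sw_keV_um^2 / (2 * qp$c3)^2))
}

#' LET spectrum at one position
#'
#' A histogram of dose (and optionally fluence) per unrestricted-LET bin on
#' an equidistant Sw grid; the beam-quality object of the formalism. The
#' canonical bin width is 0.05 keV/um.
#'
#' @param bin_edges Strictly increasing, equidistant bin edges in keV/um
#'   (length nbins + 1).
#' @param dose_per_bin Dose per bin in Gy, >= 0.
#' @param fluence_per_bin Optional fluence per bin (1/cm^2), >= 0.
#' @param label Beam-quality identifier (e.g. "Q0", "b1 z=33.4mm").
#' @param depth_mm Optional water-equivalent depth, carried as metadata.
#' @return An object of class `let_spectrum`.
#' @export
#' @examples
#' s <- let_spectrum(c(0.45, 0.50, 0.55), c(0.3, 0.7), label = "demo")
#' total_dose(s)
let_spectrum <- function(bin_edges, dose_per_bin, fluence_per_bin = NULL,
                         label = "", depth_mm = NA_real_) {
  stopifnot(is.numeric(bin_edges), length(bin_edges) >= 2,
            all(diff(bin_edges) > 0))
  w <- diff(bin_edges)
  if (max(abs(w - w[1])) > 1e-9 * w[1])
    stop("bin width must be constant")
  if (length(dose_per_bin) != length(bin_edges) - 1)
    stop("dose_per_bin must have length(bin_edges) - 1 entries")
  if (any(!is.finite(dose_per_bin)) || any(dose_per_bin < 0))
    stop("dose_per_bin must be finite and non-negative")
  if (!is.null(fluence_per_bin)) {
    stopifnot(length(fluence_per_bin) == length(dose_per_bin),
              all(is.finite(fluence_per_bin)), all(fluence_per_bin >= 0))
  }
  structure(list(bin_edges = bin_edges, dose_per_bin = dose_per_bin,
                 fluence_per_bin = fluence_per_bin, label = label,
                 depth_mm = depth_mm, bin_width = w[1]),
            class = "let_spectrum")
}

#' @export
print.let_spectrum <- function(x, ...) {
  occ <- sum(x$dose_per_bin > 0)
  cat(sprintf("LET spectrum '%s': %d bins of %.3g keV/um on [%.3g, %.3g]\n",
              x$label, length(x$dose_per_bin), x$bin_width,
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)]))
  cat(sprintf("  occupied bins: %d, total dose %.4g Gy", occ, total_dose(x)))
  if (sum(x$dose_per_bin) > 0)
    cat(sprintf(", Ld %.3g / Lt %.3g keV/um", ld_of(x), lt_of(x)))
  cat("\n")
  invisible(x)
}

#' Bin centres of a LET spectrum
#' @param spectrum A [let_spectrum()] object.
#' @return Bin-centre Sw values, keV/um.
#' @export
bin_centers <- function(spectrum) {
  stopifnot(inherits(spectrum, "let_spectrum"))
  e <- spectrum$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Total dose of a LET spectrum
#' @param spectrum A [let_spectrum()] object.
#' @return Total dose in Gy.
#' @export
total_dose <- function(spectrum) {
  stopifnot(inherits(spectrum, "let_spectrum"))
  sum(spectrum$dose_per_bin)
}

#' Rescale a LET spectrum to a prescribed total dose
#'
#' Scales dose (and fluence, if present) so that the spectral shape is
#' preserved and the total dose equals `dose_Gy`.
#'
#' @param spectrum A [let_spectrum()] object with positive total dose.
#' @param dose_Gy Target total dose, Gy.
#' @return A rescaled `let_spectrum`.
#' @export
rescale_dose <- function(spectrum, dose_Gy) {
  stopifnot(inherits(spectrum, "let_spectrum"), dose_Gy >= 0)
  tot <- total_dose(spectrum)
  if (tot <= 0) stop("cannot rescale a spectrum with zero total dose")
  f <- dose_Gy / tot
  spectrum$dose_per_bin <- spectrum$dose_per_bin * f
  if (!is.null(spectrum$fluence_per_bin))
    spectrum$fluence_per_bin <- spectrum$fluence_per_bin * f
  spectrum
}

#' Single-bin LET spectrum
#'
#' Convenience constructor: all dose in the 0.05 keV/um grid bin containing
#' `sw`; fluence is dose/Sw at the bin centre.
#'
#' @param sw Stopping power in keV/um.
#' @param dose Total dose in Gy.
#' @param bin_width Grid bin width, keV/um.
#' @param label Identifier.
#' @return A `let_spectrum` with one occupied bin.
#' @export
single_bin_spectrum <- function(sw, dose, bin_width = 0.05, label = "") {
  stopifnot(sw > 0, dose >= 0)
  i <- floor(sw / bin_width)
  edges <- c(i, i + 1) * bin_width
  ctr <- (edges[1] + edges[2]) / 2
  let_spectrum(edges, dose, fluence_per_bin = dose / ctr, label = label)
}

#' Integrator settings for the discrete net-OD update rule
#'
#' @param delta_d Global dose step in Gy; 5e-5 Gy is sufficiently small for
#'   convergence below 1e-5 net-OD. Must be in (0, 1e-3].
#' @param max_dose Largest total dose the integrator accepts, Gy.
#' @return An object of class `integrator_settings`.
#' @export
integrator_settings <- function(delta_d = 5e-5, max_dose = 20) {
  stopifnot(is.numeric(delta_d), length(delta_d) == 1,
            delta_d > 0, delta_d <= 1e-3,
            is.numeric(max_dose), length(max_dose) == 1, max_dose > 0)
  structure(list(delta_d = delta_d, max_dose = max_dose),
            class = "integrator_settings")
}

#' Spectrum-resolved net optical density
#'
#' Integrates the discrete net-OD update rule over a LET spectrum: at each
#' global dose step dD the increment is the dose-fraction-weighted sum of
#' per-bin increments, each evaluated with its own LET-dependent D1/2 at the
#' shared current net-OD (simultaneous-irradiation convention — all spectral
#' components expose the film at once). Because the per-bin increment
#' factorises as g(o)/D12_j, the weighted sum reduces to g(o) times the
#' dose-weighted harmonic term, which the compiled loop hoists out of the
#' iteration; the first step is seeded with the closed form, since the
#' update rule is singular at o = 0 for a < 1.
#'
#' @param spectrum A [let_spectrum()] object.
#' @param qp A [quench_params()] object.
#' @param settings An [integrator_settings()] object.
#' @return Net optical density in `[0, o_m)`; 0 for an empty spectrum.
#' @export
#' @examples
#' qp <- quench_params(0.96, 0.82, 9.0, 15.7, 14.8)
#' s <- single_bin_spectrum(10, 1)
#' integrate_net_od(s, qp)
integrate_net_od <- function(spectrum, qp, settings = integrator_settings()) {
  stopifnot(inherits(spectrum, "let_spectrum"),
            inherits(qp, "quench_params"),
            inherits(settings, "integrator_settings"))
  tot <- total_dose(spectrum)
  if (tot == 0) return(0)
  if (tot > settings$max_dose)
    stop(sprintf("total dose %.3g Gy exceeds max_dose = %g Gy",
                 tot, settings$max_dose))
  keep <- spectrum$dose_per_bin > 0
  w <- spectrum$dose_per_bin[keep] / tot
  dh <- d_half_of_sw(bin_centers(spectrum)[keep], qp)
  o <- cpp_integrate_net_od(w, dh, qp$o_m, qp$a, tot, settings$delta_d)
  if (o >= qp$o_m)
    stop("net optical density reached saturation o_m during integration")
  o
}

#' Relative effectiveness and beam-quality correction factor
#'
#' Iso-dose relative effectiveness: the apparent dose decoded from a net
#' optical density with the reference calibration, divided by the true dose.
#' Its reciprocal g is the beam-quality correction factor applied to
#' apparent film doses.
#'
#' @param o Net optical density, measured or calculated, `0 <= o < o_m(ref)`.
#' @param true_dose True absorbed dose to water, Gy, > 0. The quench model
#'   is characterised for doses in the 0.5--2.5 Gy window; outside it a
#'   warning is emitted (set `warn_window = FALSE` to silence).
#' @param ref The reference-quality [calibration_params()].
#' @param ld Optional dose-averaged LET of the spectrum, carried along.
#' @param warn_window Warn when `true_dose` is outside 0.5--2.5 Gy.
#' @return An object of class `re_point`: list with `re`, `g` (= 1/re),
#'   `dose` and `ld`.
#' @export
relative_effectiveness <- function(o, true_dose, ref, ld = NA_real_,
                                   warn_window = TRUE) {
  stopifnot(inherits(ref, "calibration_params"),
            is.numeric(true_dose), length(true_dose) == 1, true_dose > 0)
  if (warn_window && (true_dose < 0.5 || true_dose > 2.5))
    warning(sprintf(
      "dose %.3g Gy outside the 0.5-2.5 Gy validity window of the quench model",
      true_dose))
  apparent <- dose_from_net_od(o, ref)
  re <- apparent / true_dose
  structure(list(re = re, g = 1 / re, dose = true_dose, ld = ld),
            class = "re_point")
}

#' @export
print.re_point <- function(x, ...) {
  cat(sprintf("RE = %.4f (g = %.4f) at %.3g Gy", x$re, x$g, x$dose))
  if (is.finite(x$ld)) cat(sprintf(", Ld = %.3g keV/um", x$ld))
  cat("\n")
  invisible(x)
}

#' Fit the bimolecular calibration to dose / net-OD pairs
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the bimolecular model to
#' calibration measurements, typically 11 dose levels from 0 to 10 Gy at the
#' low-LET reference quality.
#'
#' @param dose Doses in Gy.
#' @param od Measured net optical densities.
#' @param start Optional list of starting values `o_m`, `d_half`, `a`.
#' @return A [calibration_params()] object with attributes `rms` (residual
#'   RMS) and `fit` (the underlying `nls` object).
#' @export
fit_calibration <- function(dose, od, start = NULL) {
  stopifnot(length(dose) == length(od), length(dose) >= 4,
            all(dose >= 0), all(od >= 0))
  if (is.null(start))
    start <- list(o_m = max(od) * 1.5, d_half = stats::median(dose[dose > 0]),
                  a = 0.85)
  df <- data.frame(dose = dose, od = od)
  fit <- minpack.lm::nlsLM(
    od ~ o_m * dose^a / (d_half^a + dose^a), data = df, start = start,
    lower = c(o_m = 1e-3, d_half = 1e-3, a = 0.05),
    upper = c(o_m = 3, d_half = 1e3, a = 2),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  out <- calibration_params(cf[["o_m"]], cf[["d_half"]], cf[["a"]])
  attr(out, "rms") <- sqrt(mean(stats::residuals(fit)^2))
  attr(out, "fit") <- fit
  out
}
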