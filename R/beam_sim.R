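# Analytic primary-proton transport in water: depth energy spectra,
# LET spectra on the canonical 0.05 keV/um grid, dose- and fluence-averaged
# LET, SOBP composition and the b1/b2/b3-style beam arrangements.

#' A single energy layer of a scanned proton beam
#'
#' @param energy Nominal kinetic energy in MeV, in `[0.5, 300]`.
#' @param sigma_e Gaussian energy spread in MeV (1 sd). The facility value is
#'   not published; the default, 1% of the nominal energy, is the value at
#'   which the six lowest clinical layers compose their documented flat SOBP
#'   (see the methods vignette on beam-model commissioning).
#' @param weight Relative fluence weight, >= 0.
#' @return An object of class `beam_layer`.
#' @export
beam_layer <- function(energy, sigma_e = 0.01 * energy, weight = 1) {
  stopifnot(is.numeric(energy), length(energy) == 1,
            energy >= 0.5, energy <= 300,
            is.numeric(sigma_e), length(sigma_e) == 1, sigma_e >= 0,
            is.numeric(weight), length(weight) == 1, weight >= 0)
  structure(list(energy = energy, sigma_e = sigma_e, weight = weight),
            class = "beam_layer")
}

#' A beam configuration: weighted energy layers
#'
#' @param layers List of [beam_layer()]s (at least one; weights not all 0).
#' @param label Identifier, e.g. "b1".
#' @return An object of class `beam_config`.
#' @export
beam_config <- function(layers, label = "") {
  if (inherits(layers, "beam_layer")) layers <- list(layers)
  stopifnot(is.list(layers), length(layers) >= 1)
  ok <- vapply(layers, inherits, logical(1), what = "beam_layer")
  if (!all(ok)) stop("'layers' must be beam_layer objects")
  w <- vapply(layers, `[[`, numeric(1), "weight")
  if (all(w == 0)) stop("layer weights must not all be zero")
  structure(list(layers = layers, label = label), class = "beam_config")
}

#' @export
print.beam_config <- function(x, ...) {
  e <- vapply(x$layers, `[[`, numeric(1), "energy")
  w <- vapply(x$layers, `[[`, numeric(1), "weight")
  cat(sprintf("Beam '%s': %d layer(s), %.4g-%.4g MeV\n", x$label,
              length(e), min(e), max(e)))
  print(data.frame(energy_MeV = e,
                   sigma_E_MeV = vapply(x$layers, `[[`, numeric(1), "sigma_e"),
                   weight = w), row.names = FALSE)
  invisible(x)
}

#' Transport settings of the analytic beam model
#'
#' @param k_strag Range-straggling constant: sigma_R at full range equals
#'   `k_strag * R0` (Bohr-like, default 0.012); the accumulated variance
#'   grows linearly with path length.
#' @param lambda_cm Nuclear-attenuation length in cm; primary fluence decays
#'   as exp(-z/lambda).
#' @param beamline_wet_mm Water-equivalent thickness upstream of the phantom
#'   surface (vacuum window, monitors, holder), added to every depth. The
#'   2.6 mm default places the Bragg peaks of the 62.4--67.5 MeV layers
#'   across the 30--35 mm SOBP window (beam-model commissioning, see the
#'   methods vignette).
#' @param e_floor Lowest transported energy in MeV; protons slower than this
#'   carry a negligible dose share (<0.3%).
#' @return An object of class `beam_settings`.
#' @export
beam_settings <- function(k_strag = 0.012, lambda_cm = 85,
                          beamline_wet_mm = 2.6, e_floor = 0.1) {
  stopifnot(k_strag >= 0, lambda_cm > 0, beamline_wet_mm >= 0, e_floor > 0)
  structure(list(k_strag = k_strag, lambda_cm = lambda_cm,
                 beamline_wet_mm = beamline_wet_mm, e_floor = e_floor),
            class = "beam_settings")
}

#' Primary-proton energy spectrum at depth
#'
#' Residual-range transport: the mean energy at depth is the energy whose
#' CSDA range equals the initial range minus the (WET-corrected) depth. The
#' energy spread combines the initial spread, mapped through the ratio of
#' stopping powers, with Bohr-like range straggling (variance growing
#' linearly with path length). Primary fluence is attenuated by nuclear
#' interactions, and near the end of range by the fraction of the range
#' distribution already stopped. Beyond the range plus 5 sigma the spectrum
#' is empty.
#'
#' @param layer A [beam_layer()].
#' @param depth_mm Depth in mm of water from the phantom surface, >= 0.
#' @param settings A [beam_settings()] object.
#' @return An object of class `energy_spectrum`: data frame with columns
#'   `e_low`, `e_high`, `e_mid` (MeV) and `fluence` (per incident fluence),
#'   with the layer and depth as attributes. Zero rows beyond the range.
#' @export
#' @examples
#' sp <- depth_energy_spectrum(beam_layer(179.7), 20)
#' sum(sp$fluence)
depth_energy_spectrum <- function(layer, depth_mm,
                                  settings = beam_settings()) {
  stopifnot(inherits(layer, "beam_layer"), depth_mm >= 0,
            inherits(settings, "beam_settings"))
  z <- (depth_mm + settings$beamline_wet_mm) / 10  # cm
  E0 <- layer$energy
  R0 <- csda_range(E0)
  s0_MeV_cm <- stopping_power_water(E0) * 10
  sigma_r0 <- sqrt((settings$k_strag * R0)^2 + (layer$sigma_e / s0_MeV_cm)^2)

  empty <- structure(
    data.frame(e_low = numeric(0), e_high = numeric(0),
               e_mid = numeric(0), fluence = numeric(0)),
    class = c("energy_spectrum", "data.frame"),
    layer = layer, depth_mm = depth_mm, settings = settings)
  if (z >= R0 + 5 * sigma_r0) return(empty)

  sig <- max(sigma_r0, 1e-12)
  alpha <- (z - R0) / sig
  surv_frac <- 1 - stats::pnorm(alpha)
  surviving <- exp(-z / settings$lambda_cm) * surv_frac
  if (surviving <= 0) return(empty)

  # survivors carry ranges R > z: residual range is the truncated-normal
  # mean, which decays smoothly through the distal falloff instead of
  # pinning stopped protons at the energy floor
  h <- exp(stats::dnorm(alpha, log = TRUE) -
             stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
  r_floor <- csda_range(settings$e_floor)
  r <- max(R0 - z + sig * h, r_floor)
  e_mean <- energy_at_range(r)
  s_z <- stopping_power_water(e_mean) * 10
  # local range spread: truncated-normal sd, capped by the straggling
  # accumulated over the path travelled (variance linear in path length)
  sd_trunc <- sig * sqrt(max(1 + alpha * h - h^2, 0))
  sd_accum <- sqrt((settings$k_strag * R0)^2 * min(z / R0, 1) +
                     (layer$sigma_e / s0_MeV_cm)^2)
  sigma_e <- min(sd_trunc, sd_accum) * s_z

  if (sigma_e < 1e-9) {
    out <- data.frame(e_low = e_mean, e_high = e_mean, e_mid = e_mean,
                      fluence = surviving)
    return(structure(out, class = c("energy_spectrum", "data.frame"),
                     layer = layer, depth_mm = depth_mm, settings = settings))
  }

  lo <- max(settings$e_floor, e_mean - 6 * sigma_e)
  hi <- min(299.9, e_mean + 6 * sigma_e)
  if (hi <= lo) return(empty)
  # union grid: Gaussian resolution plus the preimage of a fine Sw grid so
  # the mapped bins stay finer than 0.05 keV/um below ~30 keV/um
  e1 <- seq(lo, hi, length.out = 241L)
  s_hi <- stopping_power_water(hi)
  s_lo <- stopping_power_water(lo)
  sw_seq <- c(seq(s_hi, min(s_lo, 32), by = 0.0125),
              if (s_lo > 32.25) seq(32.25, s_lo, by = 0.25))
  e2 <- if (length(sw_seq) > 1) energy_from_sw(sw_seq) else numeric(0)
  edges <- sort(unique(c(lo, hi, e1, e2)))
  edges <- edges[edges >= lo & edges <= hi]
  p <- stats::pnorm(edges, mean = e_mean, sd = sigma_e)
  f <- diff(p)
  f <- f / sum(f) * surviving  # renormalise the truncated Gaussian
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  out <- data.frame(e_low = edges[-length(edges)], e_high = edges[-1],
                    e_mid = mid, fluence = f)
  out <- out[out$fluence > 0, , drop = FALSE]
  structure(out, class = c("energy_spectrum", "data.frame"),
            layer = layer, depth_mm = depth_mm, settings = settings)
}

#' Map an energy spectrum onto the equidistant LET grid
#'
#' Each energy bin is carried through the water stopping power at its
#' mid-energy and accumulated into the equidistant Sw histogram (canonical
#' width 0.05 keV/um). Dose per energy bin is fluence times Sw, so both
#' total fluence and total fluence-weighted Sw are conserved exactly.
#'
#' @param espec An `energy_spectrum` (or any data frame with `e_mid` and
#'   `fluence`), or a list of them to be superposed.
#' @param sw_bin Bin width in keV/um.
#' @param label Label of the resulting spectrum.
#' @param depth_mm Depth metadata.
#' @return A [let_spectrum()] with both dose and fluence per bin. Dose is
#'   in fluence-weighted keV/um units until rescaled (see [rescale_dose()]).
#' @export
spectrum_to_let <- function(espec, sw_bin = 0.05, label = "",
                            depth_mm = NA_real_) {
  if (is.data.frame(espec)) espec <- list(espec)
  e_mid <- unlist(lapply(espec, `[[`, "e_mid"))
  fl <- unlist(lapply(espec, `[[`, "fluence"))
  if (length(e_mid) == 0 || sum(fl) == 0)
    stop("empty energy spectrum: nothing to map onto the LET grid")
  sw <- stopping_power_water(e_mid)
  idx <- floor(sw / sw_bin)
  rng <- range(idx)
  nb <- rng[2] - rng[1] + 1L
  pos <- idx - rng[1] + 1L
  dose <- vapply(seq_len(nb), function(i) sum(fl[pos == i] * sw[pos == i]),
                 numeric(1))
  flu <- vapply(seq_len(nb), function(i) sum(fl[pos == i]), numeric(1))
  edges <- (rng[1]:(rng[2] + 1L)) * sw_bin
  let_spectrum(edges, dose, fluence_per_bin = flu, label = label,
               depth_mm = depth_mm)
}

.fluence_of <- function(spectrum) {
  if (!is.null(spectrum$fluence_per_bin)) return(spectrum$fluence_per_bin)
  s <- bin_centers(spectrum)
  ifelse(spectrum$dose_per_bin > 0, spectrum$dose_per_bin / s, 0)
}

#' Dose- and fluence-averaged LET of a spectrum
#'
#' `lt_of` is the fluence (track) average sum(Phi*S)/sum(Phi); `ld_of` is
#' the dose average sum(Phi*S^2)/sum(Phi*S), both over bin-centre Sw.
#' By the Cauchy-Schwarz inequality Ld >= Lt, with equality only for a
#' single occupied bin.
#'
#' @param spectrum A [let_spectrum()] with nonzero content.
#' @return LET in keV/um.
#' @export
#' @examples
#' edges <- seq(0.975, 3.025, by = 0.05)
#' mid <- (edges[-1] + edges[-length(edges)]) / 2
#' phi <- numeric(length(mid)); phi[c(1, length(phi))] <- 1
#' s <- let_spectrum(edges, phi * mid, fluence_per_bin = phi)
#' c(lt_of(s), ld_of(s)) # 2.0 and 2.5
ld_of <- function(spectrum) {
  stopifnot(inherits(spectrum, "let_spectrum"))
  phi <- .fluence_of(spectrum)
  s <- bin_centers(spectrum)
  if (sum(phi) <= 0) stop("all-zero spectrum: LET average undefined")
  sum(phi * s^2) / sum(phi * s)
}

#' @rdname ld_of
#' @export
lt_of <- function(spectrum) {
  stopifnot(inherits(spectrum, "let_spectrum"))
  phi <- .fluence_of(spectrum)
  s <- bin_centers(spectrum)
  if (sum(phi) <= 0) stop("all-zero spectrum: LET average undefined")
  sum(phi * s) / sum(phi)
}

#' Depth-dose of a beam configuration
#'
#' Dose (fluence times stopping power of the primaries, arbitrary units per
#' unit incident weight) on a depth grid, summed over layers.
#'
#' @param config A [beam_config()] (or single [beam_layer()]).
#' @param depths_mm Depths in mm.
#' @param settings [beam_settings()].
#' @param per_layer If TRUE return the depth x layer dose matrix for unit
#'   layer weights instead of the weighted sum.
#' @return Numeric vector of doses, or a matrix if `per_layer`.
#' @export
depth_dose <- function(config, depths_mm, settings = beam_settings(),
                       per_layer = FALSE) {
  if (inherits(config, "beam_layer")) config <- beam_config(config)
  stopifnot(inherits(config, "beam_config"))
  m <- vapply(config$layers, function(ly) {
    vapply(depths_mm, function(z) {
      sp <- depth_energy_spectrum(ly, z, settings)
      if (nrow(sp) == 0) 0 else sum(sp$fluence * stopping_power_water(sp$e_mid))
    }, numeric(1))
  }, numeric(length(depths_mm)))
  m <- matrix(m, nrow = length(depths_mm))
  if (per_layer) return(m)
  w <- vapply(config$layers, `[[`, numeric(1), "weight")
  drop(m %*% w)
}

#' LET spectrum of a beam configuration at one depth
#'
#' Superposes the weighted per-layer energy spectra and maps them onto the
#' 0.05 keV/um grid. If `dose_Gy` is given the spectrum is rescaled to that
#' total dose.
#'
#' @param config A [beam_config()] or [beam_layer()].
#' @param depth_mm Depth in mm.
#' @param dose_Gy Optional total dose in Gy to rescale to.
#' @param sw_bin LET bin width, keV/um.
#' @param settings [beam_settings()].
#' @return A [let_spectrum()].
#' @export
#' @examples
#' sp <- beam_let_spectrum(beam_layer(179.7), 20, dose_Gy = 1)
#' round(ld_of(sp), 1)
beam_let_spectrum <- function(config, depth_mm, dose_Gy = NULL,
                              sw_bin = 0.05, settings = beam_settings()) {
  if (inherits(config, "beam_layer")) config <- beam_config(config)
  stopifnot(inherits(config, "beam_config"))
  sps <- lapply(config$layers, function(ly) {
    sp <- depth_energy_spectrum(ly, depth_mm, settings)
    sp$fluence <- sp$fluence * ly$weight
    sp
  })
  sps <- Filter(function(s) nrow(s) > 0, sps)
  if (length(sps) == 0)
    stop(sprintf("no primary fluence at depth %.3g mm", depth_mm))
  out <- spectrum_to_let(sps, sw_bin = sw_bin, label = config$label,
                         depth_mm = depth_mm)
  if (!is.null(dose_Gy)) out <- rescale_dose(out, dose_Gy)
  out
}

#' Dose, Ld and Lt depth profile of a beam
#'
#' @param config A [beam_config()].
#' @param depths_mm Depths in mm.
#' @param settings [beam_settings()].
#' @return A data frame with `depth_mm`, `dose` (arbitrary units),
#'   `ld_keV_um`, `lt_keV_um`; depths beyond the beam range get zero dose
#'   and NA LET.
#' @export
depth_profile <- function(config, depths_mm, settings = beam_settings()) {
  if (inherits(config, "beam_layer")) config <- beam_config(config)
  rows <- lapply(depths_mm, function(z) {
    sp <- tryCatch(beam_let_spectrum(config, z, settings = settings),
                   error = function(e) NULL)
    if (is.null(sp) || total_dose(sp) == 0)
      return(data.frame(depth_mm = z, dose = 0, ld_keV_um = NA_real_,
                        lt_keV_um = NA_real_))
    data.frame(depth_mm = z, dose = total_dose(sp), ld_keV_um = ld_of(sp),
               lt_keV_um = lt_of(sp))
  })
  do.call(rbind, rows)
}

#' Least-squares SOBP layer weights
#'
#' Non-negative least squares of the per-layer depth-dose curves against a
#' constant target dose over the plateau window, on a 0.1 mm depth grid.
#'
#' @param layers List of [beam_layer()]s.
#' @param plateau Depth window `c(from, to)` in mm.
#' @param target_dose Plateau dose level (Gy; the weights carry the scale).
#' @param depth_step Grid resolution in mm.
#' @param settings [beam_settings()].
#' @return List with `weights`, `flatness` (max relative deviation from the
#'   target over the grid), `depths_mm` and `dose` (achieved plateau dose).
#' @export
sobp_weights <- function(layers, plateau = c(30, 35), target_dose = 1,
                         depth_step = 0.1, settings = beam_settings()) {
  if (inherits(layers, "beam_layer")) layers <- list(layers)
  stopifnot(length(layers) >= 1, length(plateau) == 2, plateau[1] <= plateau[2],
            target_dose >= 0)
  z <- seq(plateau[1], plateau[2], by = depth_step)
  cfg <- beam_config(layers, label = "sobp-fit")
  A <- depth_dose(cfg, z, settings, per_layer = TRUE)
  if (all(A == 0))
    stop("infeasible plateau: beyond the range of every layer")
  if (target_dose == 0) {
    w <- rep(0, length(layers))
    return(list(weights = w, flatness = 0, depths_mm = z,
                dose = rep(0, length(z))))
  }
  b <- rep(target_dose, length(z))
  w <- if (length(layers) == 1L) {
    max(sum(A * b) / sum(A * A), 0)
  } else {
    pracma::lsqnonneg(A, b)$x
  }
  achieved <- drop(A %*% w)
  list(weights = as.numeric(w),
       flatness = max(abs(achieved - target_dose)) / target_dose,
       depths_mm = z, dose = achieved)
}

#' The high-LET SOBP beam "b1" and its low-LET superpositions
#'
#' `beam_b1()` composes the six lowest clinical energy layers
#' (62.4--67.5 MeV) into a 1 Gy SOBP over 30--35 mm via [sobp_weights()].
#' `beam_b2()` replaces 50% of the initial fluence with a 252.7 MeV
#' low-LET layer; `beam_b3()` lets that layer carry 50% of the plateau
#' dose; both preserve the plateau dose and the low-energy weight ratios
#' (see [add_low_let_beam()]).
#'
#' @param settings [beam_settings()].
#' @param plateau Plateau window in mm.
#' @param target_dose Plateau dose in Gy.
#' @return A [beam_config()].
#' @export
beam_b1 <- function(settings = beam_settings(), plateau = c(30, 35),
                    target_dose = 1) {
  e <- seq(62.4, 67.5, length.out = 6)
  layers <- lapply(e, beam_layer)
  fit <- sobp_weights(layers, plateau, target_dose, settings = settings)
  layers <- Map(function(ly, w) { ly$weight <- w; ly }, layers, fit$weights)
  beam_config(layers, label = "b1")
}

#' @rdname beam_b1
#' @export
beam_b2 <- function(settings = beam_settings(), plateau = c(30, 35)) {
  add_low_let_beam(beam_b1(settings, plateau), mode = "fluence",
                   fraction = 0.5, plateau = plateau, settings = settings,
                   label = "b2")
}

#' @rdname beam_b1
#' @export
beam_b3 <- function(settings = beam_settings(), plateau = c(30, 35)) {
  add_low_let_beam(beam_b1(settings, plateau), mode = "dose",
                   fraction = 0.5, plateau = plateau, settings = settings,
                   label = "b3")
}

#' Superpose a low-LET high-energy layer on a SOBP
#'
#' In `"fluence"` mode the given fraction of the total initial fluence is
#' reassigned to the high-energy layer and the whole beam is rescaled so
#' the mean plateau dose is preserved. In `"dose"` mode the high layer's
#' weight is solved so that its plateau dose share equals the fraction,
#' with the total plateau dose preserved. The weight ratios of the base
#' layers are kept in both modes.
#'
#' @param base A [beam_config()], typically [beam_b1()].
#' @param high The low-LET layer to superpose (default 252.7 MeV).
#' @param mode "fluence" or "dose".
#' @param fraction Fraction in `[0, 1]`.
#' @param plateau Plateau window in mm used to evaluate dose shares.
#' @param settings [beam_settings()].
#' @param label Label of the composed beam.
#' @return A [beam_config()] including the high-energy layer.
#' @export
add_low_let_beam <- function(base, high = beam_layer(252.7),
                             mode = c("fluence", "dose"), fraction,
                             plateau = c(30, 35),
                             settings = beam_settings(), label = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(base, "beam_config"), inherits(high, "beam_layer"),
            is.numeric(fraction), length(fraction) == 1,
            fraction >= 0, fraction <= 1)
  if (is.null(label))
    label <- sprintf("%s+%.4gMeV(%s %.2g)", base$label, high$energy, mode,
                     fraction)
  if (fraction == 0) return(base)
  z <- seq(plateau[1], plateau[2], by = 0.1)
  d_base <- mean(depth_dose(base, z, settings))
  d_high_unit <- mean(depth_dose(beam_config(list(high)), z, settings))
  w0 <- vapply(base$layers, `[[`, numeric(1), "weight")
  W <- sum(w0)
  if (mode == "fluence") {
    low <- Map(function(ly, w) { ly$weight <- w * (1 - fraction); ly },
               base$layers, w0)
    high$weight <- fraction * W
    cfg <- beam_config(c(low, list(high)), label = label)
    d_new <- mean(depth_dose(cfg, z, settings))
    s <- d_base / d_new
    cfg$layers <- lapply(cfg$layers, function(ly) {
      ly$weight <- ly$weight * s; ly
    })
    cfg
  } else {
    if (d_high_unit <= 0)
      stop("dose mode infeasible: the high-energy layer deposits no dose in the plateau")
    low <- Map(function(ly, w) { ly$weight <- w * (1 - fraction); ly },
               base$layers, w0)
    high$weight <- fraction * d_base / d_high_unit
    beam_config(c(low, list(high)), label = label)
  }
}

#' The low-LET reference field
#'
#' A single 179.7 MeV layer; the reference beam quality Q0 is its spectrum
#' at 2 cm depth, where the primary-proton dose-averaged LET is
#' 0.5 keV/um.
#'
#' @return A [beam_config()] labelled "Q0".
#' @export
beam_reference <- function() {
  beam_config(list(beam_layer(179.7)), label = "Q0")
}
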