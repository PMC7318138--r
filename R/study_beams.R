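# The nine-beam synthetic study set: four single energy layers, the
# b1/b2/b3 arrangements and two box SOBPs at shallow and deep positions,
# each with canonical evaluation depths, plus the spectrum-resolved RE
# dataset computed over them.

#' The nine-beam synthetic study set
#'
#' Builds the nine beam arrangements used to span clinically relevant
#' dose-averaged LET: four single energy layers (62, 148, 179.7,
#' 252.7 MeV), the high-LET SOBP `b1` and its low-LET superpositions
#' `b2`/`b3`, and two 5 cm box SOBPs centred at 6 and 30 cm. Each element
#' carries canonical evaluation depths from the entrance plateau into the
#' distal region (film-position-like, excluding the steepest falloff).
#'
#' @param settings [beam_settings()].
#' @return A named list; each element is a list with `config` (a
#'   [beam_config()]) and `depths_mm`.
#' @export
study_beams <- function(settings = beam_settings()) {
  mk_sobp <- function(e_lo, e_hi, n, plateau, label) {
    layers <- lapply(seq(e_lo, e_hi, length.out = n), beam_layer)
    w <- sobp_weights(layers, plateau, 1, settings = settings)
    beam_config(Map(function(l, wi) { l$weight <- wi; l },
                    layers, w$weights), label = label)
  }
  list(
    single62 = list(config = beam_config(beam_layer(62), label = "62MeV"),
                    depths_mm = c(seq(5, 30, length.out = 12), 30.4, 30.6)),
    single148 = list(config = beam_config(beam_layer(148), label = "148MeV"),
                     depths_mm = seq(20, 134, length.out = 12)),
    single179 = list(config = beam_config(beam_layer(179.7),
                                          label = "179.7MeV"),
                     depths_mm = seq(20, 212, length.out = 12)),
    single252 = list(config = beam_config(beam_layer(252.7),
                                          label = "252.7MeV"),
                     depths_mm = seq(20, 370, length.out = 12)),
    b1 = list(config = beam_b1(settings),
              depths_mm = c(seq(30.2, 34.9, length.out = 10), 35.3, 35.6)),
    b2 = list(config = beam_b2(settings),
              depths_mm = seq(30.2, 34.9, length.out = 10)),
    b3 = list(config = beam_b3(settings),
              depths_mm = seq(30.2, 34.9, length.out = 10)),
    sobp6 = list(config = mk_sobp(65, 107, 9, c(35, 85), "sobp6cm"),
                 depths_mm = seq(36, 84, length.out = 10)),
    sobp30 = list(config = mk_sobp(206, 227, 8, c(275, 325), "sobp30cm"),
                  depths_mm = seq(276, 324, length.out = 10)))
}

#' Spectrum-resolved RE dataset over a beam set
#'
#' For every beam and depth, generates the LET spectrum at the given dose,
#' runs the spectrum-resolved net-OD integrator with the quench model,
#' decodes the apparent dose with the reference calibration and records the
#' relative effectiveness together with Ld and Lt.
#'
#' @param beams A beam set as returned by [study_beams()].
#' @param qp [quench_params()] of the film batch.
#' @param ref Reference [calibration_params()].
#' @param dose_Gy Dose at each position (constant, as in a plateau
#'   characterisation).
#' @param settings [beam_settings()].
#' @param isett [integrator_settings()].
#' @return A data frame with columns `beam`, `depth_mm`, `ld`, `lt`, `re`,
#'   `g`. Positions beyond a beam's range are dropped.
#' @export
spectrum_re_points <- function(beams, qp, ref, dose_Gy = 1,
                               settings = beam_settings(),
                               isett = integrator_settings()) {
  stopifnot(is.list(beams), inherits(qp, "quench_params"),
            inherits(ref, "calibration_params"))
  rows <- lapply(names(beams), function(nm) {
    cfg <- beams[[nm]]$config
    do.call(rbind, lapply(beams[[nm]]$depths_mm, function(z) {
      sp <- tryCatch(beam_let_spectrum(cfg, z, dose_Gy = dose_Gy,
                                       settings = settings),
                     error = function(e) NULL)
      if (is.null(sp)) return(NULL)
      o <- integrate_net_od(sp, qp, isett)
      pt <- relative_effectiveness(o, dose_Gy, ref, ld = ld_of(sp),
                                   warn_window = FALSE)
      data.frame(beam = nm, depth_mm = z, ld = pt$ld, lt = lt_of(sp),
                 re = pt$re, g = pt$g)
    }))
  })
  do.call(rbind, rows)
}
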