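# Plain-text formats, run configuration and the synthetic end-to-end
# pipeline tying calibration, quench fitting, simulation and RE correction
# together. All artifacts are columnar text or JSON with '#' provenance
# headers; no binary formats.

.prov_header <- function(config) {
  c(sprintf("# filmquench %s", as.character(utils::packageVersion("filmquench"))),
    sprintf("# seed: %d", config$seed),
    sprintf("# config: %s", .config_digest(config)))
}

.config_digest <- function(config) {
  flat <- unlist(config[setdiff(names(config), "out_dir")])
  txt <- paste(names(flat), flat, sep = "=", collapse = ";")
  tmp <- tempfile(); writeLines(txt, tmp); on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

#' Write / read a LET spectrum as columnar text
#'
#' Format: `#`-prefixed metadata header (label, depth, total dose, bin
#' width) followed by columns `sw_low_keV_um sw_high_keV_um dose_Gy
#' [fluence_per_cm2]`. The round trip preserves the numeric payload.
#'
#' @param spectrum A [let_spectrum()].
#' @param path File path.
#' @param extra_header Optional extra `#` lines (e.g. provenance).
#' @return `write_let_spectrum`: the path, invisibly. `read_let_spectrum`:
#'   a [let_spectrum()].
#' @export
write_let_spectrum <- function(spectrum, path, extra_header = character(0)) {
  stopifnot(inherits(spectrum, "let_spectrum"))
  e <- spectrum$bin_edges
  has_fl <- !is.null(spectrum$fluence_per_bin)
  hdr <- c(extra_header,
           sprintf("# label: %s", spectrum$label),
           sprintf("# depth_mm: %.10g", spectrum$depth_mm),
           sprintf("# total_dose_Gy: %.17g", total_dose(spectrum)),
           sprintf("# sw_bin_keV_um: %.10g", spectrum$bin_width),
           paste("# columns: sw_low_keV_um sw_high_keV_um dose_Gy",
                 if (has_fl) "fluence_per_cm2" else ""))
  rows <- if (has_fl) {
    sprintf("%.10g %.10g %.17g %.17g", e[-length(e)], e[-1],
            spectrum$dose_per_bin, spectrum$fluence_per_bin)
  } else {
    sprintf("%.10g %.10g %.17g", e[-length(e)], e[-1], spectrum$dose_per_bin)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_let_spectrum
#' @export
read_let_spectrum <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing artifact: %s", path))
  lines <- readLines(path)
  is_hdr <- grepl("^\\s*#", lines)
  meta <- lines[is_hdr]
  get_meta <- function(key, default = NA) {
    m <- grep(sprintf("^# %s:", key), meta, value = TRUE)
    if (length(m) == 0) return(default)
    sub(sprintf("^# %s:\\s*", key), "", m[1])
  }
  body_idx <- which(!is_hdr & nzchar(trimws(lines)))
  if (length(body_idx) == 0)
    stop(sprintf("empty spectrum: no data rows in %s", path))
  parts <- strsplit(trimws(lines[body_idx]), "\\s+")
  ncol <- length(parts[[1]])
  if (!ncol %in% c(3L, 4L))
    stop(sprintf("%s line %d: expected 3 or 4 columns, found %d",
                 path, body_idx[1], ncol))
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(v) != ncol || any(is.na(v)))
      stop(sprintf("%s line %d: malformed row", path, body_idx[i]))
    if (v[3] < 0)
      stop(sprintf("%s line %d: negative dose bin", path, body_idx[i]))
    parts[[i]] <- v
  }
  m <- do.call(rbind, parts)
  lo <- m[, 1]; hi <- m[, 2]
  if (nrow(m) > 1 && any(abs(lo[-1] - hi[-nrow(m)]) > 1e-9))
    stop(sprintf("%s: bins are not contiguous", path))
  w <- hi - lo
  if (max(abs(w - w[1])) > 1e-9 * w[1])
    stop(sprintf("%s: nonuniform bin width", path))
  let_spectrum(c(lo, hi[length(hi)]), m[, 3],
               fluence_per_bin = if (ncol == 4L) m[, 4] else NULL,
               label = get_meta("label", ""),
               depth_mm = as.numeric(get_meta("depth_mm", NA)))
}

#' Write / read model parameters as JSON
#'
#' Flat key/value JSON with units in the key names; the `type` field
#' dispatches reading back to the right constructor. Supports
#' [calibration_params()], [quench_params()] and `re_model` objects.
#'
#' @param params The parameter object.
#' @param path File path.
#' @return `write_params`: the path, invisibly; `read_params`: the object.
#' @export
write_params <- function(params, path) {
  x <- if (inherits(params, "calibration_params")) {
    list(type = "calibration_params", o_m = params$o_m,
         d_half_Gy = params$d_half, a = params$a)
  } else if (inherits(params, "quench_params")) {
    list(type = "quench_params", o_m = params$o_m, a = params$a,
         c1_Gy = params$c1, c2_Gy = params$c2, c3_keV_um = params$c3)
  } else if (inherits(params, "re_model")) {
    list(type = "re_model", order = params$order,
         coeffs = as.list(params$coeffs), ld_max_keV_um = params$ld_max)
  } else stop("unsupported parameter object")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing artifact: %s", path))
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e)
                  stop(sprintf("corrupted parameter file %s: %s", path,
                               conditionMessage(e))))
  if (is.null(x$type)) stop(sprintf("corrupted parameter file %s: no type", path))
  switch(x$type,
    calibration_params = calibration_params(x$o_m, x$d_half_Gy, x$a),
    quench_params = quench_params(x$o_m, x$a, x$c1_Gy, x$c2_Gy, x$c3_keV_um),
    re_model = {
      cf <- unlist(x$coeffs)
      .new_re_model(unname(cf), order = as.integer(x$order),
                    ld_max = x$ld_max_keV_um)
    },
    stop(sprintf("unknown parameter type '%s' in %s", x$type, path)))
}

#' Write / read a beam configuration
#'
#' Text table `energy_MeV sigma_E_MeV weight` with a `# label:` header.
#'
#' @param config A [beam_config()].
#' @param path File path.
#' @return `write_beam_config`: path, invisibly; `read_beam_config`: the
#'   [beam_config()].
#' @export
write_beam_config <- function(config, path) {
  stopifnot(inherits(config, "beam_config"))
  rows <- vapply(config$layers, function(ly)
    sprintf("%.10g %.10g %.17g", ly$energy, ly$sigma_e, ly$weight),
    character(1))
  writeLines(c(sprintf("# label: %s", config$label),
               "# columns: energy_MeV sigma_E_MeV weight", rows), path)
  invisible(path)
}

#' @rdname write_beam_config
#' @export
read_beam_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing artifact: %s", path))
  lines <- readLines(path)
  lab <- sub("^# label:\\s*", "", grep("^# label:", lines, value = TRUE)[1])
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) stop(sprintf("no layers in %s", path))
  layers <- lapply(body, function(ln) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (length(v) != 3 || any(is.na(v)))
      stop(sprintf("malformed layer row in %s: '%s'", path, ln))
    beam_layer(v[1], v[2], v[3])
  })
  beam_config(layers, label = if (is.na(lab)) "" else lab)
}

#' Run configuration for the synthetic pipeline
#'
#' Bundles the study conditions: the random seed, integrator step, LET bin
#' width, depth resolution, dose validity window, the SOBP measurement
#' depths and reference dose levels, the synthetic measurement noise, and
#' the ground-truth parameters the generator irradiates with.
#'
#' @param seed Integer RNG seed; every stochastic element derives from it.
#' @param out_dir Artifact directory.
#' @param delta_d Integrator dose step, Gy.
#' @param sw_bin LET bin width, keV/um.
#' @param depth_step Depth-dose grid step, mm.
#' @param dose_window Validity window of the quench characterisation, Gy.
#' @param depths_mm SOBP measurement depths (default 16 positions across the
#'   30--35 mm plateau).
#' @param doses_Gy Reference-quality dose levels (default 11 levels in the
#'   validity window).
#' @param noise_g Multiplicative Gaussian noise (1 sd) of the synthetic
#'   correction-factor measurements.
#' @param true_ref Ground-truth [calibration_params()] of the generator.
#' @param true_quench Ground-truth [quench_params()] of the generator.
#' @param plateau SOBP plateau window, mm.
#' @param settings [beam_settings()] of the transport model.
#' @return An object of class `run_config` (a list).
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("filmquench-run-"),
                       delta_d = 5e-5, sw_bin = 0.05, depth_step = 0.1,
                       dose_window = c(0.5, 2.5),
                       depths_mm = seq(30.2, 34.7, length.out = 16),
                       doses_Gy = seq(0.5, 2.5, length.out = 11),
                       noise_g = 0.005,
                       true_ref = calibration_params(0.93, 8.99, 0.82),
                       true_quench = quench_params(0.93, 0.82, 8.99, 15.7, 14.8),
                       plateau = c(30, 35),
                       settings = beam_settings()) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            delta_d > 0, sw_bin > 0, depth_step > 0,
            length(dose_window) == 2, dose_window[1] < dose_window[2],
            all(depths_mm > 0), all(doses_Gy > 0), noise_g >= 0,
            inherits(true_ref, "calibration_params"),
            inherits(true_quench, "quench_params"),
            inherits(settings, "beam_settings"))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 delta_d = delta_d, sw_bin = sw_bin, depth_step = depth_step,
                 dose_window = dose_window, depths_mm = depths_mm,
                 doses_Gy = doses_Gy, noise_g = noise_g, true_ref = true_ref,
                 true_quench = true_quench, plateau = plateau,
                 settings = settings),
            class = "run_config")
}

.artifact <- function(config, ...) file.path(config$out_dir, ...)

.stage_simulate <- function(config, verbose) {
  set.seed(config$seed)
  dir.create(.artifact(config, "spectra"), recursive = TRUE,
             showWarnings = FALSE)
  b1 <- beam_b1(config$settings, config$plateau)
  write_beam_config(b1, .artifact(config, "beam_b1.cfg"))
  isett <- integrator_settings(delta_d = config$delta_d)

  # SOBP spectra + synthetic film measurements at 1 Gy
  rows <- character(0)
  for (i in seq_along(config$depths_mm)) {
    z <- config$depths_mm[i]
    sp <- beam_let_spectrum(b1, z, dose_Gy = 1, sw_bin = config$sw_bin,
                            settings = config$settings)
    f <- .artifact(config, "spectra", sprintf("b1_%05.1fmm.txt", z))
    write_let_spectrum(sp, f, extra_header = .prov_header(config))
    o <- integrate_net_od(sp, config$true_quench, isett)
    g_true <- 1 / relative_effectiveness(o, 1, config$true_ref,
                                         warn_window = FALSE)$re
    g_meas <- g_true * (1 + stats::rnorm(1, 0, config$noise_g))
    rows <- c(rows, sprintf("%s %.17g %.17g %.4g", basename(f), 1, g_meas,
                            ld_of(sp)))
  }
  # reference-quality spectrum, measured at the configured dose levels
  ref_sp <- beam_let_spectrum(beam_reference(), 20, dose_Gy = 1,
                              sw_bin = config$sw_bin,
                              settings = config$settings)
  fref <- .artifact(config, "spectra", "reference_020.0mm.txt")
  write_let_spectrum(ref_sp, fref, extra_header = .prov_header(config))
  for (d in config$doses_Gy) {
    o <- integrate_net_od(rescale_dose(ref_sp, d), config$true_quench, isett)
    g_true <- 1 / relative_effectiveness(o, d, config$true_ref,
                                         warn_window = FALSE)$re
    g_meas <- g_true * (1 + stats::rnorm(1, 0, config$noise_g))
    rows <- c(rows, sprintf("%s %.17g %.17g %.4g", basename(fref), d, g_meas,
                            ld_of(ref_sp)))
  }
  writeLines(c(.prov_header(config),
               "# columns: spectrum_file dose_Gy g_measured ld_keV_um",
               rows), .artifact(config, "measurements.txt"))
  if (verbose)
    message(sprintf("simulate: %d spectra, %d measurement rows",
                    length(config$depths_mm) + 1L, length(rows)))
  invisible(NULL)
}

.stage_calibrate <- function(config, verbose) {
  set.seed(config$seed + 1L)
  doses <- seq(0, 10, length.out = 11)
  od <- net_od(doses, config$true_ref) * (1 + stats::rnorm(11, 0, 0.002))
  od[doses == 0] <- 0
  cal <- fit_calibration(doses, od)
  write_params(cal, .artifact(config, "calibration.json"))
  if (verbose)
    message(sprintf("calibrate: rms %.2g, o_m=%.3f d_half=%.3f a=%.3f",
                    attr(cal, "rms"), cal$o_m, cal$d_half, cal$a))
  invisible(NULL)
}

.stage_quench_fit <- function(config, verbose) {
  ref <- read_params(.artifact(config, "calibration.json"))
  mf <- .artifact(config, "measurements.txt")
  if (!file.exists(mf)) stop(sprintf("missing artifact: %s", mf))
  lines <- readLines(mf)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  training <- list(); ld <- g <- numeric(0)
  for (i in seq_along(body)) {
    v <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(v) != 4) stop(sprintf("%s: malformed manifest row %d", mf, i))
    sp <- read_let_spectrum(.artifact(config, "spectra", v[1]))
    dose <- as.numeric(v[2]); gm <- as.numeric(v[3])
    training[[i]] <- training_point(sp, gm, dose)
    ld <- c(ld, as.numeric(v[4])); g <- c(g, gm)
  }
  init <- initial_guess(ld, g, ref)
  fit <- fit_quench(training, ref, init,
                    settings = integrator_settings(delta_d = config$delta_d))
  write_params(fit$params, .artifact(config, "quench_params.json"))
  writeLines(c(.prov_header(config), "# best-so-far X2 per evaluation",
               sprintf("%.10e", fit$trace)),
             .artifact(config, "quench_trace.txt"))
  if (verbose)
    message(sprintf("quench-fit: X2 = %.3g over %d points, converged: %s",
                    fit$chi2, fit$n_points, fit$converged))
  invisible(NULL)
}

.stage_re_fit <- function(config, verbose) {
  ref <- read_params(.artifact(config, "calibration.json"))
  qp <- read_params(.artifact(config, "quench_params.json"))
  b1 <- read_beam_config(.artifact(config, "beam_b1.cfg"))
  isett <- integrator_settings(delta_d = config$delta_d)
  ld <- re <- numeric(0)
  rows <- character(0)
  for (z in config$depths_mm) {
    sp <- beam_let_spectrum(b1, z, dose_Gy = 1, sw_bin = config$sw_bin,
                            settings = config$settings)
    o <- integrate_net_od(sp, qp, isett)
    pt <- relative_effectiveness(o, 1, ref, ld = ld_of(sp),
                                 warn_window = FALSE)
    ld <- c(ld, pt$ld); re <- c(re, pt$re)
    rows <- c(rows, sprintf("%.4g %.17g %.17g %.17g", z, pt$ld, pt$re,
                            pt$re * 1))
  }
  model <- fit_re_ld(ld, re, order = 1)
  write_params(model, .artifact(config, "re_model.json"))
  writeLines(c(.prov_header(config),
               "# columns: depth_mm ld_keV_um re apparent_dose_Gy", rows),
             .artifact(config, "re_points.txt"))
  if (verbose)
    message(sprintf("re-fit: a0=%.4f a1=%.5f over %d points",
                    model$coeffs[1], model$coeffs[2], length(ld)))
  invisible(NULL)
}

.stage_correct <- function(config, verbose) {
  model <- read_params(.artifact(config, "re_model.json"))
  pf <- .artifact(config, "re_points.txt")
  if (!file.exists(pf)) stop(sprintf("missing artifact: %s", pf))
  lines <- readLines(pf)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rows <- character(0)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(v) != 4 || any(is.na(v)))
      stop(sprintf("%s: malformed profile row %d", pf, i))
    corrected <- correct_dose(v[4], v[2], model)
    rows <- c(rows, sprintf("%.4g %.17g %.17g %.17g", v[1], v[2], v[4],
                            corrected))
  }
  writeLines(c(.prov_header(config),
               "# columns: depth_mm ld_keV_um apparent_dose_Gy corrected_dose_Gy",
               rows), .artifact(config, "corrected.txt"))
  if (verbose) message(sprintf("correct: %d rows corrected", length(rows)))
  invisible(NULL)
}

#' Run the synthetic end-to-end pipeline
#'
#' Stages mirror the experimental workflow: `simulate` generates the
#' high-LET SOBP, its LET spectra and synthetic film measurements;
#' `calibrate` fits the reference bimolecular calibration; `quench-fit`
#' inverse-optimises the LET dependence; `re-fit` computes the
#' spectrum-resolved RE set and fits the linear RE(Ld) corrector;
#' `correct` applies it to apparent doses. `"all"` runs the full chain.
#' All artifacts are deterministic text files given the seed and carry
#' provenance headers (package version, seed, config digest).
#'
#' @param config A [run_config()].
#' @param command One of "all", "simulate", "calibrate", "quench-fit",
#'   "re-fit", "correct".
#' @param verbose Print per-stage scalars.
#' @return Invisibly, a list with `status` (0 on success) and the artifact
#'   paths present in `config$out_dir`. Missing stage inputs raise an error
#'   naming the missing artifact.
#' @export
run_pipeline <- function(config, command = c("all", "simulate", "calibrate",
                                             "quench-fit", "re-fit",
                                             "correct"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  command <- match.arg(command)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (command == "all")
    c("simulate", "calibrate", "quench-fit", "re-fit", "correct")
  else command
  for (st in stages) {
    switch(st,
           "simulate" = .stage_simulate(config, verbose),
           "calibrate" = .stage_calibrate(config, verbose),
           "quench-fit" = .stage_quench_fit(config, verbose),
           "re-fit" = .stage_re_fit(config, verbose),
           "correct" = .stage_correct(config, verbose))
  }
  arts <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  invisible(list(status = 0L, artifacts = arts))
}
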