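# Practical single-parameter corrector: polynomial RE(Ld) models, fitting,
# evaluation and dose correction.

.new_re_model <- function(coeffs, order, ld_max, rms = NA_real_, n = NA_integer_,
                          data = NULL, name = NULL) {
  names(coeffs) <- if (order == 1) c("a0", "a1") else paste0("b", 0:order)
  structure(list(coeffs = coeffs, order = order, ld_max = ld_max,
                 rms = rms, n = n, data = data, name = name),
            class = "re_model")
}

#' Reference RE(Ld) coefficient sets
#'
#' Ships the published first- and fourth-order polynomial parameterisations
#' of relative effectiveness versus dose-averaged LET for an EBT3 film batch
#' in proton beams (fit domain limited to 15 keV/um):
#' linear a0 = 1.0258, a1 = -0.0211 (keV/um)^-1; quartic b0 = 1.0054,
#' b1 = -6.4262e-4, b2 = -4.9426e-3, b3 = 4.1747e-4, b4 = -1.1622e-5.
#'
#' @param name Which fixture: `"ebt3-linear-2020"` or `"ebt3-quartic-2020"`.
#' @return An object of class `re_model`.
#' @export
#' @examples
#' m <- re_model_fixture("ebt3-linear-2020")
#' round(evaluate_re(m, c(1, 5, 10)), 1) # 1.0 0.9 0.8
re_model_fixture <- function(name = c("ebt3-linear-2020",
                                      "ebt3-quartic-2020")) {
  name <- match.arg(name)
  if (name == "ebt3-linear-2020") {
    .new_re_model(c(1.0258, -0.0211), order = 1L, ld_max = 15, name = name)
  } else {
    .new_re_model(c(1.0054, -6.4262e-4, -4.9426e-3, 4.1747e-4, -1.1622e-5),
                  order = 4L, ld_max = 15, name = name)
  }
}

#' Evaluate a RE(Ld) model
#'
#' Polynomial evaluation of the relative effectiveness at given
#' dose-averaged LET. Values outside `[0, ld_max]` are clamped to the
#' domain boundary with a warning and flagged in the `"clamped"` attribute:
#' the correction never extrapolates silently.
#'
#' @param model An `re_model` (from [fit_re_ld()] or [re_model_fixture()]).
#' @param ld Dose-averaged LET in keV/um (vectorised).
#' @return RE values; attribute `"clamped"` marks clamped entries.
#' @export
evaluate_re <- function(model, ld) {
  stopifnot(inherits(model, "re_model"), is.numeric(ld), all(is.finite(ld)))
  clamped <- ld < 0 | ld > model$ld_max
  if (any(clamped)) {
    warning(sprintf(
      "%d Ld value(s) outside [0, %g] keV/um: clamped to the fit domain",
      sum(clamped), model$ld_max))
    ld <- pmin(pmax(ld, 0), model$ld_max)
  }
  re <- drop(outer(ld, 0:model$order, `^`) %*% model$coeffs)
  if (any(clamped)) attr(re, "clamped") <- clamped
  re
}

#' Fit a polynomial RE(Ld) model
#'
#' Ordinary (unweighted) least squares of RE on powers of Ld. Points with
#' Ld above `ld_max` are excluded before fitting, mirroring the 15 keV/um
#' upper fit limit of clinically relevant LET values.
#'
#' @param ld Dose-averaged LET values, keV/um.
#' @param re Relative effectiveness values.
#' @param order Polynomial order, 1 or 4.
#' @param ld_max Fit-domain limit in keV/um.
#' @return An object of class `re_model` with `print()`, `coef()`,
#'   `predict()`, `plot()`, `residuals()` and `summary()` methods.
#' @export
#' @examples
#' ld <- seq(1, 12, by = 0.5)
#' m <- fit_re_ld(ld, 1.02 - 0.02 * ld, order = 1)
#' coef(m)
fit_re_ld <- function(ld, re, order = 1, ld_max = 15) {
  stopifnot(is.numeric(ld), is.numeric(re), length(ld) == length(re),
            all(is.finite(ld)), all(is.finite(re)), ld_max > 0)
  if (!order %in% c(1L, 4L)) stop("'order' must be 1 or 4")
  keep <- ld <= ld_max
  ld <- ld[keep]; re <- re[keep]
  if (length(ld) < order + 1)
    stop(sprintf("need >= %d points with ld <= ld_max, got %d",
                 order + 1, length(ld)))
  df <- data.frame(ld = ld, re = re)
  fit <- stats::lm(re ~ stats::poly(ld, degree = order, raw = TRUE), data = df)
  if (fit$rank < order + 1)
    stop("rank-deficient design: Ld values do not support this order")
  cf <- unname(stats::coef(fit))
  .new_re_model(cf, order = as.integer(order), ld_max = ld_max,
                rms = sqrt(mean(stats::residuals(fit)^2)), n = length(ld),
                data = df)
}

#' @export
print.re_model <- function(x, ...) {
  kind <- if (x$order == 1) "linear" else sprintf("order-%d", x$order)
  cat(sprintf("RE(Ld) model (%s%s), domain [0, %g] keV/um\n", kind,
              if (!is.null(x$name)) paste0(", fixture '", x$name, "'") else "",
              x$ld_max))
  print(round(x$coeffs, 6))
  if (is.finite(x$rms))
    cat(sprintf("  fitted to %d points, RMS residual %.4g\n", x$n, x$rms))
  invisible(x)
}

#' @export
coef.re_model <- function(object, ...) object$coeffs

#' @export
predict.re_model <- function(object, ld, ...) evaluate_re(object, ld)

#' @export
residuals.re_model <- function(object, ...) {
  if (is.null(object$data)) stop("fixture model carries no fit data")
  object$data$re - evaluate_re(object, object$data$ld)
}

#' @export
summary.re_model <- function(object, ...) {
  cat(sprintf("RE(Ld) polynomial, order %d, RE(0) = %.4g\n", object$order,
              object$coeffs[1]))
  grid <- c(1, 2, 5, 10, min(12, object$ld_max))
  print(round(stats::setNames(evaluate_re(object, grid),
                              paste0("Ld=", grid)), 4))
  invisible(object)
}

#' @export
plot.re_model <- function(x, ...) {
  ld <- seq(0, x$ld_max, length.out = 200)
  graphics::plot(ld, evaluate_re(x, ld), type = "l",
                 xlab = "Ld (keV/um)", ylab = "RE",
                 main = "Relative effectiveness vs dose-averaged LET", ...)
  if (!is.null(x$data)) graphics::points(x$data$ld, x$data$re, cex = 0.5)
  invisible(x)
}

#' Correct an apparent film dose with a RE(Ld) model
#'
#' The reciprocal of RE is the beam-quality correction factor:
#' corrected = apparent / RE(Ld).
#'
#' @param apparent_dose Apparent dose(s) in Gy decoded with the reference
#'   calibration, >= 0.
#' @param ld Dose-averaged LET in keV/um (scalar or same length).
#' @param model An `re_model`.
#' @return Corrected dose(s) in Gy.
#' @export
#' @examples
#' correct_dose(0.8, 10, re_model_fixture("ebt3-linear-2020"))
correct_dose <- function(apparent_dose, ld, model) {
  stopifnot(is.numeric(apparent_dose), all(is.finite(apparent_dose)),
            all(apparent_dose >= 0))
  re <- as.numeric(evaluate_re(model, ld))
  if (any(re <= 0))
    stop("RE evaluated non-positive: model invalid at this Ld")
  apparent_dose / re
}
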