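# Embedded proton-in-water stopping powers: table access, log-log
# interpolation, the inverse on the high-energy branch, and CSDA ranges.

.fq <- new.env(parent = emptyenv())

#' Embedded water stopping-power table
#'
#' Returns the packaged ICRU49/PSTAR-consistent table of unrestricted
#' electronic stopping power of liquid water for protons. Values are stored
#' as keV/um (mass stopping power in MeV cm2/g times a density of 1 g/cm3).
#' The table has a single interior maximum near 0.08 MeV and is strictly
#' decreasing above it; the mean excitation potential underlying the values
#' is 78 eV (informational).
#'
#' @return A data frame with columns `energy_MeV` and `sw_keV_um`.
#' @export
#' @examples
#' head(water_stopping_table())
water_stopping_table <- function() {
  if (is.null(.fq$table)) {
    path <- system.file("extdata", "water_proton_stopping.txt",
                        package = "filmquench", mustWork = TRUE)
    tab <- utils::read.table(path, comment.char = "#",
                             col.names = c("energy_MeV", "sw_keV_um"))
    stopifnot(all(diff(tab$energy_MeV) > 0), all(tab$sw_keV_um > 0))
    .fq$table <- tab
    imax <- which.max(tab$sw_keV_um)
    .fq$e_peak <- tab$energy_MeV[imax]
    .fq$sw_peak <- tab$sw_keV_um[imax]
    # high-energy branch (E >= peak), monotone decreasing in E
    .fq$branch_e <- tab$energy_MeV[imax:nrow(tab)]
    .fq$branch_s <- tab$sw_keV_um[imax:nrow(tab)]
  }
  .fq$table
}

#' Unrestricted electronic stopping power of water for protons
#'
#' Log-log interpolation of the embedded table. 15, 5 and 1 MeV protons
#' correspond to 3.3, 7.9 and 26.1 keV/um; 250 MeV to 0.4 keV/um.
#'
#' @param energy_MeV Proton kinetic energy in MeV (vectorised). Must lie
#'   within the tabulated domain; no extrapolation is performed.
#' @return Stopping power in keV/um.
#' @export
#' @examples
#' stopping_power_water(c(1, 5, 15, 250))
stopping_power_water <- function(energy_MeV) {
  tab <- water_stopping_table()
  if (!is.numeric(energy_MeV) || any(!is.finite(energy_MeV)))
    stop("'energy_MeV' must be finite numeric")
  lo <- tab$energy_MeV[1L]; hi <- tab$energy_MeV[nrow(tab)]
  if (any(energy_MeV < lo | energy_MeV > hi))
    stop(sprintf("energy outside tabulated domain [%g, %g] MeV", lo, hi))
  exp(stats::approx(log(tab$energy_MeV), log(tab$sw_keV_um),
                    xout = log(energy_MeV))$y)
}

#' Proton energy from stopping power (high-energy branch)
#'
#' Inverts [stopping_power_water()] on the branch above the Bragg maximum
#' (E > 0.08 MeV), where the mapping is one-to-one. Protons below the
#' maximum are treated as having the quenching of the equal-Sw proton on
#' this branch, so the inverse is restricted to it.
#'
#' @param sw_keV_um Stopping power in keV/um (vectorised).
#' @return Proton energy in MeV, with `stopping_power_water(E) == sw` to
#'   within interpolation accuracy (<0.1%).
#' @export
#' @examples
#' energy_from_sw(7.9) # ~5 MeV
energy_from_sw <- function(sw_keV_um) {
  water_stopping_table()
  if (!is.numeric(sw_keV_um) || any(!is.finite(sw_keV_um)))
    stop("'sw_keV_um' must be finite numeric")
  smin <- .fq$branch_s[length(.fq$branch_s)]
  if (any(sw_keV_um > .fq$sw_peak))
    stop(sprintf(
      "sw = %g keV/um exceeds the branch maximum (%g keV/um at %g MeV)",
      max(sw_keV_um), .fq$sw_peak, .fq$e_peak))
  if (any(sw_keV_um < smin))
    stop(sprintf("sw below tabulated branch minimum (%g keV/um)", smin))
  # branch_s decreases with branch_e: interpolate in reversed order
  exp(stats::approx(log(rev(.fq$branch_s)), log(rev(.fq$branch_e)),
                    xout = log(sw_keV_um))$y)
}

.csda_grid <- function() {
  if (is.null(.fq$range_e)) {
    tab <- water_stopping_table()
    e0 <- 0.1
    e <- exp(seq(log(e0), log(tab$energy_MeV[nrow(tab)]), length.out = 4000L))
    s <- stopping_power_water(e) * 10  # keV/um -> MeV/cm
    inv <- 1 / s
    dr <- diff(e) * (inv[-1] + inv[-length(inv)]) / 2
    .fq$range_e <- e
    .fq$range_r <- c(0, cumsum(dr))  # cm, from the 0.1 MeV cutoff
  }
  invisible(NULL)
}

#' CSDA range of protons in water
#'
#' Continuous-slowing-down range, the quadrature of 1/S(E) from a 0.1 MeV
#' cutoff up to the given energy, evaluated on a cached dense log grid over
#' the embedded table.
#'
#' @param energy_MeV Proton kinetic energy in MeV (vectorised, >= 0.1).
#' @return Range in cm of water.
#' @export
#' @examples
#' csda_range(179.7)
csda_range <- function(energy_MeV) {
  .csda_grid()
  lo <- .fq$range_e[1L]; hi <- .fq$range_e[length(.fq$range_e)]
  if (!is.numeric(energy_MeV) || any(!is.finite(energy_MeV)))
    stop("'energy_MeV' must be finite numeric")
  tol <- 1e-9
  if (any(energy_MeV < lo * (1 - tol) | energy_MeV > hi * (1 + tol)))
    stop(sprintf("energy outside range domain [%g, %g] MeV", lo, hi))
  e <- pmin(pmax(energy_MeV, lo), hi)
  stats::approx(log(.fq$range_e), .fq$range_r, xout = log(e))$y
}

#' Proton energy at a given residual CSDA range
#'
#' Inverse of [csda_range()]; the residual-range method of analytic
#' transport (the mean energy at depth z is the energy whose range equals
#' the initial range minus z).
#'
#' @param range_cm Residual range in cm of water (vectorised, >= 0).
#' @return Proton energy in MeV; ranges at or below the 0.1 MeV cutoff map
#'   to 0.1 MeV.
#' @export
energy_at_range <- function(range_cm) {
  .csda_grid()
  if (!is.numeric(range_cm) || any(!is.finite(range_cm)))
    stop("'range_cm' must be finite numeric")
  if (any(range_cm > .fq$range_r[length(.fq$range_r)]))
    stop("residual range exceeds tabulated maximum")
  r <- pmax(range_cm, 0)
  stats::approx(.fq$range_r, log(.fq$range_e), xout = r)$y |> exp()
}
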