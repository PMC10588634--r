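#' Arrhenius thermal-damage integration
#'
#' Accumulates the injury integral
#' \eqn{\Omega = \int_0^\tau A \exp(-E_a/(R\,T(t)))\,dt} per grid node by
#' the trapezoidal rule over the stored temperature snapshots. Temperatures
#' are given in degrees Celsius and converted to kelvin internally; the
#' integrand is evaluated in log space, so the enormous pre-exponential
#' factor never overflows. Cooling after laser-off contributes whenever the
#' snapshot series extends past the switch-off time. No low-temperature
#' cutoff is applied: sub-coagulative temperatures contribute their
#' (negligible) true rate.
#'
#' Integrating `[0, t1]` and `[t1, t2]` separately and summing equals the
#' one-pass integral exactly (`omega_start` continues a previous field).
#'
#' @param T_series a `temperature_field` from [solve_pennes()] (or any list
#'   with `times` and a `[nr, nz, nt]` array `T` in degrees C).
#' @param params a [damage_parameters()] set.
#' @param omega_start optional `[nr, nz]` matrix of already-accumulated
#'   damage to continue from.
#' @return an object of class `damage_field`: `omega` (`[nr, nz]`),
#'   `t_end`, and `params`.
#' @export
integrate_arrhenius <- function(T_series, params = damage_parameters(),
                                omega_start = NULL) {
  stopifnot(inherits(params, "damage_parameters"))
  times <- T_series$times
  if (length(times) < 1 || any(diff(times) <= 0)) {
    stop("snapshot times must be strictly increasing", call. = FALSE)
  }
  d <- dim(T_series$T)
  omega <- omega_start %||% matrix(0, d[1], d[2])
  stopifnot(all(dim(omega) == d[1:2]))
  lnA <- log(params$A)
  rate <- function(s) {
    Tc <- T_series$T[, , s]
    r <- exp(lnA - params$Ea / (params$R * (Tc + 273.15)))
    r[is.na(Tc)] <- 0 # unmeshed (coolant) nodes accumulate no damage
    r
  }
  if (length(times) >= 2) {
    prev <- rate(1)
    for (s in 2:length(times)) {
      cur <- rate(s)
      omega <- omega + 0.5 * (prev + cur) * (times[s] - times[s - 1])
      prev <- cur
    }
  }
  structure(list(omega = omega, t_end = times[length(times)],
                 params = params),
            class = "damage_field")
}

#' Denatured molecular fraction for a damage value
#'
#' The fraction of native molecules lost at damage \eqn{\Omega} under
#' first-order kinetics, \eqn{100 (1 - e^{-\Omega})} percent;
#' \eqn{\Omega = 1} corresponds to 63% denaturation, the irreversible-damage
#' threshold.
#'
#' @param omega damage value(s), >= 0.
#' @return percentage in `[0, 100)`.
#' @examples
#' round(denatured_fraction(1)) # 63
#' @export
denatured_fraction <- function(omega) {
  if (any(omega < 0)) stop("omega must be >= 0", call. = FALSE)
  100 * (1 - exp(-omega))
}

#' Extract the ablation boundary from a damage field
#'
#' Marching-squares isoline of \eqn{\Omega} at the damage threshold with
#' linear sub-cell interpolation along cell edges (via
#' [grDevices::contourLines()]), the maximum cross-section diameter
#' `D2 = 2 * max(r)` over the contour, and the enclosed axisymmetric
#' volume (sum of node volumes with \eqn{\Omega \ge} threshold).
#'
#' @param damage a `damage_field` from [integrate_arrhenius()].
#' @param grid the grid it was computed on.
#' @param threshold damage threshold, default the field's
#'   `params$omega_threshold` (1).
#' @return an object of class `ablation_result`: `contour` (list of data
#'   frames with `r`, `z` in metres), `diameter` (mm; 0 when the field
#'   nowhere reaches the threshold) and `volume` (mm^3).
#' @export
ablation_boundary <- function(damage, grid, threshold = NULL) {
  stopifnot(inherits(damage, "damage_field"),
            inherits(grid, "axisym_grid"))
  threshold <- threshold %||% damage$params$omega_threshold
  check_positive(threshold, "threshold")
  om <- damage$omega
  om[is.na(om)] <- 0
  inside <- om >= threshold
  if (!any(inside)) {
    return(structure(list(contour = list(), diameter = 0, volume = 0,
                          threshold = threshold),
                     class = "ablation_result"))
  }
  cl <- if (diff(range(om)) > 0) {
    grDevices::contourLines(x = grid$r, y = grid$z, z = om,
                            levels = threshold)
  } else {
    list() # field constant at or above the threshold: no isoline exists
  }
  contour <- lapply(cl, function(s) data.frame(r = s$x, z = s$y))
  r_max <- if (length(contour) > 0) {
    max(vapply(contour, function(s) max(s$r), 0))
  } else {
    max(grid$r[row(om)[inside]]) # threshold exceeded out to the boundary
  }
  volume <- sum(grid$volumes[inside])
  structure(list(contour = contour,
                 diameter = 2 * r_max * 1e3,
                 volume = volume * 1e9,
                 threshold = threshold),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat(sprintf(
    "Ablation result (Omega >= %g): diameter %.2f mm, volume %.1f mm^3\n",
    x$threshold, x$diameter, x$volume))
  invisible(x)
}

#' @export
print.damage_field <- function(x, ...) {
  cat(sprintf("Damage field at t = %g s: max Omega = %.3g\n",
              x$t_end, max(x$omega, na.rm = TRUE)))
  invisible(x)
}
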