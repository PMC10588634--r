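# Gridded field containers shared by the optics and thermal stages.

fluence_field <- function(phi, mu_a, power, method, grid, ...) {
  absorbed_density <- mu_a * phi
  structure(c(list(phi = phi, absorbed_density = absorbed_density,
                   power = power, method = method, grid = grid),
              list(...)),
            class = "fluence_field")
}

#' @export
print.fluence_field <- function(x, ...) {
  cat(sprintf("Fluence field (%s), source power %g W\n", x$method, x$power))
  cat(sprintf("  absorbed %.4g W, escaped %.4g W", x$absorbed_power,
              x$escaped_power))
  if (!is.null(x$returned_power)) {
    cat(sprintf(", returned to catheter %.4g W", x$returned_power))
  }
  cat(sprintf("\n  peak fluence %.4g W/m^2\n", max(x$phi)))
  invisible(x)
}

# Pull a plain [r, z] matrix out of a field object.
field_matrix <- function(field, time_index = NULL) {
  if (is.matrix(field)) return(field)
  if (inherits(field, "fluence_field")) return(field$phi)
  if (inherits(field, "temperature_field")) {
    i <- time_index %||% dim(field$T)[3]
    return(field$T[, , i])
  }
  if (inherits(field, "damage_field")) return(field$omega)
  stop("unsupported field type", call. = FALSE)
}

#' Radial profile of a gridded field
#'
#' Interpolates a field (fluence, temperature, damage, or a plain matrix) at
#' requested radial distances on an axial plane, by default measured from
#' the outer edge of the catheter wall, matching how light-intensity and
#' temperature profiles are plotted against distance from the applicator.
#'
#' @param field a `fluence_field`, `temperature_field`, `damage_field`, or
#'   an `[nr, nz]` matrix of node values.
#' @param grid the [build_grid()] grid the field lives on.
#' @param z_plane axial position of the profile (m); default 0, the
#'   diffuser mid-plane.
#' @param radii distances at which to sample (m).
#' @param distances_from `"wall"` (from the catheter outer wall, requires an
#'   applicator grid) or `"axis"`.
#' @param time_index for temperature fields, which snapshot (default last).
#' @return data frame with columns `distance` (m, as requested), `radius`
#'   (m, from the axis) and `value`.
#' @export
radial_profile <- function(field, grid, z_plane = 0, radii,
                           distances_from = c("wall", "axis"),
                           time_index = NULL) {
  stopifnot(inherits(grid, "axisym_grid"))
  distances_from <- match.arg(distances_from)
  M <- field_matrix(field, time_index)
  if (length(radii) == 0) {
    return(data.frame(distance = numeric(0), radius = numeric(0),
                      value = numeric(0)))
  }
  offset <- if (distances_from == "wall") {
    if (is.na(grid$r_out)) {
      stop("wall-referenced distances need an applicator grid",
           call. = FALSE)
    }
    grid$r_out
  } else {
    0
  }
  r_abs <- radii + offset
  if (any(r_abs > max(grid$r) + 1e-12) || any(r_abs < min(grid$r) - 1e-12)) {
    stop("requested radius beyond the grid domain", call. = FALSE)
  }
  data.frame(distance = radii, radius = r_abs,
             value = interp_bilinear(grid$r, grid$z, M, r_abs,
                                     rep(z_plane, length(r_abs))))
}
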