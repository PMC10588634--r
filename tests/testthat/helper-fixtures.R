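# Shared fixtures: canonical parameter sets and small grids built in code.

fix_optics_1064 <- function() brain_optics("1064nm")
fix_optics_980 <- function() brain_optics("980nm")
fix_thermal <- function() thermal_properties()
fix_damage <- function() damage_parameters()

fix_applicator <- function(L1 = 0.010, power = 15) {
  applicator_spec(L1 = L1, D1 = 0.00155, power = power, duration = 120)
}

# coarse applicator grid for fast coupled tests
fix_grid_coarse <- function(app = fix_applicator(), spacing = 8e-4,
                            radius = 0.03, half = 0.03) {
  build_grid(app, domain_radius = radius, domain_halflength = half,
             spacing = spacing)
}

# full-cylinder grid for point-source verification harnesses
fix_grid_cylinder <- function(radius = 0.02, half = 0.02, spacing = 4e-4) {
  build_grid(NULL, domain_radius = radius, domain_halflength = half,
             spacing = spacing)
}

# infinite-medium diffusion Green's function for a unit point source
green_fluence <- function(r, optics) {
  D <- diffusion_coefficient(optics)
  exp(-mu_eff(optics) * r) / (4 * pi * D * r)
}

# volume-weighted spherical-shell average of a gridded field around origin
shell_average <- function(M, grid, r_centre, half_width) {
  R <- sqrt(outer(grid$r^2, grid$z^2, "+"))
  sel <- R >= r_centre - half_width & R < r_centre + half_width
  sum(M[sel] * grid$volumes[sel]) / sum(grid$volumes[sel])
}

# a temperature series on a trivial 1-node grid, for damage-kernel tests
make_T_series <- function(times, temps) {
  list(times = times, T = array(rep(temps, each = 1),
                                c(1, 1, length(times))))
}

# fluence-like object carrying a prescribed absorbed power density
make_source <- function(grid, Q) {
  structure(list(phi = Q, absorbed_density = Q, power = NA_real_),
            class = "fluence_field")
}
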