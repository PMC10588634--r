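#' Tissue optical properties
#'
#' Absorption, scattering and Henyey-Greenstein anisotropy of the (assumed
#' homogeneous, isotropic) brain tissue at the laser wavelength. Defaults are
#' the 1064 nm brain parameter set; [brain_optics()] retrieves either
#' wavelength from the material library.
#'
#' @param mu_a absorption coefficient (m^-1), > 0.
#' @param mu_s scattering coefficient (m^-1), >= 0.
#' @param g Henyey-Greenstein anisotropy factor, 0 <= g < 1.
#' @param wavelength_label text label, `"1064nm"` or `"980nm"` (free-form
#'   labels are allowed for non-library parameter sets).
#' @return an object of class `optical_properties`.
#' @examples
#' op <- brain_optics("1064nm")
#' mu_eff(op) # effective attenuation coefficient, ~305 m^-1
#' @export
optical_properties <- function(mu_a = 50, mu_s = 5700, g = 0.9,
                               wavelength_label = "1064nm") {
  check_positive(mu_a, "mu_a")
  check_positive(mu_s, "mu_s", strict = FALSE)
  if (!is.numeric(g) || length(g) != 1L || is.na(g) || g < 0 || g >= 1) {
    stop("g must satisfy 0 <= g < 1", call. = FALSE)
  }
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g,
                 wavelength_label = as.character(wavelength_label)),
            class = "optical_properties")
}

#' @rdname optical_properties
#' @param wavelength `"1064nm"` or `"980nm"`.
#' @export
brain_optics <- function(wavelength = c("1064nm", "980nm")) {
  wavelength <- match.arg(wavelength)
  lib <- material_library()
  m <- if (wavelength == "1064nm") lib$brain_1064 else lib$brain_980
  optical_properties(mu_a = material_si(m, "absorption_coefficient"),
                     mu_s = material_si(m, "scattering_coefficient"),
                     g = material_si(m, "anisotropy_factor"),
                     wavelength_label = wavelength)
}

#' Tissue and blood thermal properties
#'
#' Constants of the Pennes bioheat equation
#' \deqn{\rho c \,\partial T/\partial t = \nabla\cdot k\nabla T +
#'       \rho_b c_b \omega_b (T_b - T) + Q_r}
#' (metabolic heat is neglected: it is small against the laser source at
#' coagulative temperatures). Defaults are the brain/blood library values.
#'
#' @param rho tissue density (kg m^-3).
#' @param c tissue heat capacity (J kg^-1 K^-1).
#' @param k tissue thermal conductivity (W m^-1 K^-1).
#' @param rho_b blood density (kg m^-3).
#' @param c_b blood heat capacity (J kg^-1 K^-1).
#' @param omega_b blood perfusion rate (s^-1), >= 0.
#' @param T_b arterial blood temperature (degrees C), default 37.
#' @return an object of class `thermal_properties`.
#' @export
thermal_properties <- function(rho = 1040, c = 3590, k = 0.503,
                               rho_b = 1050, c_b = 3640, omega_b = 0.0048,
                               T_b = 37) {
  check_positive(rho, "rho"); check_positive(c, "c"); check_positive(k, "k")
  check_positive(rho_b, "rho_b"); check_positive(c_b, "c_b")
  check_positive(omega_b, "omega_b", strict = FALSE)
  stopifnot(is.numeric(T_b), length(T_b) == 1L, is.finite(T_b))
  structure(list(rho = rho, c = c, k = k, rho_b = rho_b, c_b = c_b,
                 omega_b = omega_b, T_b = T_b),
            class = "thermal_properties")
}

#' Blood perfusion heat-sink coefficient
#'
#' The coefficient \eqn{\rho_b c_b \omega_b} multiplying \eqn{(T_b - T)} in
#' the Pennes perfusion term, in W m^-3 K^-1.
#'
#' @param thermal a [thermal_properties()] object.
#' @return scalar, W m^-3 K^-1 (18345.6 for the default blood values).
#' @export
perfusion_heat_sink_coefficient <- function(thermal) {
  stopifnot(inherits(thermal, "thermal_properties"))
  thermal$rho_b * thermal$c_b * thermal$omega_b
}

#' Arrhenius damage kinetics parameters
#'
#' Parameters of the thermal-injury integral
#' \eqn{\Omega = \int_0^\tau A \exp(-E_a/(R T(t)))\,dt} with \eqn{T} in
#' kelvin. \eqn{\Omega = 1} (about 63% molecular denaturation) marks
#' irreversible damage.
#'
#' @param A pre-exponential frequency factor (s^-1).
#' @param Ea activation energy (J mol^-1).
#' @param R universal gas constant (J mol^-1 K^-1).
#' @param omega_threshold damage threshold defining the ablation boundary.
#' @return an object of class `damage_parameters`.
#' @export
damage_parameters <- function(A = 3.1e98, Ea = 6.28e5, R = 8.31,
                              omega_threshold = 1) {
  check_positive(A, "A", finite = FALSE); check_positive(Ea, "Ea")
  check_positive(R, "R"); check_positive(omega_threshold, "omega_threshold")
  structure(list(A = A, Ea = Ea, R = R, omega_threshold = omega_threshold),
            class = "damage_parameters")
}

#' Laser applicator specification
#'
#' Geometry and drive settings of the water-cooled diffusing-tip applicator.
#' The cylindrical diffuser of length `L1` emits uniformly over its surface;
#' the coolant is modelled as an isothermal inner catheter wall.
#'
#' All lengths are SI metres; use [to_si()] for unit-tagged input.
#'
#' @param L1 diffuser (diffusion tip) length (m); clinical tips are 4 or
#'   10 mm but any positive length is accepted.
#' @param D1 catheter outer diameter (m).
#' @param coolant_wall_temperature isothermal inner-wall temperature
#'   (degrees C), default 25.
#' @param power laser power (W), >= 0.
#' @param duration irradiation time (s), >= 0.
#' @return an object of class `applicator_spec`.
#' @examples
#' applicator_spec(L1 = to_si(10, "mm"), D1 = to_si(1.55, "mm"),
#'                 power = 15, duration = 120)
#' @export
applicator_spec <- function(L1 = 0.010, D1 = 0.00155,
                            coolant_wall_temperature = 25,
                            power = 10, duration = 120) {
  check_positive(L1, "L1"); check_positive(D1, "D1")
  check_positive(power, "power", strict = FALSE)
  check_positive(duration, "duration", strict = FALSE)
  stopifnot(is.numeric(coolant_wall_temperature),
            is.finite(coolant_wall_temperature))
  structure(list(L1 = L1, D1 = D1,
                 coolant_wall_temperature = coolant_wall_temperature,
                 power = power, duration = duration),
            class = "applicator_spec")
}

#' Material parameter library
#'
#' Named parameter sets for brain tissue (at 1064 nm and at the 980 nm
#' control wavelength), blood, cooling water and the polycarbonate catheter
#' wall, stored with their conventional printed values and units. Values are
#' retrieved in SI via [material_si()].
#'
#' @return a named list of materials; each material is a data frame with
#'   columns `parameter`, `value`, `unit`.
#' @examples
#' lib <- material_library()
#' material_si(lib$brain_1064, "absorption_coefficient") # 50 m^-1
#' @export
material_library <- function() {
  mat <- function(...) {
    rows <- list(...)
    data.frame(parameter = vapply(rows, `[[`, "", 1),
               value = vapply(rows, function(r) as.numeric(r[[2]]), 0),
               unit = vapply(rows, `[[`, "", 3),
               stringsAsFactors = FALSE)
  }
  list(
    brain_1064 = mat(
      list("absorption_coefficient", 0.5, "cm^-1"),
      list("scattering_coefficient", 57, "cm^-1"),
      list("anisotropy_factor", 0.9, ""),
      list("density", 1040, "kg/m^3"),
      list("heat_conductivity", 0.503, "W m^-1 K^-1"),
      list("heat_capacity", 3590, "J kg^-1 K^-1")
    ),
    brain_980 = mat(
      list("absorption_coefficient", 0.9, "cm^-1"),
      list("scattering_coefficient", 78, "cm^-1"),
      list("anisotropy_factor", 0.95, ""),
      list("density", 1040, "kg/m^3"),
      list("heat_conductivity", 0.503, "W m^-1 K^-1"),
      list("heat_capacity", 3590, "J kg^-1 K^-1")
    ),
    blood = mat(
      list("density", 1050, "kg/m^3"),
      list("perfusion_rate", 0.0048, "1/s"),
      list("heat_capacity", 3640, "J kg^-1 K^-1")
    ),
    cooling_water = mat(
      list("density", 1000, "kg/m^3"),
      list("heat_conductivity", 0.598, "W m^-1 K^-1"),
      list("heat_capacity", 4137, "J kg^-1 K^-1")
    ),
    polycarbonate = mat(
      list("density", 1300, "kg/m^3"),
      list("heat_conductivity", 0.341, "W m^-1 K^-1"),
      list("heat_capacity", 2300, "J kg^-1 K^-1")
    ),
    damage = mat(
      list("rate_constant_A", 3.1e98, "s^-1"),
      list("activation_energy_Ea", 6.28e5, "J mol^-1"),
      list("gas_constant_R", 8.31, "J mol^-1 K^-1")
    )
  )
}

#' @rdname material_library
#' @param material one element of [material_library()].
#' @param parameter parameter name within the material.
#' @export
material_si <- function(material, parameter) {
  i <- match(parameter, material$parameter)
  if (is.na(i)) {
    stop("unknown material parameter: '", parameter, "'", call. = FALSE)
  }
  to_si(material$value[i], material$unit[i])
}

#' Load a simulation configuration
#'
#' Reads a structured configuration (YAML or JSON file path, or an
#' equivalent nested list) with sections `tissue_optical`, `tissue_thermal`,
#' `blood`, `damage`, `applicator`, `laser`, `grid`, `solver` and `output`,
#' normalizes every quantity to SI, and fills unspecified fields from the
#' material library for the configured wavelength. Quantities may be given
#' as bare SI numbers or as `"value unit"` strings such as `"0.5 cm^-1"`.
#'
#' @param config file path or nested list; `NULL` gives all defaults.
#' @return a list with elements `optical` ([optical_properties()]),
#'   `thermal` ([thermal_properties()]), `damage` ([damage_parameters()]),
#'   `applicator` ([applicator_spec()]), `wavelength`, `grid`, `solver`,
#'   `output` (grid/solver/output as plain SI lists).
#' @examples
#' p <- load_parameters(list(laser = list(wavelength = "980nm")))
#' p$optical$mu_a # 90 m^-1, the 980 nm library default
#' @export
load_parameters <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  config <- config %||% list()
  stopifnot(is.list(config))
  get_q <- function(section, field, default) {
    x <- config[[section]][[field]]
    if (is.null(x)) default else parse_quantity(x, paste(section, field))
  }

  laser <- config$laser %||% list()
  wavelength <- as.character(laser$wavelength %||% "1064nm")
  wavelength <- sub("^(\\d+)\\s*nm$", "\\1nm", tolower(wavelength))
  if (!wavelength %in% c("1064nm", "980nm")) {
    stop("laser wavelength must be '1064nm' or '980nm'", call. = FALSE)
  }
  op_def <- brain_optics(wavelength)
  optical <- optical_properties(
    mu_a = get_q("tissue_optical", "absorption", op_def$mu_a),
    mu_s = get_q("tissue_optical", "scattering", op_def$mu_s),
    g = get_q("tissue_optical", "anisotropy", op_def$g),
    wavelength_label = wavelength
  )

  lib <- material_library()
  thermal <- thermal_properties(
    rho = get_q("tissue_thermal", "density", 1040),
    c = get_q("tissue_thermal", "heat_capacity", 3590),
    k = get_q("tissue_thermal", "heat_conductivity", 0.503),
    rho_b = get_q("blood", "density", 1050),
    c_b = get_q("blood", "heat_capacity", 3640),
    omega_b = get_q("blood", "perfusion_rate", 0.0048),
    T_b = get_q("blood", "arterial_temperature", 37)
  )
  damage <- damage_parameters(
    A = get_q("damage", "rate_constant", 3.1e98),
    Ea = get_q("damage", "activation_energy", 6.28e5),
    R = get_q("damage", "gas_constant", 8.31),
    omega_threshold = get_q("damage", "threshold", 1)
  )
  applicator <- applicator_spec(
    L1 = get_q("applicator", "diffuser_length", 0.010),
    D1 = get_q("applicator", "catheter_diameter", 0.00155),
    coolant_wall_temperature =
      get_q("applicator", "coolant_wall_temperature", 25),
    power = get_q("laser", "power", 10),
    duration = get_q("laser", "duration", 120)
  )
  grid <- list(
    spacing = get_q("grid", "spacing", 2e-4),
    domain_radius = get_q("grid", "domain_radius", 0.040),
    domain_halflength = get_q("grid", "domain_halflength", 0.040),
    resolve_wall = isTRUE(config$grid$resolve_wall %||% TRUE)
  )
  solver <- list(
    optics = match.arg(config$solver$optics %||% "p1", c("p1", "mc")),
    dt = get_q("solver", "dt", 0.25),
    scheme = match.arg(config$solver$scheme %||% "backward",
                       c("backward", "crank-nicolson")),
    cooldown = get_q("solver", "cooldown", 600),
    snapshot_interval = get_q("solver", "snapshot_interval", 2),
    photons = get_q("solver", "photons", 1e6),
    seed = as.integer(config$solver$seed %||% 1L)
  )
  list(optical = optical, thermal = thermal, damage = damage,
       applicator = applicator, wavelength = wavelength,
       grid = grid, solver = solver,
       output = config$output %||% list())
}

#' @export
print.optical_properties <- function(x, ...) {
  cat("Optical properties (", x$wavelength_label, ")\n", sep = "")
  cat(sprintf("  mu_a = %g m^-1, mu_s = %g m^-1, g = %g\n",
              x$mu_a, x$mu_s, x$g))
  cat(sprintf("  mu_s' = %g m^-1, D = %.4g m, mu_eff = %.4g m^-1\n",
              x$mu_s * (1 - x$g), diffusion_coefficient(x), mu_eff(x)))
  invisible(x)
}

#' @export
print.applicator_spec <- function(x, ...) {
  cat(sprintf(
    "Applicator: L1 = %g mm, D1 = %g mm, wall %g degC, %g W for %g s\n",
    x$L1 * 1e3, x$D1 * 1e3, x$coolant_wall_temperature, x$power, x$duration))
  invisible(x)
}
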