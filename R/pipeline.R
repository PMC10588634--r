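#' Run a complete ablation simulation
#'
#' Orchestrates configuration, grid construction, optics (P1 by default;
#' Monte Carlo on request), the Pennes bioheat solve over irradiation plus
#' post-laser cool-down, Arrhenius damage integration and ablation-boundary
#' extraction. Damage accumulated during the default 10-minute cool-down is
#' included (set `cooldown: 0` in the solver section to disable). With an
#' output directory the run writes the radial fluence and temperature
#' profiles, the ablation contour, an ablation report JSON and a
#' reproducibility manifest (configuration snapshot, seeds, per-stage
#' wall-clock, output checksums). Reruns with the same configuration and
#' seed are identical.
#'
#' @param config configuration for [load_parameters()] (path, list or
#'   `NULL` for defaults).
#' @param output_dir directory for output files, or `NULL` to skip writing.
#' @param seed overrides the solver-section seed for the Monte Carlo
#'   optics backend.
#' @return invisible list with `params`, `grid`, `fluence`, `temperature`,
#'   `damage`, `ablation`, `report` and `manifest`.
#' @examples
#' \donttest{
#' res <- run_ablation(list(
#'   laser = list(power = 15, duration = 120),
#'   grid = list(spacing = "0.8 mm"),
#'   solver = list(dt = 1, cooldown = 60)
#' ))
#' res$ablation$diameter
#' }
#' @export
run_ablation <- function(config = NULL, output_dir = NULL, seed = NULL) {
  t_all <- proc.time()[["elapsed"]]
  params <- load_parameters(config)
  if (!is.null(seed)) params$solver$seed <- as.integer(seed)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  grid <- build_grid(params$applicator,
                     domain_radius = params$grid$domain_radius,
                     domain_halflength = params$grid$domain_halflength,
                     spacing = params$grid$spacing,
                     resolve_wall = params$grid$resolve_wall)
  timings["grid_s"] <- tic() - t0

  t0 <- tic()
  fluence <- if (params$solver$optics == "mc") {
    launch_photons(photon_batch(n_photons = params$solver$photons,
                                seed = params$solver$seed),
                   params$optical, params$applicator, grid)
  } else {
    solve_p1(grid, params$optical, params$applicator)
  }
  timings["optics_s"] <- tic() - t0

  t0 <- tic()
  duration <- params$applicator$duration
  t_end <- duration + params$solver$cooldown
  temperature <- solve_pennes(
    grid, params$thermal, source = fluence,
    applicator = params$applicator,
    t_end = max(t_end, params$solver$dt), dt = params$solver$dt,
    laser_off_time = duration,
    snapshot_times = seq(0, max(t_end, params$solver$dt),
                         by = max(params$solver$snapshot_interval,
                                  params$solver$dt)),
    scheme = params$solver$scheme
  )
  timings["bioheat_s"] <- tic() - t0

  t0 <- tic()
  damage <- integrate_arrhenius(temperature, params$damage)
  ablation <- ablation_boundary(damage, grid)
  timings["damage_s"] <- tic() - t0

  report <- list(
    diameter_mm = ablation$diameter,
    volume_mm3 = ablation$volume,
    threshold = ablation$threshold,
    wavelength = params$wavelength,
    power_W = params$applicator$power,
    duration_s = duration,
    cooldown_s = params$solver$cooldown,
    optics_backend = params$solver$optics,
    peak_temperature_C = max(temperature$T[, , dim(temperature$T)[3]],
                             na.rm = TRUE)
  )
  timings["total_s"] <- tic() - t_all

  manifest <- NULL
  if (!is.null(output_dir)) {
    manifest <- write_run_outputs(output_dir, params, grid, fluence,
                                  temperature, damage, ablation, report,
                                  timings)
  }
  invisible(list(params = params, grid = grid, fluence = fluence,
                 temperature = temperature, damage = damage,
                 ablation = ablation, report = report,
                 manifest = manifest, timings = timings))
}

write_run_outputs <- function(output_dir, params, grid, fluence,
                              temperature, damage, ablation, report,
                              timings) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(name, fun) {
    path <- file.path(output_dir, name)
    fun(path)
    files <<- c(files, path)
    path
  }
  radii <- seq(5e-4, min(0.010, grid$domain_radius -
                           max(grid$r_out, 0, na.rm = TRUE) - 1e-3),
               by = 5e-4)
  wr("fluence_profile.csv", function(p) {
    write.csv(radial_profile(fluence, grid, 0, radii,
                             distances_from =
                               if (is.na(grid$r_out)) "axis" else "wall"),
              p, row.names = FALSE)
  })
  wr("temperature_profile.csv", function(p) {
    prof <- temperature_at_probes(
      temperature, grid,
      cbind(c(5.6e-3, 7.0e-3, 8.4e-3), 0))
    write.csv(prof, p, row.names = FALSE)
  })
  wr("ablation_contour.csv", function(p) {
    ct <- if (length(ablation$contour) > 0) {
      do.call(rbind, lapply(seq_along(ablation$contour), function(i) {
        cbind(segment = i, ablation$contour[[i]] * 1e3)
      }))
    } else {
      data.frame(segment = integer(0), r = numeric(0), z = numeric(0))
    }
    names(ct) <- c("segment", "r_mm", "z_mm")
    write.csv(ct, p, row.names = FALSE)
  })
  wr("ablation_report.json", function(p) {
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  manifest <- list(
    package_version = as.character(packageVersion("littsim")),
    config = serialize_params(params),
    seeds = list(mc = params$solver$seed),
    timings_s = as.list(timings),
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  mpath <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}

serialize_params <- function(params) {
  list(
    wavelength = params$wavelength,
    optical = unclass(params$optical),
    thermal = unclass(params$thermal),
    damage = unclass(params$damage),
    applicator = unclass(params$applicator),
    grid = params$grid,
    solver = params$solver
  )
}

#' Validate the P1 approximation against Monte Carlo
#'
#' Runs both optics solvers on diffuser setups and compares their radial
#' fluence profiles at the diffuser mid-plane, sampled from 0.5 mm to 10 mm
#' beyond the outer catheter wall at 0.5 mm intervals (Pearson correlation,
#' paired t-test, difference statistics). Default setups: a 4 mm tip at
#' 10 W and a 10 mm tip at 15 W, both with the 1064 nm brain optics and a
#' 1.55 mm catheter.
#'
#' @param setups list of [applicator_spec()]s to validate.
#' @param optics an [optical_properties()] set.
#' @param photons Monte Carlo photon count per setup.
#' @param seed Monte Carlo seed (incremented by one per setup).
#' @param spacing,domain_radius,domain_halflength grid settings (m).
#' @param radii sampling distances beyond the outer catheter wall (m).
#' @param normalize peak-normalize the profiles before comparing (default
#'   raw values).
#' @return list with one element per setup: `stats`
#'   ([compare_profiles()] result), `profile_mc`, `profile_p1`, `setup`.
#' @export
run_p1_mc_validation <- function(
    setups = list(
      applicator_spec(L1 = 0.004, D1 = 0.00155, power = 10),
      applicator_spec(L1 = 0.010, D1 = 0.00155, power = 15)
    ),
    optics = brain_optics("1064nm"),
    photons = 1e6, seed = 1,
    spacing = 2e-4, domain_radius = 0.040, domain_halflength = 0.040,
    radii = seq(5e-4, 1e-2, by = 5e-4), normalize = FALSE) {
  out <- list()
  for (k in seq_along(setups)) {
    app <- setups[[k]]
    grid <- build_grid(app, domain_radius = domain_radius,
                       domain_halflength = domain_halflength,
                       spacing = spacing)
    mc <- launch_photons(photon_batch(n_photons = photons,
                                      seed = seed + k - 1),
                         optics, app, grid)
    p1 <- solve_p1(grid, optics, app)
    pr_mc <- radial_profile(mc, grid, 0, radii)
    pr_p1 <- radial_profile(p1, grid, 0, radii)
    out[[k]] <- list(
      setup = app,
      stats = compare_profiles(pr_mc, pr_p1, normalize = normalize),
      profile_mc = pr_mc, profile_p1 = pr_p1
    )
    names(out)[k] <- sprintf("L1_%gmm_%gW", app$L1 * 1e3, app$power)
  }
  out
}

#' Export a temperature snapshot as NIfTI
#'
#' Resamples an axisymmetric temperature snapshot onto a Cartesian slice
#' through the fiber axis and writes it as a NIfTI volume (requires the
#' RNifti package).
#'
#' @param field a `temperature_field`.
#' @param grid its grid.
#' @param path output `.nii`/`.nii.gz` path.
#' @param time_index snapshot to export (default last).
#' @param pixel_size output pixel size (m).
#' @return the path, invisibly.
#' @export
export_temperature_nifti <- function(field, grid, path, time_index = NULL,
                                     pixel_size = 1e-3) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI export", call. = FALSE)
  }
  M <- field_matrix(field, time_index)
  M[is.na(M)] <- field$baseline %||% 37
  rmax <- max(grid$r)
  nx <- max(2L, floor(2 * rmax / pixel_size))
  x <- (seq_len(nx) - (nx + 1) / 2) * pixel_size
  nzp <- max(2L, floor((max(grid$z) - min(grid$z)) / pixel_size))
  zp <- (seq_len(nzp) - (nzp + 1) / 2) * pixel_size
  img <- matrix(0, nx, nzp)
  for (jz in seq_len(nzp)) {
    img[, jz] <- interp_bilinear(grid$r, grid$z, M,
                                 pmin(pmax(abs(x), min(grid$r)), rmax),
                                 rep(pmin(pmax(zp[jz], min(grid$z)),
                                          max(grid$z)), nx))
  }
  vol <- array(img, c(nx, nzp, 1))
  nii <- RNifti::asNifti(vol)
  RNifti::pixdim(nii) <- c(pixel_size * 1e3, pixel_size * 1e3, 1)
  RNifti::writeNifti(nii, path)
  invisible(path)
}
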