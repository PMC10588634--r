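#' Time-dependent Pennes bioheat solver
#'
#' Integrates \eqn{\rho c\,\partial T/\partial t = \nabla\cdot k\nabla T +
#' \rho_b c_b \omega_b (T_b - T) + Q_r} on the axisymmetric grid by a
#' flux-conservative finite-volume discretization and an implicit theta
#' scheme (backward Euler by default, Crank-Nicolson optional), so the
#' 0.2 mm default grid needs no stability-limited time step. The absorbed
#' optical power density `Q_r` is held static (one-way optics-to-thermal
#' coupling, temperature-independent properties) and switched off after
#' `laser_off_time`. Boundary conditions: isothermal cooled inner catheter
#' wall (Dirichlet, `applicator$coolant_wall_temperature`), Dirichlet
#' `outer_temperature` on the far boundaries, zero-flux symmetry on the
#' axis. The one-node polycarbonate wall layer conducts without perfusion
#' or source.
#'
#' @param grid the [build_grid()] grid.
#' @param thermal a [thermal_properties()] set.
#' @param source a `fluence_field` on the same grid (its
#'   `absorbed_density` is `Q_r`), or `NULL` for no laser source.
#' @param applicator the [applicator_spec()] used to build the grid, or
#'   `NULL`.
#' @param t_end simulation end time (s).
#' @param dt time step (s), default 0.25.
#' @param laser_off_time time (s) after which `Q_r` is zeroed; `NULL`
#'   keeps the laser on to `t_end`. A step straddling the switch uses the
#'   on-fraction of that step.
#' @param snapshot_times times (s) at which to store the field (rounded to
#'   step boundaries); default about 120 evenly spaced frames plus t = 0.
#' @param scheme `"backward"` (Euler) or `"crank-nicolson"`.
#' @param baseline initial temperature (degrees C): a scalar for a
#'   uniform start (default 37) or an `[nr, nz]` matrix.
#' @param inner_boundary,outer_boundary `"dirichlet"` (default) or
#'   `"adiabatic"`; adiabatic variants exist for conservation tests.
#' @param outer_temperature far-boundary temperature (degrees C).
#' @param conduction set `FALSE` to disable conduction (pure-perfusion
#'   verification mode).
#' @param wall_thermal optional list with `k`, `rho`, `c` for the catheter
#'   wall; defaults to the polycarbonate library values.
#' @return an object of class `temperature_field`: `times` (s), `T`
#'   (`[nr, nz, n_times]` array, degrees C) and `baseline`.
#' @export
solve_pennes <- function(grid, thermal, source = NULL, applicator = NULL,
                         t_end, dt = 0.25, laser_off_time = NULL,
                         snapshot_times = NULL,
                         scheme = c("backward", "crank-nicolson"),
                         baseline = 37,
                         inner_boundary = c("dirichlet", "adiabatic"),
                         outer_boundary = c("dirichlet", "adiabatic"),
                         outer_temperature = 37,
                         conduction = TRUE, wall_thermal = NULL) {
  scheme <- match.arg(scheme)
  inner_boundary <- match.arg(inner_boundary)
  outer_boundary <- match.arg(outer_boundary)
  check_positive(dt, "dt")
  if (t_end < dt) stop("t_end must be at least dt", call. = FALSE)
  sys <- assemble_pennes(grid, thermal, source, applicator,
                         inner_boundary, outer_boundary, outer_temperature,
                         conduction, wall_thermal)

  theta <- if (scheme == "backward") 1 else 0.5
  n_steps <- as.integer(ceiling(t_end / dt - 1e-9))
  if (is.null(snapshot_times)) {
    by <- max(dt, round(t_end / 120 / dt) * dt)
    snapshot_times <- seq(0, t_end, by = by)
  }
  rec_steps <- sort(unique(pmin(pmax(round(snapshot_times / dt), 0),
                                n_steps)))
  times <- rec_steps * dt

  Cdt <- sys$capacity / dt
  lhs <- Matrix::Diagonal(x = Cdt) + theta * sys$K
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(lhs), LDL = FALSE)

  Tn <- if (is.matrix(baseline)) {
    stopifnot(all(dim(baseline) == c(grid$nr, grid$nz)))
    baseline[sys$unknown]
  } else {
    rep(baseline, sys$n_un)
  }
  out <- array(NA_real_, c(grid$nr, grid$nz, length(rec_steps)))
  store <- function(slot, Tv) {
    M <- matrix(NA_real_, grid$nr, grid$nz)
    M[sys$unknown] <- Tv
    M[!sys$unknown] <- sys$dirichlet_values[!sys$unknown]
    out[, , slot] <<- M
  }
  slot <- 1L
  if (rec_steps[1] == 0L) {
    store(slot, Tn)
    slot <- slot + 1L
  }
  t_off <- laser_off_time %||% Inf
  for (n in seq_len(n_steps)) {
    t0 <- (n - 1) * dt
    on_frac <- if (!is.finite(t_off)) 1 else
      max(0, min(t_off, t0 + dt) - t0) / dt
    b <- sys$b_const + on_frac * sys$b_src
    rhs <- Cdt * Tn - (1 - theta) * as.numeric(sys$K %*% Tn) + b
    Tn <- as.numeric(Matrix::solve(ch, rhs))
    if (!all(is.finite(Tn))) {
      stop("solver error: non-finite temperature at t = ", n * dt,
           call. = FALSE)
    }
    if (slot <= length(rec_steps) && n == rec_steps[slot]) {
      store(slot, Tn)
      slot <- slot + 1L
    }
  }
  structure(list(times = times, T = out,
                 baseline = if (is.matrix(baseline)) mean(baseline) else
                   baseline,
                 grid = grid),
            class = "temperature_field")
}

#' Steady-state Pennes solution
#'
#' Direct solve of the stationary Pennes equation (one sparse solve), used
#' e.g. to verify the perfused point-source Green's function
#' \eqn{T - T_b = P e^{-r/\delta}/(4\pi k r)},
#' \eqn{\delta = \sqrt{k/(\rho_b c_b \omega_b)}}.
#'
#' @inheritParams solve_pennes
#' @return a `temperature_field` with a single snapshot (`times = Inf`).
#' @export
solve_pennes_steady <- function(grid, thermal, source = NULL,
                                applicator = NULL,
                                inner_boundary = c("dirichlet", "adiabatic"),
                                outer_boundary = c("dirichlet", "adiabatic"),
                                outer_temperature = 37,
                                conduction = TRUE, wall_thermal = NULL) {
  inner_boundary <- match.arg(inner_boundary)
  outer_boundary <- match.arg(outer_boundary)
  sys <- assemble_pennes(grid, thermal, source, applicator,
                         inner_boundary, outer_boundary, outer_temperature,
                         conduction, wall_thermal)
  b <- sys$b_const + sys$b_src
  Tv <- tryCatch(
    as.numeric(Matrix::solve(sys$K, b)),
    error = function(e) stop("singular steady-state system (no Dirichlet ",
                             "boundary and no perfusion?): ",
                             conditionMessage(e), call. = FALSE)
  )
  resid <- sqrt(sum((as.numeric(sys$K %*% Tv) - b)^2)) /
    max(sqrt(sum(b^2)), 1e-300)
  if (!all(is.finite(Tv)) || resid > 1e-6) {
    stop("singular steady-state system (no Dirichlet boundary and no ",
         "perfusion?)", call. = FALSE)
  }
  M <- matrix(NA_real_, grid$nr, grid$nz)
  M[sys$unknown] <- Tv
  M[!sys$unknown] <- sys$dirichlet_values[!sys$unknown]
  structure(list(times = Inf, T = array(M, c(grid$nr, grid$nz, 1)),
                 baseline = NA_real_, grid = grid),
            class = "temperature_field")
}

# Build the stiffness matrix (conduction + perfusion sink), capacity vector
# and constant/source load vectors over the unknown nodes.
assemble_pennes <- function(grid, thermal, source, applicator,
                            inner_boundary, outer_boundary,
                            outer_temperature, conduction, wall_thermal) {
  stopifnot(inherits(grid, "axisym_grid"),
            inherits(thermal, "thermal_properties"))
  if (!is.null(source)) {
    Q <- if (inherits(source, "fluence_field")) {
      source$absorbed_density # Q_r = mu_a * phi, W m^-3
    } else {
      field_matrix(source)
    }
    if (!all(dim(Q) == c(grid$nr, grid$nz))) {
      stop("source field grid does not match the thermal grid",
           call. = FALSE)
    }
  } else {
    Q <- matrix(0, grid$nr, grid$nz)
  }
  wall <- wall_thermal %||% list(k = 0.341, rho = 1300, c = 2300)

  region_r <- grid$region[, 1]
  k_r <- ifelse(region_r == "tissue", thermal$k, wall$k)
  rhoc_r <- ifelse(region_r == "tissue", thermal$rho * thermal$c,
                   wall$rho * wall$c)
  is_tis_r <- region_r == "tissue"

  nr <- grid$nr
  nz <- grid$nz
  dirichlet <- matrix(FALSE, nr, nz)
  dval <- matrix(NA_real_, nr, nz)
  if (inner_boundary == "dirichlet" &&
      any(region_r == "coolant_boundary")) {
    iw <- which(region_r == "coolant_boundary")
    tw <- if (!is.null(applicator)) {
      applicator$coolant_wall_temperature
    } else {
      25
    }
    dirichlet[iw, ] <- TRUE
    dval[iw, ] <- tw
  }
  if (outer_boundary == "dirichlet") {
    dirichlet[nr, ] <- TRUE
    dval[nr, ] <- outer_temperature
    dirichlet[, 1] <- TRUE
    dval[, 1] <- outer_temperature
    dirichlet[, nz] <- TRUE
    dval[, nz] <- outer_temperature
    # a cooled-wall Dirichlet wins at shared nodes
    if (inner_boundary == "dirichlet" &&
        any(region_r == "coolant_boundary")) {
      dval[which(region_r == "coolant_boundary"), c(1, nz)] <-
        if (!is.null(applicator)) applicator$coolant_wall_temperature else 25
    }
  }
  unknown <- !dirichlet
  umap <- matrix(NA_integer_, nr, nz)
  umap[unknown] <- seq_len(sum(unknown))
  n_un <- sum(unknown)

  V <- grid$volumes
  dzf <- diff(grid$z_faces)
  rf <- grid$r_faces
  ring <- pi * diff(rf^2)
  perf <- perfusion_heat_sink_coefficient(thermal)

  ii <- jj <- xx <- list()
  nlist <- 0L
  push <- function(a, b, v) {
    nlist <<- nlist + 1L
    ii[[nlist]] <<- a; jj[[nlist]] <<- b; xx[[nlist]] <<- v
  }
  diag_add <- numeric(n_un)
  b_const <- numeric(n_un)
  add_diag <- function(k, v) {
    s <- rowsum(v, k)
    r <- as.integer(rownames(s))
    diag_add[r] <<- diag_add[r] + s
  }

  link <- function(ia, ja, ib, jb, G) {
    ka <- umap[cbind(ia, ja)]
    kb <- umap[cbind(ib, jb)]
    both <- !is.na(ka) & !is.na(kb)
    if (any(both)) {
      push(ka[both], kb[both], -G[both])
      push(kb[both], ka[both], -G[both])
      add_diag(ka[both], G[both])
      add_diag(kb[both], G[both])
    }
    a_only <- !is.na(ka) & is.na(kb)
    if (any(a_only)) {
      add_diag(ka[a_only], G[a_only])
      s <- rowsum(G[a_only] * dval[cbind(ib, jb)][a_only], ka[a_only])
      r <- as.integer(rownames(s))
      b_const[r] <<- b_const[r] + s
    }
    b_only <- is.na(ka) & !is.na(kb)
    if (any(b_only)) {
      add_diag(kb[b_only], G[b_only])
      s <- rowsum(G[b_only] * dval[cbind(ia, ja)][b_only], kb[b_only])
      r <- as.integer(rownames(s))
      b_const[r] <<- b_const[r] + s
    }
  }

  if (conduction) {
    i <- rep(1:(nr - 1), nz)
    j <- rep(1:nz, each = nr - 1)
    fr <- rf[i + 1]
    A <- 2 * pi * fr * dzf[j]
    d1 <- fr - grid$r[i]
    d2 <- grid$r[i + 1] - fr
    G <- A / (d1 / k_r[i] + d2 / k_r[i + 1])
    link(i, j, i + 1L, j, G)

    i <- rep(1:nr, nz - 1)
    j <- rep(1:(nz - 1), each = nr)
    G <- k_r[i] * ring[i] / (grid$z[j + 1] - grid$z[j])
    link(i, j, i, j + 1L, G)
  }

  # perfusion sink and laser source on tissue nodes
  all_i <- rep(1:nr, nz)
  all_j <- rep(1:nz, each = nr)
  ku <- umap[cbind(all_i, all_j)]
  tis <- is_tis_r[all_i] & !is.na(ku)
  if (perf > 0 && any(tis)) {
    pv <- perf * V[cbind(all_i, all_j)][tis]
    add_diag(ku[tis], pv)
    s <- rowsum(pv * thermal$T_b, ku[tis])
    r <- as.integer(rownames(s))
    b_const[r] <- b_const[r] + s
  }
  b_src <- numeric(n_un)
  if (any(tis)) {
    qv <- Q[cbind(all_i, all_j)][tis] * V[cbind(all_i, all_j)][tis]
    s <- rowsum(qv, ku[tis])
    r <- as.integer(rownames(s))
    b_src[r] <- b_src[r] + s
  }

  K <- Matrix::sparseMatrix(
    i = c(unlist(ii), 1:n_un), j = c(unlist(jj), 1:n_un),
    x = c(unlist(xx), diag_add), dims = c(n_un, n_un)
  )
  capacity <- (rhoc_r[all_i] * V[cbind(all_i, all_j)])[!is.na(ku)][
    order(ku[!is.na(ku)])]
  list(K = K, capacity = capacity, b_const = b_const, b_src = b_src,
       unknown = unknown, dirichlet_values = dval, n_un = n_un)
}

#' Temperature time-courses at probe locations
#'
#' Bilinear interpolation of a [solve_pennes()] temperature field at fixed
#' (r, z) probe positions for every stored snapshot. Distances are from the
#' fiber axis, so a probe "at d mm from the fiber centre on the mid-plane"
#' is `c(d, 0)`.
#'
#' @param field a `temperature_field`.
#' @param grid the grid it was computed on.
#' @param probes a 2-column matrix or list of `c(r, z)` positions (m).
#' @return data frame: column `time` (s) plus one `T_<k>` column per probe
#'   (degrees C), probes in the order given.
#' @export
temperature_at_probes <- function(field, grid, probes) {
  stopifnot(inherits(field, "temperature_field"),
            inherits(grid, "axisym_grid"))
  if (is.list(probes)) probes <- do.call(rbind, probes)
  probes <- matrix(as.numeric(probes), ncol = 2)
  out <- data.frame(time = field$times)
  for (k in seq_len(nrow(probes))) {
    out[[paste0("T_", k)]] <- vapply(
      seq_along(field$times),
      function(s) interp_bilinear(grid$r, grid$z, field$T[, , s],
                                  probes[k, 1], probes[k, 2]),
      0
    )
  }
  attr(out, "probes") <- probes
  out
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf(
    "Temperature field: %d snapshot(s), t in [%g, %g] s, baseline %g degC\n",
    length(x$times), min(x$times), max(x$times), x$baseline))
  cat(sprintf("  final range [%.2f, %.2f] degC\n",
              min(x$T[, , dim(x$T)[3]]), max(x$T[, , dim(x$T)[3]])))
  invisible(x)
}
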