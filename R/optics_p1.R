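#' Diffusion coefficient and effective attenuation of the P1 approximation
#'
#' `diffusion_coefficient()` returns
#' \eqn{D = 1 / (3 (\mu_a + \mu_s (1 - g)))} (m);
#' `mu_eff()` returns the effective attenuation coefficient
#' \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s (1 - g))} = \sqrt{\mu_a/D}}
#' (m^-1) that governs the far-field fluence decay.
#'
#' @param optics an [optical_properties()] object, or any list with fields
#'   `mu_a`, `mu_s`, `g` (so limiting cases such as `g = 1` can be
#'   evaluated).
#' @return scalar D in metres / mu_eff in m^-1.
#' @examples
#' diffusion_coefficient(brain_optics("1064nm")) # 5.376e-4 m
#' @export
diffusion_coefficient <- function(optics) {
  mu_tr <- optics$mu_a + optics$mu_s * (1 - optics$g)
  if (mu_tr <= 0) {
    stop("singular optics: mu_a + mu_s (1 - g) must be positive",
         call. = FALSE)
  }
  1 / (3 * mu_tr)
}

#' @rdname diffusion_coefficient
#' @export
mu_eff <- function(optics) {
  sqrt(optics$mu_a / diffusion_coefficient(optics))
}

#' Solve the P1 (diffusion) approximation for the fluence rate
#'
#' Solves \eqn{-\nabla\cdot D\nabla\phi + \mu_a \phi = 0} by a
#' flux-conservative finite-volume discretization on the axisymmetric grid
#' (symmetric positive-definite system, one direct sparse solve). Light
#' enters the tissue through the diffuser surface as a prescribed net
#' influx of `power / (pi * D1 * L1)` over `|z| <= L1/2`, so exactly
#' `power` watts are injected regardless of the tissue albedo. The far
#' boundaries carry the zero-incident Marshak (partial-current)
#' condition. By default the catheter surface is reflecting
#' (`catheter = "transparent"`), the diffusive-limit analogue of the
#' transparent lumen that the Monte Carlo solver lets photons cross;
#' `catheter = "absorbing"` instead applies the zero-incident Marshak
#' loss on the non-diffuser catheter surface, mirroring
#' `lumen = "terminate"` transport. In both cases
#' `absorbed + escaped + returned = power` to solver precision and the
#' absorbed power never exceeds the source power.
#'
#' @param grid the [build_grid()] grid.
#' @param optics an [optical_properties()] set.
#' @param applicator an [applicator_spec()] (supplies the diffuser geometry
#'   and power); `NULL` with `source = "point"`.
#' @param source `"diffuser"` (default) or `"point"`: an isotropic point
#'   source at the origin on a full-cylinder grid, the verification harness
#'   against the infinite-medium Green's function
#'   \eqn{\phi = P e^{-\mu_{eff} r} / (4 \pi D r)}.
#' @param power source power (W) for `source = "point"`; for the diffuser
#'   the applicator power is used.
#' @param catheter `"transparent"` (reflecting wall, default) or
#'   `"absorbing"` (Marshak loss on the non-diffuser wall).
#' @return a `fluence_field` with `phi >= 0`, `absorbed_density = mu_a*phi`,
#'   the power ledger, and the relative linear-system residual
#'   `residual_norm`.
#' @export
solve_p1 <- function(grid, optics, applicator = NULL,
                     source = c("diffuser", "point"), power = 1,
                     catheter = c("transparent", "absorbing")) {
  stopifnot(inherits(grid, "axisym_grid"),
            inherits(optics, "optical_properties"))
  source <- match.arg(source)
  catheter <- match.arg(catheter)
  D <- diffusion_coefficient(optics)

  if (source == "diffuser") {
    stopifnot(inherits(applicator, "applicator_spec"))
    if (is.na(grid$r_out)) {
      stop("diffuser source requires a grid built with the applicator",
           call. = FALSE)
    }
    power <- applicator$power
  } else if (!is.na(grid$r_out)) {
    stop("point source requires a full-cylinder grid (applicator = NULL)",
         call. = FALSE)
  }
  check_positive(power, "power", strict = FALSE)

  it <- grid$i_first_tissue:grid$nr
  nrt <- length(it)
  nz <- grid$nz
  rt <- grid$r[it]
  rf <- grid$r_faces[it[1] + 0:nrt] # nrt + 1 tissue faces
  dzf <- diff(grid$z_faces)
  V <- grid$volumes[it, , drop = FALSE]
  ring <- pi * diff(rf^2) # axial face areas per radial node

  idx <- function(i, j) (j - 1L) * nrt + i
  n_un <- nrt * nz

  ii <- jj <- xx <- list()
  push <- function(a, b, v) {
    k <- length(ii) + 1L
    ii[[k]] <<- a; jj[[k]] <<- b; xx[[k]] <<- v
  }

  diag_v <- as.vector(optics$mu_a * V) # absorption
  rhs <- numeric(n_un)

  # radial links
  i <- rep(1:(nrt - 1), nz)
  j <- rep(1:nz, each = nrt - 1)
  G <- D * 2 * pi * rf[i + 1] * dzf[j] / (rt[i + 1] - rt[i])
  a <- idx(i, j); b <- idx(i + 1L, j)
  push(a, b, -G); push(b, a, -G)
  diag_add <- numeric(n_un)
  tapply_add <- function(target, at, v) {
    s <- rowsum(v, at)
    target[as.integer(rownames(s))] <- target[as.integer(rownames(s))] + s
    target
  }
  diag_add <- tapply_add(diag_add, a, G)
  diag_add <- tapply_add(diag_add, b, G)

  # axial links
  i <- rep(1:nrt, nz - 1)
  j <- rep(1:(nz - 1), each = nrt)
  G <- D * ring[i] / (grid$z[j + 1] - grid$z[j])
  a <- idx(i, j); b <- idx(i, j + 1L)
  push(a, b, -G); push(b, a, -G)
  diag_add <- tapply_add(diag_add, a, G)
  diag_add <- tapply_add(diag_add, b, G)

  # Marshak boundary faces: leakage phi/2 per unit area
  jz <- 1:nz
  A_leak <- numeric(nz)
  if (!is.na(grid$r_out)) {
    if (catheter == "absorbing") A_leak <- 2 * pi * grid$r_out * dzf
    if (source == "diffuser") {
      # prescribed net influx power/(pi*D1*L1) over the diffuser span, so
      # exactly `power` enters the tissue
      dsc <- diffuser_surface_cells(grid, applicator)
      q_in <- power / (pi * applicator$D1 * applicator$L1)
      rhs[idx(rep(1L, nrow(dsc)), dsc$iz)] <- q_in * dsc$area
      A_leak[dsc$iz] <- pmax(A_leak[dsc$iz] - dsc$area, 0)
    }
    if (any(A_leak > 0)) {
      k <- idx(rep(1L, nz), jz)
      diag_add[k] <- diag_add[k] + A_leak / 2
    }
  }
  A_out <- 2 * pi * grid$domain_radius * dzf
  k <- idx(rep(nrt, nz), jz)
  diag_add[k] <- diag_add[k] + A_out / 2
  ir <- 1:nrt
  k <- idx(ir, rep(1L, nrt))
  diag_add[k] <- diag_add[k] + ring / 2
  k <- idx(ir, rep(nz, nrt))
  diag_add[k] <- diag_add[k] + ring / 2

  if (source == "point") {
    j0 <- which.min(abs(grid$z))
    rhs[idx(1L, j0)] <- power
  }

  dtot <- diag_v + diag_add
  A_mat <- Matrix::sparseMatrix(
    i = c(unlist(ii), 1:n_un), j = c(unlist(jj), 1:n_un),
    x = c(unlist(xx), dtot), dims = c(n_un, n_un)
  )
  phi_v <- as.numeric(Matrix::solve(A_mat, rhs))
  resid <- sqrt(sum((as.numeric(A_mat %*% phi_v) - rhs)^2))
  rhs_n <- sqrt(sum(rhs^2))

  phi_t <- matrix(phi_v, nrt, nz)
  phi <- matrix(0, grid$nr, grid$nz)
  phi[it, ] <- phi_t

  absorbed <- sum(optics$mu_a * phi_t * V)
  escaped <- sum(A_out / 2 * phi_t[nrt, ]) +
    sum(ring / 2 * phi_t[, 1]) + sum(ring / 2 * phi_t[, nz])
  returned <- if (!is.na(grid$r_out)) sum(A_leak / 2 * phi_t[1, ]) else 0

  fluence_field(
    phi = phi, mu_a = optics$mu_a, power = power, method = "p1",
    grid = grid,
    absorbed_power = absorbed, escaped_power = escaped,
    returned_power = returned,
    residual_norm = if (rhs_n > 0) resid / rhs_n else resid,
    diffusion_D = D
  )
}

#' Compare two aligned profiles
#'
#' Pearson correlation (with p-value), two-sided paired t-test p-value, and
#' the standard deviation and median of the point differences `b - a`, for
#' two equal-length profiles sampled at the same positions -- the statistics
#' used to compare P1 against Monte Carlo fluence profiles and simulated
#' against measured temperature time-courses.
#'
#' @param a,b numeric vectors, or data frames with a `value` column
#'   (e.g. from [radial_profile()]).
#' @param normalize if `TRUE`, peak-normalize each profile before
#'   comparison; default `FALSE` (raw values).
#' @return an object of class `comparison_stats` with fields `pearson_r`,
#'   `pearson_p`, `paired_t_p`, `n_points`, `diff_std`, `diff_median`.
#' @export
compare_profiles <- function(a, b, normalize = FALSE) {
  va <- if (is.data.frame(a)) a$value else as.numeric(a)
  vb <- if (is.data.frame(b)) b$value else as.numeric(b)
  if (length(va) != length(vb)) {
    stop("profiles have different lengths", call. = FALSE)
  }
  if (length(va) < 3) {
    stop("need at least 3 aligned points", call. = FALSE)
  }
  if (normalize) {
    va <- va / max(va)
    vb <- vb / max(vb)
  }
  if (sd(va) == 0 || sd(vb) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- cor.test(va, vb)
  d <- vb - va
  t_p <- if (sd(d) == 0) {
    if (all(d == 0)) 1 else 0
  } else {
    t.test(vb, va, paired = TRUE)$p.value
  }
  structure(list(pearson_r = unname(ct$estimate),
                 pearson_p = ct$p.value,
                 paired_t_p = t_p,
                 n_points = length(va),
                 diff_std = sd(d),
                 diff_median = median(d)),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf(
    "Profile comparison (n = %d): r = %.4f (p = %.3g), paired t p = %.3g\n",
    x$n_points, x$pearson_r, x$pearson_p, x$paired_t_p))
  cat(sprintf("  difference std = %.4g, median = %.4g\n",
              x$diff_std, x$diff_median))
  invisible(x)
}
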