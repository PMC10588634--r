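#' Photon batch settings for the Monte Carlo solver
#'
#' @param n_photons number of photon packets (>= 1).
#' @param seed RNG seed for the transport kernel (deterministic: the same
#'   seed reproduces the tallies bit-identically).
#' @param weight_threshold Russian-roulette weight threshold.
#' @param survival_probability roulette survival chance in (0, 1);
#'   survivors are reweighted by its inverse so energy is conserved in
#'   expectation.
#' @return an object of class `photon_batch`.
#' @export
photon_batch <- function(n_photons = 1e6, seed = 1,
                         weight_threshold = 1e-4,
                         survival_probability = 0.1) {
  if (!is.numeric(n_photons) || n_photons < 1) {
    stop("n_photons must be >= 1", call. = FALSE)
  }
  if (survival_probability <= 0 || survival_probability >= 1) {
    stop("survival_probability must lie in (0, 1)", call. = FALSE)
  }
  check_positive(weight_threshold, "weight_threshold")
  structure(list(n_photons = floor(n_photons), seed = seed,
                 weight_threshold = weight_threshold,
                 survival_probability = survival_probability),
            class = "photon_batch")
}

#' Sample the Henyey-Greenstein phase function
#'
#' Closed-form inverse-CDF sample of the scattering deflection cosine for
#' anisotropy `g`; `g = 0` reduces to isotropic scattering
#' (`cos_theta = 2u - 1`) and the sample mean equals `g`.
#'
#' @param g anisotropy factor, 0 <= g < 1.
#' @param u uniform variates in `[0, 1)`.
#' @return `cos(theta)` values in `[-1, 1]`.
#' @export
sample_henyey_greenstein <- function(g, u) {
  if (!is.numeric(g) || length(g) != 1L || is.na(g) || g < 0 || g >= 1) {
    stop("g must satisfy 0 <= g < 1", call. = FALSE)
  }
  stopifnot(all(u >= 0 & u <= 1))
  if (g < 1e-8) {
    return(2 * u - 1)
  }
  t <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(pmax((1 + g^2 - t^2) / (2 * g), -1), 1)
}

#' Monte Carlo photon transport
#'
#' Launches weighted photon packets from the diffuser surface (uniform
#' position on the cylinder `r = D1/2`, `|z| <= L1/2`, Lambertian outward
#' angles) into homogeneous tissue and tallies the fluence rate on the grid
#' with a collision estimator. Photon steps are exponential with mean
#' `1/(mu_a + mu_s)`; implicit capture deposits the absorbed weight fraction
#' at each collision and Russian roulette terminates low-weight packets.
#' The catheter is treated as index-matched and transparent, with no
#' Fresnel reflection anywhere: by default photons re-entering the lumen
#' cross it without interaction and continue on the far side
#' (`lumen = "transmit"`; a water-filled 1.55 mm lumen transmits nearly
#' all crossing light at these wavelengths). `lumen = "terminate"`
#' instead kills such photons and tallies them as returned power, which
#' discards several percent of the source power -- more at 1064 nm than
#' at 980 nm, enough to distort wavelength comparisons.
#'
#' Energy is conserved by construction:
#' `absorbed + escaped (+ returned) = power` up to roulette noise.
#'
#' @param batch a [photon_batch()].
#' @param optics an [optical_properties()] set.
#' @param applicator an [applicator_spec()]; ignored for `source = "point"`.
#' @param grid the [build_grid()] grid (built with `applicator`, or a full
#'   cylinder for the point source).
#' @param source `"diffuser"` (default) or `"point"`: an isotropic point
#'   source of the same power at the origin, the verification harness for
#'   the infinite-medium diffusion Green's function.
#' @param n_batches photon sub-batches used for the per-cell standard error
#'   estimate.
#' @param lumen `"transmit"` (default) or `"terminate"`: what happens to
#'   photons whose free path re-enters the catheter lumen.
#' @return a `fluence_field` with elements `phi` (W m^-2 per node),
#'   `absorbed_density` (`mu_a * phi`, W m^-3), `mc_stderr`, and the power
#'   ledger `absorbed_power`, `escaped_power`, `returned_power` (W).
#' @export
launch_photons <- function(batch, optics, applicator, grid,
                           source = c("diffuser", "point"),
                           n_batches = 10L,
                           lumen = c("transmit", "terminate")) {
  stopifnot(inherits(batch, "photon_batch"),
            inherits(optics, "optical_properties"),
            inherits(grid, "axisym_grid"))
  source <- match.arg(source)
  lumen <- match.arg(lumen)
  if (optics$mu_a + optics$mu_s <= 0) {
    stop("mu_a + mu_s must be positive", call. = FALSE)
  }

  if (source == "diffuser") {
    stopifnot(inherits(applicator, "applicator_spec"))
    if (is.na(grid$r_out)) {
      stop("diffuser source requires a grid built with the applicator",
           call. = FALSE)
    }
    it <- grid$i_first_tissue:grid$nr
    r_anchor <- grid$r_out
    src_radius <- grid$r_out
    src_halflen <- applicator$L1 / 2
    power <- applicator$power
    mode <- 0L
  } else {
    if (!is.na(grid$r_out)) {
      stop("point source requires a full-cylinder grid (applicator = NULL)",
           call. = FALSE)
    }
    it <- seq_len(grid$nr)
    r_anchor <- 0
    src_radius <- 0
    src_halflen <- 0
    power <- if (!is.null(applicator)) applicator$power else 1
    mode <- 1L
  }

  n <- batch$n_photons
  n_batches <- as.integer(n_batches)
  res <- mc_transport_cpp(
    n_photons = n, mu_a = optics$mu_a, mu_s = optics$mu_s, g = optics$g,
    source_mode = mode, src_radius = src_radius, src_halflen = src_halflen,
    r_anchor = r_anchor, dr = grid$dr_tissue, nr = length(it),
    z_half = grid$domain_halflength, dz = grid$dz, nz = grid$nz,
    r_max = grid$domain_radius,
    w_threshold = batch$weight_threshold,
    p_survive = batch$survival_probability,
    n_batches = n_batches, seed = as.numeric(batch$seed),
    lumen_mode = if (lumen == "terminate") 1L else 0L
  )

  V <- grid$volumes[it, , drop = FALSE]
  tot <- apply(res$tally, c(1, 2), sum)
  phi_t <- power * tot / (n * V)
  # standard error across sub-batch estimates of phi
  nb <- n_batches
  per_batch_scale <- power * nb / n
  m1 <- tot / nb
  m2 <- apply(res$tally^2, c(1, 2), sum) / nb
  sd_b <- sqrt(pmax(m2 - m1^2, 0) * nb / (nb - 1))
  stderr_t <- per_batch_scale * sd_b / V / sqrt(nb)

  phi <- matrix(0, grid$nr, grid$nz)
  se <- matrix(0, grid$nr, grid$nz)
  phi[it, ] <- phi_t
  se[it, ] <- stderr_t

  fluence_field(
    phi = phi, mu_a = optics$mu_a, power = power, method = "mc",
    grid = grid,
    mc_stderr = se,
    absorbed_power = power * sum(res$absorbed) / n,
    escaped_power = power * sum(res$escaped) / n,
    returned_power = power * sum(res$returned) / n,
    n_photons = n, seed = batch$seed
  )
}
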