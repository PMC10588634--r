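test_that("Henyey-Greenstein sampling has the right limits and moments", {
  u <- seq(0, 0.999, length.out = 200)
  # isotropic limit
  expect_equal(sample_henyey_greenstein(0, u), 2 * u - 1)
  # closed form stays inside the cosine domain for extreme anisotropy
  expect_true(all(abs(sample_henyey_greenstein(0.99, c(0, u, 1))) <= 1))
  # sample mean equals g (E[cos theta] = g)
  set.seed(42)
  n <- 1e6
  draws <- sample_henyey_greenstein(0.9, runif(n))
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - 0.9), 3 * se)
  expect_error(sample_henyey_greenstein(1.2, 0.5), "g must")
})

test_that("photon batch settings are validated", {
  expect_error(photon_batch(n_photons = 0), "n_photons")
  expect_error(photon_batch(survival_probability = 1), "survival")
  expect_error(
    launch_photons(photon_batch(100),
                   optical_properties(mu_a = 1e-12, mu_s = 0),
                   fix_applicator(), fix_grid_coarse()),
    NA
  ) # tiny but positive mu_t is legal
})

test_that("Monte Carlo transport conserves energy and is deterministic", {
  app <- fix_applicator(L1 = 0.004, power = 10)
  g <- build_grid(app, domain_radius = 0.025, domain_halflength = 0.025,
                  spacing = 4e-4)
  b <- photon_batch(5e4, seed = 13)
  f1 <- launch_photons(b, fix_optics_1064(), app, g)
  # ledger closes to the launched power
  total <- f1$absorbed_power + f1$escaped_power + f1$returned_power
  expect_lt(abs(total - app$power) / app$power, 0.005)
  # absorbed density is mu_a * phi pointwise, and phi >= 0
  expect_true(all(f1$phi >= 0))
  expect_equal(f1$absorbed_density, fix_optics_1064()$mu_a * f1$phi)
  # same seed, same tallies
  f2 <- launch_photons(b, fix_optics_1064(), app, g)
  expect_identical(f1$phi, f2$phi)
  # different seed differs
  f3 <- launch_photons(photon_batch(5e4, seed = 14), fix_optics_1064(),
                       app, g)
  expect_false(identical(f1$phi, f3$phi))
})

test_that("far-field fluence decays at the effective attenuation rate", {
  op <- fix_optics_1064()
  app <- fix_applicator(L1 = 0.004, power = 10)
  g <- build_grid(app, domain_radius = 0.03, domain_halflength = 0.03,
                  spacing = 4e-4)
  f <- launch_photons(photon_batch(2e5, seed = 3), op, app, g)
  rr <- seq(0.006, 0.014, by = 0.001)
  pr <- radial_profile(f, g, 0, rr, distances_from = "axis")
  # exp(-mu_eff r)/r decay: fit the log of r * phi
  slope <- unname(coef(lm(log(pr$value * pr$radius) ~ pr$radius))[2])
  expect_lt(abs(slope + mu_eff(op)) / mu_eff(op), 0.10)
  # profile decreases monotonically away from the diffuser mid-plane
  full <- radial_profile(f, g, 0, seq(1e-3, 2e-2, 1e-3),
                         distances_from = "wall")
  expect_true(all(diff(full$value) < 0))
})

test_that("point-source tallies match the diffusion Green's function", {
  op <- fix_optics_1064()
  g <- fix_grid_cylinder(radius = 0.02, half = 0.02, spacing = 4e-4)
  f <- launch_photons(photon_batch(1.5e5, seed = 7), op, NULL, g,
                      source = "point")
  for (rc in seq(0.002, 0.010, by = 0.002)) {
    num <- shell_average(f$phi, g, rc, 2e-4)
    expect_lt(abs(num / green_fluence(rc, op) - 1), 0.10)
  }
})

test_that("standard error shrinks like one over root n", {
  op <- fix_optics_1064()
  app <- fix_applicator(L1 = 0.004, power = 10)
  g <- build_grid(app, domain_radius = 0.02, domain_halflength = 0.02,
                  spacing = 8e-4)
  f1 <- launch_photons(photon_batch(4e4, seed = 5), op, app, g)
  f4 <- launch_photons(photon_batch(1.6e5, seed = 5), op, app, g)
  sel <- f1$phi > 0 & f4$phi > 0 & f1$mc_stderr > 0 & f4$mc_stderr > 0
  ratio <- median(f1$mc_stderr[sel] / f4$mc_stderr[sel])
  expect_lt(abs(ratio - 2), 0.4) # 1/sqrt(n): quadrupling halves the error
})

test_that("tallies are invariant under batch splitting", {
  op <- fix_optics_1064()
  app <- fix_applicator(L1 = 0.004, power = 10)
  g <- build_grid(app, domain_radius = 0.02, domain_halflength = 0.02,
                  spacing = 8e-4)
  full <- launch_photons(photon_batch(1e5, seed = 21), op, app, g)
  h1 <- launch_photons(photon_batch(5e4, seed = 22), op, app, g)
  h2 <- launch_photons(photon_batch(5e4, seed = 23), op, app, g)
  avg <- (h1$phi + h2$phi) / 2
  rr <- seq(1e-3, 8e-3, by = 1e-3)
  pa <- littsim:::interp_bilinear(g$r, g$z, avg, rr + g$r_out, rr * 0)
  pf <- radial_profile(full, g, 0, rr)$value
  sef <- littsim:::interp_bilinear(g$r, g$z, full$mc_stderr, rr + g$r_out,
                                   rr * 0)
  expect_true(all(abs(pa - pf) < 5 * pmax(sef, 1e-9)))
  # absorbed power agrees within a percent between the two estimates
  expect_lt(abs((h1$absorbed_power + h2$absorbed_power) / 2 -
                  full$absorbed_power) / full$absorbed_power, 0.01)
})

test_that("lumen transmission recovers power the terminate mode loses", {
  op <- fix_optics_1064()
  app <- fix_applicator(L1 = 0.010, power = 15)
  g <- build_grid(app, domain_radius = 0.025, domain_halflength = 0.025,
                  spacing = 4e-4)
  ft <- launch_photons(photon_batch(5e4, seed = 9), op, app, g,
                       lumen = "transmit")
  fk <- launch_photons(photon_batch(5e4, seed = 9), op, app, g,
                       lumen = "terminate")
  expect_lt(ft$returned_power, 0.01 * app$power)
  expect_gt(fk$returned_power, 0.03 * app$power)
  expect_gt(ft$absorbed_power, fk$absorbed_power)
})
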