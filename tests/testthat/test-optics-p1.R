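test_that("diffusion coefficient follows 1/(3(mu_a + mu_s(1-g)))", {
  expect_equal(diffusion_coefficient(fix_optics_1064()),
               1 / (3 * (50 + 5700 * 0.1))) # 5.376e-4 m
  expect_equal(diffusion_coefficient(fix_optics_980()),
               1 / (3 * (90 + 7800 * 0.05))) # 6.944e-4 m
  # forward-peaked limit of the formula
  expect_equal(diffusion_coefficient(list(mu_a = 40, mu_s = 9000, g = 1)),
               1 / (3 * 40))
  expect_error(diffusion_coefficient(list(mu_a = 0, mu_s = 100, g = 1)),
               "singular")
  expect_equal(mu_eff(fix_optics_1064()), sqrt(3 * 50 * (50 + 570)))
})

test_that("P1 solution is linear in power and zero without a source", {
  app0 <- applicator_spec(L1 = 0.004, power = 0)
  g <- build_grid(app0, domain_radius = 0.02, domain_halflength = 0.02,
                  spacing = 4e-4)
  f0 <- solve_p1(g, fix_optics_1064(), app0)
  expect_true(all(f0$phi == 0))
  app1 <- applicator_spec(L1 = 0.004, power = 10)
  app2 <- applicator_spec(L1 = 0.004, power = 20)
  f1 <- solve_p1(g, fix_optics_1064(), app1)
  f2 <- solve_p1(g, fix_optics_1064(), app2)
  expect_equal(f2$phi, 2 * f1$phi, tolerance = 1e-12)
})

test_that("P1 satisfies the discrete equation and conserves power", {
  app <- fix_applicator(L1 = 0.010, power = 15)
  g <- build_grid(app, domain_radius = 0.03, domain_halflength = 0.03,
                  spacing = 4e-4)
  f <- solve_p1(g, fix_optics_1064(), app)
  expect_lt(f$residual_norm, 1e-8)
  expect_true(all(f$phi >= 0))
  balance <- f$absorbed_power + f$escaped_power + f$returned_power
  expect_equal(balance, app$power, tolerance = 1e-8)
  expect_lte(f$absorbed_power, app$power)
  # monotone radial decay at the mid-plane
  pr <- radial_profile(f, g, 0, seq(5e-4, 2e-2, 5e-4))
  expect_true(all(diff(pr$value) < 0))
})

test_that("P1 point source reproduces the diffusion Green's function", {
  op <- fix_optics_1064()
  g <- fix_grid_cylinder(radius = 0.02, half = 0.02, spacing = 2e-4)
  f <- solve_p1(g, op, source = "point", power = 1)
  rr <- seq(0.002, 0.010, by = 0.001)
  pr <- radial_profile(f, g, 0, rr, distances_from = "axis")
  expect_true(all(abs(pr$value / green_fluence(rr, op) - 1) < 0.05))
})

test_that("P1 fluence converges under grid refinement", {
  app <- fix_applicator(L1 = 0.004, power = 10)
  phi5 <- vapply(c(4e-4, 2e-4), function(h) {
    g <- build_grid(app, domain_radius = 0.025, domain_halflength = 0.025,
                    spacing = h)
    radial_profile(solve_p1(g, fix_optics_1064(), app), g, 0, 5e-3)$value
  }, 0)
  expect_lt(abs(phi5[2] / phi5[1] - 1), 0.02)
})

test_that("profile comparison statistics behave as designed", {
  a <- c(5, 4, 3, 2, 1.5)
  s_id <- compare_profiles(a, a)
  expect_equal(s_id$pearson_r, 1)
  expect_equal(s_id$diff_std, 0)
  expect_equal(s_id$diff_median, 0)
  expect_equal(s_id$paired_t_p, 1)
  # a constant offset keeps r = 1 and shows up in the median
  s_off <- compare_profiles(a, a + 2.5)
  expect_equal(s_off$pearson_r, 1)
  expect_equal(s_off$diff_median, 2.5)
  expect_equal(s_off$diff_std, 0)
  # normalization mode rescales peaks to one
  s_n <- compare_profiles(a, 3 * a, normalize = TRUE)
  expect_equal(s_n$diff_median, 0)
  expect_error(compare_profiles(a, a[-1]), "length")
  expect_error(compare_profiles(a[1:2], a[1:2]), "at least 3")
  expect_error(compare_profiles(rep(1, 5), a), "zero variance")
})

test_that("radial profile interpolation honours nodes and bounds", {
  app <- fix_applicator()
  g <- build_grid(app, domain_radius = 0.02, domain_halflength = 0.02,
                  spacing = 4e-4)
  f <- solve_p1(g, fix_optics_1064(), app)
  # a node radius returns the node value exactly
  i <- g$i_first_tissue + 5L
  j0 <- which.min(abs(g$z))
  pr <- radial_profile(f, g, 0, g$r[i] - g$r_out)
  expect_identical(pr$value, f$phi[i, j0])
  expect_identical(nrow(radial_profile(f, g, 0, numeric(0))), 0L)
  expect_error(radial_profile(f, g, 0, 0.05), "beyond")
})
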