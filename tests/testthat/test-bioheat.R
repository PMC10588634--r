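test_that("uniform body temperature is a steady state without a source", {
  g <- fix_grid_cylinder(radius = 0.01, half = 0.01, spacing = 1e-3)
  f <- solve_pennes(g, fix_thermal(), t_end = 20, dt = 1,
                    snapshot_times = c(0, 10, 20))
  expect_true(all(abs(f$T - 37) < 1e-9))
})

test_that("pure perfusion decay matches the closed-form exponential", {
  th <- fix_thermal()
  g <- fix_grid_cylinder(radius = 0.005, half = 0.005, spacing = 1e-3)
  f <- solve_pennes(g, th, t_end = 60, dt = 0.25,
                    scheme = "crank-nicolson", baseline = 47,
                    outer_boundary = "adiabatic", conduction = FALSE,
                    snapshot_times = c(0, 60))
  lam <- perfusion_heat_sink_coefficient(th) / (th$rho * th$c)
  expected <- 37 + 10 * exp(-lam * 60) # 44.447 degC
  expect_equal(f$T[3, 3, 2], expected, tolerance = 1e-6)
  # backward Euler converges to the same value as dt shrinks
  fb <- solve_pennes(g, th, t_end = 60, dt = 0.05, baseline = 47,
                     outer_boundary = "adiabatic", conduction = FALSE,
                     snapshot_times = c(0, 60))
  expect_equal(fb$T[3, 3, 2], expected, tolerance = 1e-4)
})

test_that("steady point source matches the perfused Green's function", {
  th <- fix_thermal()
  g <- fix_grid_cylinder(radius = 0.028, half = 0.028, spacing = 4e-4)
  Q <- matrix(0, g$nr, g$nz)
  j0 <- which.min(abs(g$z))
  Q[1, j0] <- 1 / g$volumes[1, j0] # 1 W point source on the axis
  st <- solve_pennes_steady(g, th, source = make_source(g, Q))
  delta <- sqrt(th$k / perfusion_heat_sink_coefficient(th))
  expect_equal(delta, 5.236e-3, tolerance = 1e-3)
  for (rc in seq(0.002, 0.010, by = 0.002)) {
    num <- littsim:::interp_bilinear(g$r, g$z, st$T[, , 1], rc, 0) - 37
    ana <- exp(-rc / delta) / (4 * pi * th$k * rc)
    expect_lt(abs(num / ana - 1), 0.05)
  }
})

test_that("solver obeys the maximum principle without a source", {
  app <- fix_applicator()
  g <- fix_grid_coarse(app, spacing = 4e-4, radius = 0.02, half = 0.02)
  f <- solve_pennes(g, fix_thermal(), applicator = app, t_end = 30,
                    dt = 0.5, snapshot_times = c(0, 10, 30))
  expect_true(all(f$T >= 25 - 1e-9, na.rm = TRUE))
  expect_true(all(f$T <= 37 + 1e-9, na.rm = TRUE))
})

test_that("discrete energy balance holds with adiabatic boundaries", {
  th <- fix_thermal()
  g <- fix_grid_cylinder(radius = 0.01, half = 0.01, spacing = 5e-4)
  # non-uniform start exercises internal conduction, which must net to zero
  T0 <- 37 + 15 * exp(-outer(g$r^2, g$z^2, "+") / 2e-5)
  f <- solve_pennes(g, th, t_end = 2, dt = 0.5, baseline = T0,
                    outer_boundary = "adiabatic",
                    snapshot_times = seq(0, 2, 0.5))
  C <- th$rho * th$c * g$volumes
  P <- perfusion_heat_sink_coefficient(th) * g$volumes
  for (s in 2:length(f$times)) {
    dH <- sum(C * (f$T[, , s] - f$T[, , s - 1]))
    exch <- sum(P * (37 - f$T[, , s])) * (f$times[s] - f$times[s - 1])
    expect_lt(abs(dH - exch) / abs(exch), 0.005)
  }
})

test_that("time-step refinement changes the peak temperature little", {
  app <- fix_applicator(L1 = 0.004, power = 10)
  g <- fix_grid_coarse(app, spacing = 8e-4, radius = 0.025, half = 0.025)
  src <- solve_p1(g, fix_optics_1064(), app)
  peak <- vapply(c(1, 0.5), function(dt) {
    f <- solve_pennes(g, fix_thermal(), src, app, t_end = 120, dt = dt,
                      snapshot_times = c(0, 120))
    max(f$T[, , 2], na.rm = TRUE)
  }, 0)
  expect_lt(abs(peak[2] / peak[1] - 1), 0.005)
})

test_that("coupled heating is fastest at the centre and decelerates", {
  app <- fix_applicator(L1 = 0.010, power = 15)
  g <- fix_grid_coarse(app, spacing = 4e-4, radius = 0.03, half = 0.03)
  src <- solve_p1(g, fix_optics_1064(), app)
  f <- solve_pennes(g, fix_thermal(), src, app, t_end = 120, dt = 0.5,
                    snapshot_times = seq(0, 120, 30))
  pr <- temperature_at_probes(f, g, cbind(c(2e-3, 5.6e-3, 8.4e-3), 0))
  # the centre outruns the periphery at all times
  expect_true(all(pr$T_1[-1] > pr$T_2[-1]))
  expect_true(all(pr$T_2[-1] > pr$T_3[-1]))
  # peripheral heating decelerates towards 120 s
  early <- pr$T_2[pr$time == 60] - pr$T_2[pr$time == 30]
  late <- pr$T_2[pr$time == 120] - pr$T_2[pr$time == 90]
  expect_lt(late, early)
})

test_that("probes interpolate exactly at nodes and reject outsiders", {
  g <- fix_grid_cylinder(radius = 0.01, half = 0.01, spacing = 1e-3)
  f <- solve_pennes(g, fix_thermal(), t_end = 4, dt = 1, baseline = 41,
                    outer_boundary = "adiabatic",
                    snapshot_times = c(0, 2, 4))
  pr <- temperature_at_probes(f, g, cbind(g$r[4], g$z[6]))
  expect_equal(pr$T_1, f$T[4, 6, ])
  # constant-in-space field gives a constant series per snapshot
  expect_equal(length(unique(round(pr$T_1 - f$T[2, 2, ], 12))), 1L)
  expect_error(temperature_at_probes(f, g, cbind(0.5, 0)), "outside")
})

test_that("solver rejects bad inputs", {
  g <- fix_grid_cylinder(radius = 0.01, half = 0.01, spacing = 1e-3)
  g2 <- fix_grid_cylinder(radius = 0.01, half = 0.01, spacing = 5e-4)
  src <- make_source(g2, matrix(1, g2$nr, g2$nz))
  expect_error(solve_pennes(g, fix_thermal(), src, t_end = 1), "match")
  expect_error(solve_pennes(g, fix_thermal(), t_end = 0.1, dt = 0.25),
               "at least dt")
  Q1 <- matrix(1e5, g$nr, g$nz) # heated, insulated, unperfused: no steady state
  expect_error(
    solve_pennes_steady(g, thermal_properties(omega_b = 0),
                        source = make_source(g, Q1),
                        outer_boundary = "adiabatic"),
    "singular"
  )
})
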