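test_that("PRF conversion slope and inversion match the closed form", {
  canine <- prf_settings(TE = 7e-3)
  expect_equal(phase_slope(canine),
               2 * pi * -1e-8 * 42.58e6 * 3 * 7e-3) # -0.056183 rad/degC
  expect_equal(phase_to_temperature(0, canine), 0)
  expect_equal(phase_to_temperature(-0.56183, canine), 10.00,
               tolerance = 1e-4)
  human <- prf_settings(TE = 12e-3)
  expect_equal(abs(phase_slope(human)), 0.096314, tolerance = 1e-5)
  # exact inverse pair
  dT <- seq(-5, 60, by = 0.7)
  expect_equal(phase_to_temperature(temperature_to_phase(dT, canine),
                                    canine), dT, tolerance = 1e-12)
  expect_error(prf_settings(TE = 0), "positive")
  expect_error(prf_settings(alpha = 0), "nonzero")
})

test_that("phase series convert to temperature against the baseline", {
  s <- prf_settings(TE = 7e-3, n_baseline_frames = 5)
  nb <- 5
  # identical frames: temperature is the 37 degC baseline everywhere
  ph <- array(0.3, c(4, 4, nb + 3)) # common offset in every frame
  ser <- mrt_series(seq(0, by = 6, length.out = nb + 3), ph, 1.46e-3)
  out <- series_to_temperature(ser, s)
  expect_true(all(abs(out$T - 37) < 1e-12))
  # a phase ramp of one slope-unit per frame heats 1 degC per frame
  ph2 <- ph
  for (k in seq_len(3)) {
    ph2[, , nb + k] <- 0.3 + k * phase_slope(s)
  }
  ser2 <- mrt_series(seq(0, by = 6, length.out = nb + 3), ph2, 1.46e-3)
  out2 <- series_to_temperature(ser2, s)
  expect_equal(out2$T[1, 1, ], 37 + 1:3, tolerance = 1e-12)
  expect_error(
    series_to_temperature(
      mrt_series(1:4, array(0, c(2, 2, 4)), 1e-3), s),
    "baseline frames"
  )
})

test_that("difference statistics summarise sim minus meas", {
  tmv <- seq(0, 114, by = 6)
  sim <- data.frame(time = tmv, value = 37 + 0.3 * tmv)
  st0 <- profile_difference_stats(sim, sim)
  expect_equal(st0$diff_std, 0)
  expect_equal(st0$diff_median, 0)
  meas <- sim
  meas$value <- sim$value - 1.39
  st <- profile_difference_stats(sim, meas)
  expect_equal(st$diff_median, 1.39)
  expect_equal(st$diff_std, 0)
  expect_equal(st$pearson_r, 1)
  # two noise-free ramps differing in slope: the median difference is the
  # difference at the middle time point
  m2 <- data.frame(time = tmv, value = 37 + 0.25 * tmv)
  st2 <- profile_difference_stats(sim, m2)
  expect_equal(st2$diff_median, 0.05 * stats::median(tmv))
  # swapping the inputs negates the median and keeps the std
  stswap <- profile_difference_stats(m2, sim)
  expect_equal(stswap$diff_median, -st2$diff_median)
  expect_equal(stswap$diff_std, st2$diff_std)
  expect_error(
    profile_difference_stats(sim, data.frame(time = 500, value = 1)),
    "common time"
  )
})

test_that("synthetic MRT series round-trips through the PRF conversion", {
  s <- prf_settings(TE = 7e-3)
  g <- fix_grid_cylinder(radius = 0.012, half = 0.012, spacing = 1e-3)
  # constant truth: exact recovery
  truth_c <- structure(list(
    times = c(6, 12), T = array(42, c(g$nr, g$nz, 2)),
    baseline = 37, grid = g), class = "temperature_field")
  ser <- synthesize_mrt(truth_c, s, noise_sigma = 0)
  expect_equal(dim(ser$phase_maps)[3], s$n_baseline_frames + 2)
  rec <- series_to_temperature(ser, s)
  expect_equal(max(abs(rec$T - 42)), 0, tolerance = 1e-12)
  # linear-in-z truth: pixel averaging is exact for affine fields
  Tz <- outer(rep(1, g$nr), 37 + 400 * g$z)
  truth_l <- structure(list(
    times = c(6, 12), T = array(Tz, c(g$nr, g$nz, 2)),
    baseline = 37, grid = g), class = "temperature_field")
  rec_l <- series_to_temperature(synthesize_mrt(truth_l, s, 0), s)
  # reconstruct the pixel z-coordinates used by the synthesizer
  nzp <- dim(rec_l$T)[2]
  zp <- (seq_len(nzp) - (nzp + 1) / 2) * ser$pixel_size
  expect_equal(rec_l$T[2, , 1], 37 + 400 * zp, tolerance = 1e-9)
})

test_that("phase noise propagates into temperature with the PRF slope", {
  s <- prf_settings(TE = 7e-3)
  g <- fix_grid_cylinder(radius = 0.012, half = 0.012, spacing = 1e-3)
  truth <- structure(list(
    times = 6, T = array(37, c(g$nr, g$nz, 1)),
    baseline = 37, grid = g), class = "temperature_field")
  sigma <- 0.056183 # one slope-unit: about 1 degC of temperature noise
  ser <- synthesize_mrt(truth, s, noise_sigma = sigma, seed = 4)
  rec <- series_to_temperature(ser, s)
  noise_sd <- sd(rec$T - 37)
  # baseline averaging inflates the per-pixel sd by sqrt(1 + 1/n_baseline)
  expected_sd <- sigma / abs(phase_slope(s)) * sqrt(1 + 1 / 5)
  expect_lt(abs(noise_sd / expected_sd - 1), 0.15)
  # reproducible for a fixed seed
  ser2 <- synthesize_mrt(truth, s, noise_sigma = sigma, seed = 4)
  expect_identical(ser$phase_maps, ser2$phase_maps)
  expect_error(synthesize_mrt(truth, s, noise_sigma = -1), "noise_sigma")
})

test_that("wrapped phases unwrap along time before conversion", {
  s <- prf_settings(TE = 7e-3, n_baseline_frames = 2)
  # a steady ramp that wraps past pi between frames
  n <- 8
  ph <- array(0, c(2, 2, n))
  for (k in seq_len(n)) ph[, , k] <- (k - 1) * 1.9
  wrapped <- littsim:::wrap_phase(ph)
  ser <- mrt_series(seq_len(n), wrapped, 1e-3, wrapped = TRUE)
  rec <- series_to_temperature(ser, s)
  kk <- 3:n # baseline mean sits at phase 0.95 rad
  expect_equal(rec$T[1, 1, ], 37 + ((kk - 1) * 1.9 - 0.95) / phase_slope(s),
               tolerance = 1e-9)
})
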