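#' PRF thermometry settings
#'
#' Constants of the proton-resonance-frequency temperature conversion
#' \eqn{\Delta T = \Delta\phi / (2\pi\, a\, \gamma\, B_0\, T_E)}. The
#' sensitivity `alpha` is signed (-0.010 ppm/degC): heating produces a
#' negative phase shift in this convention. `gamma` is the proton
#' gyromagnetic ratio in Hz/T (42.58 MHz/T).
#'
#' @param alpha temperature sensitivity coefficient (ppm per degree C).
#' @param gamma gyromagnetic ratio (Hz/T), default 42.58e6.
#' @param B0 main field strength (T), default 3.
#' @param TE echo time (s); 7 ms is the canine protocol, 12 ms the human
#'   protocol.
#' @param baseline_temperature assumed tissue temperature during the
#'   baseline frames (degrees C), default 37.
#' @param n_baseline_frames number of pre-laser baseline frames averaged
#'   for the phase reference, default 5.
#' @return an object of class `prf_settings`.
#' @examples
#' s <- prf_settings(TE = 7e-3)
#' phase_slope(s) # -0.0562 rad per degree C
#' @export
prf_settings <- function(alpha = -0.010, gamma = 42.58e6, B0 = 3.0,
                         TE = 7e-3, baseline_temperature = 37,
                         n_baseline_frames = 5L) {
  if (alpha == 0) stop("alpha must be nonzero", call. = FALSE)
  check_positive(B0, "B0")
  check_positive(TE, "TE")
  stopifnot(n_baseline_frames >= 1)
  structure(list(alpha = alpha, gamma = gamma, B0 = B0, TE = TE,
                 baseline_temperature = baseline_temperature,
                 n_baseline_frames = as.integer(n_baseline_frames)),
            class = "prf_settings")
}

#' PRF phase/temperature conversion
#'
#' `phase_slope()` returns the conversion slope
#' \eqn{2\pi a \gamma B_0 T_E} in rad per degree C (`alpha` taken in
#' absolute units, ppm = 1e-6); `phase_to_temperature()` divides a phase
#' change by it, `temperature_to_phase()` multiplies. The two conversions
#' are exact inverses.
#'
#' @param delta_phi phase change(s), radians.
#' @param delta_T temperature change(s), degrees C.
#' @param settings a [prf_settings()] object.
#' @return temperature change in degrees C (or phase in radians).
#' @export
phase_to_temperature <- function(delta_phi, settings) {
  delta_phi / phase_slope(settings)
}

#' @rdname phase_to_temperature
#' @export
temperature_to_phase <- function(delta_T, settings) {
  delta_T * phase_slope(settings)
}

#' @rdname phase_to_temperature
#' @export
phase_slope <- function(settings) {
  stopifnot(inherits(settings, "prf_settings"))
  2 * pi * settings$alpha * 1e-6 * settings$gamma * settings$B0 *
    settings$TE
}

#' Construct an MR-thermometry phase series
#'
#' Container for a dynamic phase-image series: frame times, per-frame phase
#' maps (radians, unwrapped unless noted), pixel size and the noise level
#' used to generate synthetic series.
#'
#' @param frame_times acquisition times (s), strictly increasing.
#' @param phase_maps `[nx, ny, n_frames]` array of phase (radians).
#' @param pixel_size pixel edge length (m).
#' @param noise_sigma phase noise standard deviation (radians), or `NA`.
#' @param wrapped whether phases are stored wrapped to `(-pi, pi]`.
#' @return an object of class `mrt_series`.
#' @export
mrt_series <- function(frame_times, phase_maps, pixel_size,
                       noise_sigma = NA_real_, wrapped = FALSE) {
  stopifnot(length(dim(phase_maps)) == 3,
            dim(phase_maps)[3] == length(frame_times))
  if (any(diff(frame_times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  structure(list(frame_times = frame_times, phase_maps = phase_maps,
                 pixel_size = pixel_size, noise_sigma = noise_sigma,
                 wrapped = wrapped),
            class = "mrt_series")
}

#' Convert a phase series to temperature maps
#'
#' Averages the first `n_baseline_frames` phase maps as the per-pixel
#' baseline reference, converts the phase difference of every later frame
#' to a temperature change, and adds the baseline temperature. Any phase
#' offset common to all frames cancels exactly. For `wrapped` series the
#' phase is first unwrapped along time per pixel.
#'
#' @param series an [mrt_series()].
#' @param settings a [prf_settings()].
#' @return list with `frame_times` (the post-baseline frames) and `T`
#'   (`[nx, ny, n]` temperature array, degrees C).
#' @export
series_to_temperature <- function(series, settings) {
  stopifnot(inherits(series, "mrt_series"),
            inherits(settings, "prf_settings"))
  nb <- settings$n_baseline_frames
  nf <- dim(series$phase_maps)[3]
  if (nf <= nb) {
    stop("need more frames than the ", nb, " baseline frames",
         call. = FALSE)
  }
  ph <- series$phase_maps
  if (isTRUE(series$wrapped)) {
    ph <- unwrap_time(ph)
  }
  baseline <- apply(ph[, , 1:nb, drop = FALSE], c(1, 2), mean)
  post <- (nb + 1):nf
  dT <- sweep(ph[, , post, drop = FALSE], c(1, 2), baseline, "-") /
    phase_slope(settings)
  list(frame_times = series$frame_times[post],
       T = dT + settings$baseline_temperature)
}

# temporal phase unwrap per pixel: cumulative sum of wrapped differences
unwrap_time <- function(ph) {
  nf <- dim(ph)[3]
  if (nf < 2) return(ph)
  out <- ph
  for (s in 2:nf) {
    d <- ph[, , s] - ph[, , s - 1]
    d <- (d + pi) %% (2 * pi) - pi
    out[, , s] <- out[, , s - 1] + d
  }
  out
}

wrap_phase <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Simulation-vs-measurement time-course statistics
#'
#' Standard deviation and median of the differences `sim - meas` between a
#' simulated and a measured temperature time-course, plus their Pearson
#' correlation. The measured series is linearly interpolated onto the
#' simulated time grid where the grids differ.
#'
#' @param sim,meas data frames with columns `time` and `value` (or
#'   numeric vectors on a common grid).
#' @return a `comparison_stats` object; `diff_median`/`diff_std` summarise
#'   `sim - meas` in degrees C.
#' @export
profile_difference_stats <- function(sim, meas) {
  if (!is.data.frame(sim)) sim <- data.frame(time = seq_along(sim),
                                             value = as.numeric(sim))
  if (!is.data.frame(meas)) meas <- data.frame(time = seq_along(meas),
                                               value = as.numeric(meas))
  keep <- sim$time >= min(meas$time) - 1e-9 &
    sim$time <= max(meas$time) + 1e-9
  if (sum(keep) < 2) {
    stop("fewer than 2 common time points", call. = FALSE)
  }
  m_i <- approx(meas$time, meas$value, xout = sim$time[keep])$y
  s_v <- sim$value[keep]
  d <- s_v - m_i
  r <- if (length(d) >= 3 && sd(s_v) > 0 && sd(m_i) > 0) {
    ct <- cor.test(s_v, m_i)
    list(est = unname(ct$estimate), p = ct$p.value)
  } else {
    list(est = NA_real_, p = NA_real_)
  }
  structure(list(pearson_r = r$est, pearson_p = r$p,
                 paired_t_p = if (sd(d) == 0) {
                   if (all(d == 0)) 1 else 0
                 } else {
                   t.test(s_v, m_i, paired = TRUE)$p.value
                 },
                 n_points = length(d),
                 diff_std = sd(d), diff_median = median(d)),
            class = "comparison_stats")
}

#' Synthesize an MR-thermometry series from a simulated temperature field
#'
#' Inverts the PRF conversion per pixel to produce a synthetic phase-image
#' series standing in for an in-vivo acquisition: the axisymmetric truth
#' field is resampled onto a Cartesian pixel slice through the fiber axis,
#' averaged over each pixel footprint (MR thermometry reports the average
#' temperature change over a pixel), converted to phase, prefixed with
#' `n_baseline_frames` baseline frames, and degraded with Gaussian phase
#' noise. A noise-free series round-trips through
#' [series_to_temperature()] exactly.
#'
#' @param series_truth a `temperature_field` whose snapshots are the frame
#'   acquisition times (default frame spacing in the canine protocol: 6 s).
#' @param settings a [prf_settings()].
#' @param noise_sigma Gaussian phase noise standard deviation (radians),
#'   >= 0.
#' @param seed RNG seed for the noise.
#' @param pixel_size pixel edge length (m); default 1.46 mm (210 mm field
#'   of view / 144 matrix).
#' @param frame_interval spacing assumed for the prepended baseline frames
#'   (s), default 6.
#' @param subsamples per-axis sub-samples used for the pixel-footprint
#'   average.
#' @param wrap store phases wrapped to `(-pi, pi]` (default unwrapped).
#' @return an [mrt_series()].
#' @export
synthesize_mrt <- function(series_truth, settings, noise_sigma = 0,
                           seed = 1, pixel_size = 1.46e-3,
                           frame_interval = 6, subsamples = 3L,
                           wrap = FALSE) {
  stopifnot(inherits(series_truth, "temperature_field"),
            inherits(settings, "prf_settings"))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  grid <- series_truth$grid
  nb <- settings$n_baseline_frames

  rmax <- max(grid$r)
  nx <- max(2L, floor(2 * rmax / pixel_size))
  x <- (seq_len(nx) - (nx + 1) / 2) * pixel_size
  nzp <- max(2L, floor((max(grid$z) - min(grid$z)) / pixel_size))
  zp <- (seq_len(nzp) - (nzp + 1) / 2) * pixel_size

  off <- (seq_len(subsamples) - (subsamples + 1) / 2) / subsamples *
    pixel_size
  baseT <- settings$baseline_temperature
  r_lo <- min(grid$r)
  z_rng <- range(grid$z)
  sample_frame <- function(M) {
    M0 <- M
    M0[is.na(M0)] <- baseT # unmeshed coolant shows baseline phase
    out <- matrix(baseT, nx, nzp)
    for (jz in seq_len(nzp)) {
      for (ix in seq_len(nx)) {
        pts_r <- abs(rep(x[ix] + off, times = subsamples))
        pts_z <- rep(zp[jz] + off, each = subsamples)
        ok <- pts_r <= rmax & pts_z >= z_rng[1] & pts_z <= z_rng[2]
        if (any(ok)) {
          out[ix, jz] <- mean(interp_bilinear(
            grid$r, grid$z, M0, pmax(pts_r[ok], r_lo), pts_z[ok]))
        }
      }
    }
    out
  }

  nf <- dim(series_truth$T)[3]
  frames <- array(0, c(nx, nzp, nb + nf))
  for (s in seq_len(nf)) {
    Tpix <- sample_frame(series_truth$T[, , s])
    frames[, , nb + s] <- temperature_to_phase(Tpix - baseT, settings)
  }
  set.seed(seed)
  if (noise_sigma > 0) {
    frames <- frames + array(rnorm(length(frames), sd = noise_sigma),
                             dim(frames))
  }
  if (wrap) frames <- wrap_phase(frames)
  t0 <- series_truth$times[1]
  times <- c(t0 - frame_interval * (nb:1), series_truth$times)
  mrt_series(frame_times = times, phase_maps = frames,
             pixel_size = pixel_size, noise_sigma = noise_sigma,
             wrapped = wrap)
}

#' @export
print.mrt_series <- function(x, ...) {
  d <- dim(x$phase_maps)
  cat(sprintf(
    "MRT series: %d frames of %d x %d pixels (%.2f mm), noise sd %s rad\n",
    d[3], d[1], d[2], x$pixel_size * 1e3, format(x$noise_sigma)))
  invisible(x)
}

#' @export
print.prf_settings <- function(x, ...) {
  cat(sprintf(
    "PRF settings: a = %g ppm/degC, B0 = %g T, TE = %g ms -> %.5f rad/degC\n",
    x$alpha, x$B0, x$TE * 1e3, phase_slope(x)))
  invisible(x)
}
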