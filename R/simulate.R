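#' Configuration of the synthetic HD-sEMG + torque generator
#'
#' The simulator emulates the phenomenology of a fatiguing isometric
#' contraction recorded with an HD-sEMG grid, with every ground-truth quantity
#' known by construction: a spatial Gaussian activity kernel whose centre
#' drifts along a piecewise-linear path, riding on a diffuse whole-muscle
#' activity base; band-limited stochastic carriers whose spectral centroid
#' declines linearly (the myoelectric sign of fatigue); multiplicative
#' amplitude growth; and a torque trace with ramp-hold-decline shape, rising
#' variability during the hold and an exactly constructed failure time.
#'
#' @param layout `grid_layout` (default: fused 26x5 grid, 8 mm IED).
#' @param fs EMG and torque sampling rate, Hz (default 2048).
#' @param duration_s total record length, s (default 100).
#' @param rest_s quiet rest period before the torque ramp begins, s; provides
#'   the quasi-zero reference used for SNR-based bad-channel detection.
#' @param kernel_sigma_ft,kernel_sigma_fp widths (mm) of the Gaussian activity
#'   kernel along the fiber-transverse and fiber-parallel directions.
#' @param center_path numeric matrix with columns (t_s, ft_mm, fp_mm):
#'   piecewise-linear waypoints of the activity-kernel centre. Default: a
#'   20 mm fiber-parallel drift across the grid over the whole record.
#' @param center_jitter_mm standard deviation (mm) of the stochastic wobble
#'   superimposed on the waypoint path (an Ornstein-Uhlenbeck process per
#'   coordinate); the wobble is part of the injected ground truth. Zero
#'   disables it.
#' @param center_jitter_tau_s correlation time of the wobble, s.
#' @param amp0 hotspot peak amplitude, mV RMS.
#' @param base_frac diffuse whole-muscle activity amplitude as a fraction of
#'   `amp0`; every channel carries at least this much muscle signal.
#' @param amp_slope fractional amplitude growth per second (fatigue-related
#'   envelope rise); gain is multiplied by `1 + amp_slope * t`.
#' @param f_med0 initial carrier spectral centroid, Hz.
#' @param f_med_slope centroid drift, Hz/s (negative = fatigue decline).
#' @param carrier_bw spectral width (Gaussian sigma, Hz) of the carrier bump.
#' @param noise_floor additive white measurement-noise amplitude, mV RMS.
#' @param mvt maximum voluntary torque, N*m.
#' @param target_fraction contraction target as fraction of MVT.
#' @param torque_ramp_s duration of the initial 0-to-target torque ramp.
#' @param hold_fraction fraction of the ramp-to-failure interval held at
#'   target before the terminal decline begins.
#' @param failure_time_s instant at which torque first crosses 50% of MVT on
#'   the decline (stays below thereafter).
#' @param torque_noise_cov0,torque_noise_cov_slope coefficient of variation of
#'   the hold-phase torque noise at t = 0 and its growth per second.
#' @param seed integer seed making every draw reproducible.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(layout = default_grid_layout(),
                       fs = 2048, duration_s = 100, rest_s = 3,
                       kernel_sigma_ft = 10, kernel_sigma_fp = 12,
                       center_path = NULL,
                       center_jitter_mm = 0.5, center_jitter_tau_s = 2,
                       amp0 = 1, base_frac = 0.15, amp_slope = 0.003,
                       f_med0 = 130, f_med_slope = -0.35, carrier_bw = 35,
                       noise_floor = 0.03,
                       mvt = 100, target_fraction = 0.60,
                       torque_ramp_s = 2, hold_fraction = 0.95,
                       failure_time_s = 90,
                       torque_noise_cov0 = 0.02, torque_noise_cov_slope = 8e-4,
                       seed = 1L) {
  stopifnot(inherits(layout, "grid_layout"),
            fs > 2 * 450, duration_s > 0, rest_s >= 0,
            kernel_sigma_ft > 0, kernel_sigma_fp > 0,
            amp0 > 0, base_frac >= 0, noise_floor >= 0, carrier_bw > 0,
            center_jitter_mm >= 0, center_jitter_tau_s > 0,
            f_med0 > 20, f_med0 < 450,
            mvt > 0, target_fraction > 0, target_fraction < 1,
            torque_ramp_s > 0, hold_fraction > 0, hold_fraction < 1,
            failure_time_s < duration_s,
            failure_time_s > rest_s + torque_ramp_s,
            torque_noise_cov0 >= 0)
  ft_max <- (layout$n_cols - 1) * layout$ied_ft
  fp_max <- (layout$n_rows - 1) * layout$ied_fp
  if (is.null(center_path))
    center_path <- rbind(c(0, ft_max / 2, fp_max / 2 - 10),
                         c(duration_s, ft_max / 2, fp_max / 2 + 10))
  center_path <- matrix(as.numeric(center_path), ncol = 3,
                        dimnames = list(NULL, c("t", "ft", "fp")))
  if (any(center_path[, "ft"] < 0 | center_path[, "ft"] > ft_max |
          center_path[, "fp"] < 0 | center_path[, "fp"] > fp_max))
    stop("center_path waypoints must lie inside the grid bounds")
  if (is.unsorted(center_path[, "t"]))
    stop("center_path waypoints must be time-ordered")
  structure(list(layout = layout, fs = fs, duration_s = duration_s,
                 rest_s = rest_s,
                 kernel_sigma_ft = kernel_sigma_ft,
                 kernel_sigma_fp = kernel_sigma_fp,
                 center_path = center_path,
                 center_jitter_mm = center_jitter_mm,
                 center_jitter_tau_s = center_jitter_tau_s,
                 amp0 = amp0, base_frac = base_frac, amp_slope = amp_slope,
                 f_med0 = f_med0, f_med_slope = f_med_slope,
                 carrier_bw = carrier_bw, noise_floor = noise_floor,
                 mvt = mvt, target_fraction = target_fraction,
                 torque_ramp_s = torque_ramp_s, hold_fraction = hold_fraction,
                 failure_time_s = failure_time_s,
                 torque_noise_cov0 = torque_noise_cov0,
                 torque_noise_cov_slope = torque_noise_cov_slope,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# interpolated kernel-centre position at arbitrary times
center_at <- function(cfg, t) {
  cp <- cfg$center_path
  if (nrow(cp) == 1)
    return(cbind(ft = rep(cp[1, "ft"], length(t)),
                 fp = rep(cp[1, "fp"], length(t))))
  cbind(ft = stats::approx(cp[, "t"], cp[, "ft"], t, rule = 2)$y,
        fp = stats::approx(cp[, "t"], cp[, "fp"], t, rule = 2)$y)
}

# noiseless torque profile in N*m at arbitrary times
torque_profile <- function(cfg, t) {
  target <- cfg$target_fraction * cfg$mvt
  ramp0 <- cfg$rest_s
  ramp1 <- cfg$rest_s + cfg$torque_ramp_s
  t_dec <- ramp1 + cfg$hold_fraction * (cfg$failure_time_s - ramp1)
  slope <- (0.5 * cfg$mvt - target) / (cfg$failure_time_s - t_dec)
  y <- ifelse(t < ramp0, 0,
              ifelse(t < ramp1, target * (t - ramp0) / cfg$torque_ramp_s,
                     ifelse(t <= t_dec, target, target + slope * (t - t_dec))))
  pmax(y, 0)
}

#' Simulate a synthetic HD-sEMG recording with known activity-centre path
#'
#' Each channel is `gain(t) * carrier(t) + noise_floor * white`, where the
#' gain combines the drifting Gaussian hotspot, the diffuse base activity and
#' the fatigue-related amplitude growth, all gated by the normalized torque
#' profile (no muscle signal before the ramp). Carriers are synthesized
#' independently per channel in 1-s blocks in the frequency domain as a
#' Gaussian spectral bump whose centre follows `f_med0 + f_med_slope * t`, so
#' the injected spectral centroid is known exactly. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param map_rate_hz rate at which the ground-truth centre path is sampled
#'   (default 10 Hz, matching the default envelope frame rate).
#' @return list with elements `rec` (an [emg_recording()]) and `truth`
#'   (data.frame t, ft, fp: the injected centre trajectory at map rate).
#' @export
simulate_recording <- function(cfg, map_rate_hz = 10) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  tt <- (seq_len(n) - 0.5) / cfg$fs
  map <- channel_map(cfg$layout)
  nch <- nrow(map)

  wob <- center_wobble(cfg)
  ctr <- realized_center(cfg, wob, tt)
  act <- pmin(torque_profile(cfg, tt) / (cfg$target_fraction * cfg$mvt), 1)
  growth <- (1 + cfg$amp_slope * tt) * act

  blocks <- block_bounds(n, cfg$fs)
  # the hotspot source is one shared carrier: nearby electrodes see the same
  # motor-unit activity through the volume conductor, so their amplitude
  # ratios (and hence the centroid) are stable; the diffuse base activity and
  # the measurement noise are independent per channel
  src <- synth_carrier(blocks, cfg$fs, tt, cfg$f_med0, cfg$f_med_slope,
                       cfg$carrier_bw)
  signals <- matrix(0, nrow = nch, ncol = n)
  for (ch in seq_len(nch)) {
    g <- cfg$amp0 * exp(-((map$ft[ch] - ctr[, "ft"])^2 / (2 * cfg$kernel_sigma_ft^2) +
                          (map$fp[ch] - ctr[, "fp"])^2 / (2 * cfg$kernel_sigma_fp^2)))
    base <- synth_carrier(blocks, cfg$fs, tt, cfg$f_med0, cfg$f_med_slope,
                          cfg$carrier_bw)
    signals[ch, ] <- growth * (g * src + cfg$base_frac * cfg$amp0 * base) +
      cfg$noise_floor * stats::rnorm(n)
  }

  t_map <- seq(0.5 / map_rate_hz, cfg$duration_s - 0.5 / map_rate_hz + 1e-9,
               by = 1 / map_rate_hz)
  truth <- data.frame(t = t_map, realized_center(cfg, wob, t_map))
  list(rec = emg_recording(signals, cfg$fs, cfg$layout), truth = truth)
}

# Ornstein-Uhlenbeck wobble of the kernel centre, sampled on a 4 Hz knot
# grid; returns a function-like list for later interpolation
center_wobble <- function(cfg) {
  knots <- seq(0, cfg$duration_s + 0.25, by = 0.25)
  if (cfg$center_jitter_mm == 0)
    return(list(t = knots, ft = numeric(length(knots)),
                fp = numeric(length(knots))))
  a <- exp(-0.25 / cfg$center_jitter_tau_s)
  ou <- function() {
    x <- numeric(length(knots))
    x[1] <- stats::rnorm(1)
    innov <- stats::rnorm(length(knots) - 1)
    for (i in seq_along(innov)) x[i + 1] <- a * x[i] + sqrt(1 - a^2) * innov[i]
    cfg$center_jitter_mm * x
  }
  list(t = knots, ft = ou(), fp = ou())
}

realized_center <- function(cfg, wob, t) {
  base <- center_at(cfg, t)
  ft_max <- (cfg$layout$n_cols - 1) * cfg$layout$ied_ft
  fp_max <- (cfg$layout$n_rows - 1) * cfg$layout$ied_fp
  cbind(ft = pmin(pmax(base[, "ft"] +
                         stats::approx(wob$t, wob$ft, t, rule = 2)$y, 0), ft_max),
        fp = pmin(pmax(base[, "fp"] +
                         stats::approx(wob$t, wob$fp, t, rule = 2)$y, 0), fp_max))
}

block_bounds <- function(n, fs) {
  starts <- seq(1, n, by = fs)
  cbind(start = starts, end = pmin(starts + fs - 1, n))
}

# band-limited noise with a Gaussian spectral bump; one realization over all
# blocks, unit RMS per block
synth_carrier <- function(blocks, fs, tt, f0, fslope, bw) {
  out <- numeric(length(tt))
  for (b in seq_len(nrow(blocks))) {
    i0 <- blocks[b, "start"]; i1 <- blocks[b, "end"]
    L <- i1 - i0 + 1
    fc <- f0 + fslope * mean(tt[i0:i1])
    freqs <- seq(0, fs / 2, by = fs / L)
    mag <- exp(-(freqs - fc)^2 / (4 * bw^2))   # amplitude => Gaussian power bump
    mag[freqs < 20 | freqs > 450] <- 0
    nf <- length(freqs)
    z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * mag
    full <- complex(real = numeric(L), imaginary = numeric(L))
    full[seq_len(nf)] <- z
    full[L + 2 - seq(2, nf)] <- Conj(z[seq(2, nf)])  # hermitian => real ifft
    x <- Re(stats::fft(full, inverse = TRUE)) / L
    r <- sqrt(mean(x^2))
    if (r > 0) x <- x / r
    out[i0:i1] <- x
  }
  out
}

#' Simulate the torque trace of a fatiguing contraction
#'
#' Linear ramp from zero to the target over `torque_ramp_s`, a hold at target
#' with multiplicative band-limited noise whose coefficient of variation grows
#' linearly in time, then a linear decline that crosses 50% of MVT exactly at
#' `failure_time_s` and stays below it for the rest of the record. The noise
#' is tapered out before the decline so the constructed failure time is exact.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a [torque_trace()].
#' @export
simulate_torque <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- round(cfg$duration_s * cfg$fs)
  tt <- (seq_len(n) - 0.5) / cfg$fs
  prof <- torque_profile(cfg, tt)
  ramp1 <- cfg$rest_s + cfg$torque_ramp_s
  t_dec <- ramp1 + cfg$hold_fraction * (cfg$failure_time_s - ramp1)

  # band-limited unit-variance noise: iid normals on a 4 Hz knot grid,
  # linearly interpolated (variance of the interpolant is 2/3, compensated)
  knots <- seq(0, cfg$duration_s + 0.25, by = 0.25)
  z <- stats::approx(knots, stats::rnorm(length(knots)), tt, rule = 2)$y *
    sqrt(3 / 2)
  cov_t <- cfg$torque_noise_cov0 + cfg$torque_noise_cov_slope * tt
  taper <- pmin(pmax(tt - ramp1, 0), 1) * pmin(pmax(t_dec - tt, 0), 1)
  torque <- prof * (1 + cov_t * z * taper)
  torque_trace(torque, cfg$fs, cfg$mvt, cfg$target_fraction)
}

#' Simulate a complete synthetic subject
#'
#' Convenience wrapper producing the EMG recording, torque trace and injected
#' centre-path ground truth of one subject from a single configuration.
#'
#' @inheritParams simulate_recording
#' @return list with elements `rec`, `torque`, `truth`.
#' @export
simulate_subject <- function(cfg, map_rate_hz = 10) {
  sim <- simulate_recording(cfg, map_rate_hz)
  list(rec = sim$rec, torque = simulate_torque(cfg), truth = sim$truth)
}
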