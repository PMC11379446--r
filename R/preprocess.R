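#' Filter specification for torque and EMG conditioning
#'
#' Third-order Butterworth filters applied forward-backward (zero-phase):
#' a 20-450 Hz bandpass plus a 50 Hz notch for the EMG, and a 10 Hz low-pass
#' for the torque. Zero-phase application doubles the effective order but
#' leaves event timing unshifted, which matters for centroid tracking.
#'
#' @param order Butterworth design order (3).
#' @param band EMG bandpass edges, Hz.
#' @param notch power-line notch frequency, Hz (NULL disables).
#' @param notch_q notch quality factor.
#' @param torque_lowpass torque low-pass cutoff, Hz.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(order = 3, band = c(20, 450), notch = 50, notch_q = 30,
                        torque_lowpass = 10) {
  stopifnot(order >= 1, length(band) == 2, band[1] > 0, band[2] > band[1],
            torque_lowpass > 0)
  structure(list(order = order, band = band, notch = notch, notch_q = notch_q,
                 torque_lowpass = torque_lowpass),
            class = "filter_spec")
}

# RBJ-cookbook biquad notch; returns list(b, a)
notch_coefs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass and notch filter a multichannel EMG recording
#'
#' Applies the Butterworth bandpass and the 50 Hz notch of `spec` to every
#' channel, forward-backward (zero-phase). The DC component is rejected by
#' the 20 Hz high-pass edge.
#'
#' @param rec an [emg_recording()].
#' @param spec a [filter_spec()].
#' @return filtered `emg_recording` of the same shape.
#' @export
filter_emg <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "emg_recording"), inherits(spec, "filter_spec"))
  if (spec$band[2] >= rec$fs / 2)
    stop("bandpass upper edge ", spec$band[2], " Hz is not below Nyquist ",
         rec$fs / 2, " Hz")
  bp <- signal::butter(spec$order, spec$band / (rec$fs / 2), type = "pass")
  nf <- if (!is.null(spec$notch)) notch_coefs(spec$notch, rec$fs, spec$notch_q)
  out <- rec$signals
  for (ch in seq_len(nrow(out))) {
    x <- signal::filtfilt(bp, out[ch, ])
    if (!is.null(nf)) x <- signal::filtfilt(signal::Arma(b = nf$b, a = nf$a), x)
    out[ch, ] <- x
  }
  rec$signals <- out
  rec
}

#' Low-pass filter a torque trace
#'
#' 3rd-order Butterworth low-pass (default 10 Hz cutoff) applied zero-phase.
#'
#' @param tq a [torque_trace()].
#' @param spec a [filter_spec()].
#' @return filtered `torque_trace`.
#' @export
filter_torque <- function(tq, spec = filter_spec()) {
  stopifnot(inherits(tq, "torque_trace"), inherits(spec, "filter_spec"))
  if (spec$torque_lowpass >= tq$fs / 2)
    stop("torque low-pass cutoff must be below Nyquist")
  lp <- signal::butter(spec$order, spec$torque_lowpass / (tq$fs / 2), type = "low")
  tq$torque <- signal::filtfilt(lp, tq$torque)
  tq
}

sample_times <- function(n, fs) (seq_len(n) - 0.5) / fs

window_rms <- function(x, fs, t0, t1) {
  tt <- sample_times(length(x), fs)
  idx <- tt >= t0 & tt <= t1
  if (!any(idx)) return(NA_real_)
  sqrt(mean(x[idx]^2))
}

#' Flag low-SNR channels
#'
#' Automated surrogate for manual channel inspection. When a hold-phase window
#' and a quasi-zero (rest) window are available, a channel's SNR is estimated
#' as `20*log10(RMS_hold / RMS_quiet)` and channels below `snr_floor_db` are
#' flagged. Without a quiet reference the function falls back to a robust
#' outlier rule on hold-phase channel RMS: flagged if more than 5 median
#' absolute deviations above the grid median, or below 0.2 times the median.
#' Sidecar-declared bad channels (`layout$bad`) are always included. A warning
#' is emitted when more than 20% of channels end up flagged.
#'
#' @param rec a filtered [emg_recording()].
#' @param snr_floor_db SNR threshold in dB (default 10).
#' @param hold_window,quiet_window numeric `c(start_s, end_s)`; `quiet_window
#'   = NULL` triggers the outlier fallback.
#' @return integer matrix with columns (row, col) of flagged positions; the
#'   attribute `fallback` records whether the outlier rule was used.
#' @export
detect_bad_channels <- function(rec, snr_floor_db = 10,
                                hold_window = NULL, quiet_window = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  n <- ncol(rec$signals)
  if (is.null(hold_window)) hold_window <- c(0, n / rec$fs)
  hold_rms <- apply(rec$signals, 1, window_rms, rec$fs,
                    hold_window[1], hold_window[2])
  fallback <- is.null(quiet_window)
  if (!fallback) {
    quiet_rms <- apply(rec$signals, 1, window_rms, rec$fs,
                       quiet_window[1], quiet_window[2])
    snr_db <- 20 * log10(hold_rms / pmax(quiet_rms, .Machine$double.eps))
    flag <- snr_db < snr_floor_db
  } else {
    med <- stats::median(hold_rms)
    dev <- stats::mad(hold_rms)
    flag <- (hold_rms - med) > 5 * dev | hold_rms < 0.2 * med
  }
  pos <- as.matrix(rec$map[flag, c("row", "col")])
  out <- as_rc_matrix(rbind(pos, rec$layout$bad))
  if (nrow(out) > 0.2 * nrow(rec$map))
    warning(sprintf("%d of %d channels flagged bad (> 20%%)",
                    nrow(out), nrow(rec$map)))
  attr(out, "fallback") <- fallback
  out
}

#' Segment a fatiguing contraction from its torque trace
#'
#' Locates the two transient marks of the contraction -- the end of the
#' ascending ramp (first attainment of the target torque) and the failure
#' instant on the descent (first sustained drop below 50% MVT) -- then places
#' a quasi-zero window of width `quasi_zero_s` around each mark
#' (`guard_s` seconds on either side) and returns the analysis region strictly
#' between the two windows with its three segments T1, T2, T3. Manually
#' determined marks, when supplied, take precedence over the automated
#' detection.
#'
#' @param tq a low-pass filtered [torque_trace()].
#' @param quasi_zero_s width of each quasi-zero window, s.
#' @param guard_s half-width of the window around each mark, s (the window is
#'   `mark +/- guard_s`; `quasi_zero_s` must equal `2 * guard_s`).
#' @param segment_length_s length of T1/T2/T3, s.
#' @param marks optional numeric `c(ascending_s, descending_s)` overriding the
#'   automated transient detection.
#' @return an [analysis_region()] with extra fields `marks` and `windows`.
#' @export
segment_contraction <- function(tq, quasi_zero_s = 4, guard_s = 2,
                                segment_length_s = 10, marks = NULL) {
  stopifnot(inherits(tq, "torque_trace"))
  if (abs(quasi_zero_s - 2 * guard_s) > 1e-9)
    stop("quasi_zero_s must equal 2 * guard_s")
  tt <- sample_times(length(tq$torque), tq$fs)
  target <- tq$target_fraction * tq$mvt
  if (is.null(marks)) {
    up <- which(tq$torque >= 0.995 * target)
    if (!length(up)) stop("no contraction detected: torque never reaches target")
    m1 <- tt[up[1]]
    et <- endurance_time(tq, hold_onset_s = m1)
    m2 <- if (!et$censored) et$failure_s else tt[up[length(up)]]
    marks <- c(m1, m2)
  }
  if (marks[2] <= marks[1]) stop("descending mark precedes ascending mark")
  region <- analysis_region(marks[1] + guard_s, marks[2] - guard_s,
                            segment_length_s)
  region$marks <- marks
  region$windows <- rbind(ascending = marks[1] + c(-guard_s, guard_s),
                          descending = marks[2] + c(-guard_s, guard_s))
  region
}

#' Endurance time of a contraction
#'
#' Time from hold-phase onset to the first instant from which torque stays
#' below `drop_fraction * MVT` for at least `sustain_s` consecutive seconds.
#' Brief dips shorter than `sustain_s` are ignored. If the criterion is never
#' met the result is censored at end of record.
#'
#' @param tq a low-pass filtered [torque_trace()].
#' @param drop_fraction failure threshold as a fraction of MVT (default 0.5).
#' @param sustain_s minimum time below threshold, s (default 3).
#' @param hold_onset_s hold-phase onset, s; if `NULL`, detected as the first
#'   attainment of 99.5% of the target torque.
#' @return list with `endurance_s` (NA when censored), `failure_s`,
#'   `hold_onset_s`, `censored`.
#' @export
endurance_time <- function(tq, drop_fraction = 0.5, sustain_s = 3,
                           hold_onset_s = NULL) {
  stopifnot(inherits(tq, "torque_trace"))
  if (tq$mvt <= 0) stop("mvt must be positive")
  tt <- sample_times(length(tq$torque), tq$fs)
  if (is.null(hold_onset_s)) {
    up <- which(tq$torque >= 0.995 * tq$target_fraction * tq$mvt)
    if (!length(up)) stop("no contraction detected: torque never reaches target")
    hold_onset_s <- tt[up[1]]
  }
  below <- tq$torque < drop_fraction * tq$mvt & tt > hold_onset_s
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  need <- ceiling(sustain_s * tq$fs)
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit))
    return(list(endurance_s = NA_real_, failure_s = NA_real_,
                hold_onset_s = hold_onset_s, censored = TRUE))
  t_fail <- tt[starts[hit[1]]]
  list(endurance_s = t_fail - hold_onset_s, failure_s = t_fail,
       hold_onset_s = hold_onset_s, censored = FALSE)
}

#' Per-segment torque level and variability
#'
#' For each of T1/T2/T3: the mean of the MVT-normalized torque and its
#' coefficient of variation (population standard deviation over mean).
#'
#' @param tq a low-pass filtered [torque_trace()].
#' @param region an [analysis_region()].
#' @return data.frame with columns label, torque_mean, torque_cov.
#' @export
torque_segment_stats <- function(tq, region) {
  stopifnot(inherits(tq, "torque_trace"), inherits(region, "analysis_region"))
  tt <- sample_times(length(tq$torque), tq$fs)
  segs <- region$segments
  out <- lapply(seq_len(nrow(segs)), function(i) {
    x <- tq$torque[tt >= segs$start_s[i] & tt < segs$end_s[i]] / tq$mvt
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    data.frame(label = segs$label[i], torque_mean = m,
               torque_cov = if (abs(m) < 1e-9) NA_real_ else s / m)
  })
  do.call(rbind, out)
}
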