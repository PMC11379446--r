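#' RMS envelope of a multichannel recording
#'
#' Per channel: square, centered moving average of length `window_s`
#' (truncated at the record edges), square root; the smoothed RMS is then
#' sampled at `frame_rate_hz` frames per second for map construction.
#'
#' @param rec a filtered [emg_recording()].
#' @param window_s smoothing window, s (default 0.5).
#' @param frame_rate_hz output frame rate, Hz (default 10).
#' @return object of class `envelope_series`: `values` (channels x frames,
#'   mV), `t` (frame centers, s), `frame_rate`.
#' @export
rms_envelope <- function(rec, window_s = 0.5, frame_rate_hz = 10) {
  stopifnot(inherits(rec, "emg_recording"), frame_rate_hz > 0)
  n <- ncol(rec$signals)
  h <- round(window_s * rec$fs / 2)
  if (2 * h < 2) stop("window_s too short for the sampling rate")
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  cnt <- hi - lo + 1
  t_frame <- seq(0.5 / frame_rate_hz, n / rec$fs, by = 1 / frame_rate_hz)
  idx <- pmin(pmax(round(t_frame * rec$fs), 1L), n)
  vals <- matrix(0, nrow = nrow(rec$signals), ncol = length(idx))
  for (ch in seq_len(nrow(rec$signals))) {
    cs <- c(0, cumsum(rec$signals[ch, ]^2))
    ms <- (cs[hi + 1] - cs[lo]) / cnt
    vals[ch, ] <- sqrt(ms[idx])
  }
  structure(list(values = vals, t = t_frame[seq_len(ncol(vals))],
                 frame_rate = frame_rate_hz),
            class = "envelope_series")
}

#' Average instantaneous frequency (spectral centroid) per frame
#'
#' The spectrogram is estimated on non-overlapping frames of `frame_s`
#' seconds (Hann-tapered periodogram); the instantaneous frequency of a frame
#' is its power-weighted mean frequency (spectral centroid) restricted to
#' `band`. Frames with negligible in-band power yield NA.
#'
#' @param rec a filtered [emg_recording()].
#' @param frame_s frame length, s (default 0.5, no overlap).
#' @param band integration band, Hz.
#' @return object of class `spectral_series`: `aif` (channels x frames, Hz),
#'   `t` (frame centers, s), `frame_s`.
#' @export
aif_series <- function(rec, frame_s = 0.5, band = c(20, 450)) {
  stopifnot(inherits(rec, "emg_recording"))
  L <- round(frame_s * rec$fs)
  if (L < 64) stop("frame too short: needs at least 64 samples")
  n <- ncol(rec$signals)
  nfr <- floor(n / L)
  if (nfr < 1) stop("recording shorter than one frame")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))      # Hann taper
  freqs <- (seq_len(L) - 1) * rec$fs / L
  keep <- freqs >= band[1] & freqs <= band[2]
  f_in <- freqs[keep]
  aif <- matrix(NA_real_, nrow = nrow(rec$signals), ncol = nfr)
  for (fr in seq_len(nfr)) {
    blk <- t(rec$signals[, ((fr - 1) * L + 1):(fr * L), drop = FALSE]) * w
    P <- Mod(stats::mvfft(blk))^2
    P <- P[keep, , drop = FALSE]
    tot <- colSums(P)
    cen <- colSums(P * f_in) / tot
    cen[tot <= .Machine$double.eps * L] <- NA_real_
    aif[, fr] <- cen
  }
  structure(list(aif = aif, t = (seq_len(nfr) - 0.5) * frame_s,
                 frame_s = frame_s),
            class = "spectral_series")
}

#' Good-channel indices of a layout
#'
#' Channels of `channel_map(layout)` whose lattice position is neither in
#' `layout$bad` nor in `extra_bad`.
#'
#' @param layout a `grid_layout`.
#' @param extra_bad optional (row, col) matrix of additional bad positions.
#' @return integer vector of channel indices.
#' @export
good_channels <- function(layout, extra_bad = NULL) {
  map <- channel_map(layout)
  bad <- as_rc_matrix(rbind(layout$bad, as_rc_matrix(extra_bad)))
  if (!nrow(bad)) return(map$channel)
  key <- paste(map$row, map$col)
  map$channel[!(key %in% paste(bad[, 1], bad[, 2]))]
}

#' Per-segment spatial-average envelope
#'
#' Mean RMS envelope over good channels and over the frames inside each
#' segment: the grid-level amplitude index.
#'
#' @param env an [rms_envelope()] result.
#' @param region an [analysis_region()].
#' @param layout the recording's `grid_layout`.
#' @param bad optional extra (row, col) bad-channel matrix.
#' @return data.frame with columns label, envelope_mean (mV).
#' @export
envelope_segment_mean <- function(env, region, layout, bad = NULL) {
  good <- good_channels(layout, bad)
  if (!length(good)) stop("all channels flagged bad")
  segs <- region$segments
  out <- vapply(seq_len(nrow(segs)), function(i) {
    cols <- env$t >= segs$start_s[i] & env$t < segs$end_s[i]
    mean(env$values[good, cols, drop = FALSE])
  }, numeric(1))
  data.frame(label = segs$label, envelope_mean = out)
}

#' Per-segment grid-level AIF
#'
#' Frames are averaged within the segment first (per channel), then across
#' good channels; frames with undefined centroid are dropped.
#'
#' @param sp an [aif_series()] result.
#' @param region an [analysis_region()].
#' @param layout the recording's `grid_layout`.
#' @param bad optional extra (row, col) bad-channel matrix.
#' @return data.frame with columns label, aif (Hz).
#' @export
aif_segment_mean <- function(sp, region, layout, bad = NULL) {
  good <- good_channels(layout, bad)
  if (!length(good)) stop("all channels flagged bad")
  segs <- region$segments
  out <- vapply(seq_len(nrow(segs)), function(i) {
    cols <- sp$t >= segs$start_s[i] & sp$t < segs$end_s[i]
    per_ch <- rowMeans(sp$aif[good, cols, drop = FALSE], na.rm = TRUE)
    mean(per_ch, na.rm = TRUE)
  }, numeric(1))
  data.frame(label = segs$label, aif = out)
}
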