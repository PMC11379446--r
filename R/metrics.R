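#' Configuration of the trajectory metric suite
#'
#' @param reference_policy reference point for the distance (AID) family:
#'   `"baseline"` (mean RoA over the first `baseline_s` seconds of the
#'   analysis region -- the initial position of the activity centroid) or
#'   `"window_mean"` (each segment's own mean, the strict
#'   postural-sway convention).
#' @param baseline_s length of the baseline window, s.
#' @param ellipse_confidence confidence level of the ellipse area (AEZ).
#' @param circle_z one-sided z quantile of the confidence circle (ACZ);
#'   1.645 gives the 95% circle.
#' @param max_gap_s longest tolerated gap of missing frames inside a segment
#'   before its path metrics (AIP, AIV, AMZ) are invalidated; interpolating
#'   across gaps would inflate path length, so gaps are never bridged.
#' @return object of class `metric_config`.
#' @export
metric_config <- function(reference_policy = c("baseline", "window_mean"),
                          baseline_s = 1, ellipse_confidence = 0.95,
                          circle_z = 1.645, max_gap_s = 1) {
  reference_policy <- match.arg(reference_policy)
  stopifnot(ellipse_confidence > 0, ellipse_confidence < 1,
            baseline_s > 0, circle_z > 0, max_gap_s > 0)
  structure(list(reference_policy = reference_policy, baseline_s = baseline_s,
                 ellipse_confidence = ellipse_confidence, circle_z = circle_z,
                 max_gap_s = max_gap_s),
            class = "metric_config")
}

#' Extract the part of a trajectory inside a time window
#'
#' @param traj a trajectory data.frame (t, ft, fp).
#' @param start_s,end_s window bounds; frames with `start_s <= t < end_s` are
#'   kept.
#' @param drop_na drop frames whose coordinates are undefined.
#' @return trajectory data.frame.
#' @export
traj_window <- function(traj, start_s, end_s, drop_na = TRUE) {
  out <- traj[traj$t >= start_s & traj$t < end_s, , drop = FALSE]
  if (drop_na) out <- out[stats::complete.cases(out[, c("ft", "fp")]), ,
                          drop = FALSE]
  out
}

traj_duration <- function(seg) {
  if (nrow(seg) < 2) return(0)
  nrow(seg) * stats::median(diff(seg$t))
}

path_valid <- function(seg, max_gap_s) {
  nrow(seg) >= 2 && max(diff(seg$t)) <= max_gap_s
}

#' Mean activation intensity distance (AID)
#'
#' Mean distance of the centroid from a reference point: the resultant
#' (`aid`) plus the per-direction means of absolute deviations (`aid_ft`,
#' `aid_fp`). With the default baseline reference this measures displacement
#' of the RoA from its initial position.
#'
#' @param seg trajectory segment (data.frame t, ft, fp).
#' @param ref named numeric `c(ft, fp)`: the reference point, mm.
#' @return named numeric `c(aid, aid_ft, aid_fp)` in mm.
#' @export
roa_aid <- function(seg, ref) {
  if (nrow(seg) < 1 || anyNA(ref)) stop("empty segment or undefined reference")
  x <- seg$ft - ref[["ft"]]
  y <- seg$fp - ref[["fp"]]
  c(aid = mean(sqrt(x^2 + y^2)), aid_ft = mean(abs(x)), aid_fp = mean(abs(y)))
}

#' Activation intensity path (AIP)
#'
#' Total path length of the centroid trajectory over the segment: resultant
#' plus per-direction components.
#'
#' @param seg trajectory segment (missing frames already dropped).
#' @return named numeric `c(aip, aip_ft, aip_fp)` in mm.
#' @export
roa_aip <- function(seg) {
  if (nrow(seg) < 2) return(c(aip = 0, aip_ft = 0, aip_fp = 0))
  du <- diff(seg$ft)
  dv <- diff(seg$fp)
  c(aip = sum(sqrt(du^2 + dv^2)), aip_ft = sum(abs(du)), aip_fp = sum(abs(dv)))
}

#' Activation intensity velocity (AIV)
#'
#' Mean speed of the centroid: each AIP component divided by the segment
#' duration.
#'
#' @param seg trajectory segment.
#' @return named numeric `c(aiv, aiv_ft, aiv_fp)` in mm/s.
#' @export
roa_aiv <- function(seg) {
  T <- traj_duration(seg)
  if (T <= 0) stop("segment duration is zero")
  p <- roa_aip(seg)
  stats::setNames(p / T, c("aiv", "aiv_ft", "aiv_fp"))
}

#' Activation intensity spread (AIS) and per-direction statistics
#'
#' Segment means and population standard deviations of the two coordinates,
#' and their RMS combination `ais = sqrt(std_ft^2 + std_fp^2)` (the RMS
#' deviation of the centroid from its segment mean).
#'
#' @param seg trajectory segment.
#' @return named numeric `c(ais, std_ft, std_fp, avg_ft, avg_fp)`.
#' @export
roa_spread <- function(seg) {
  if (nrow(seg) < 1) stop("empty segment")
  su <- sqrt(mean((seg$ft - mean(seg$ft))^2))
  sv <- sqrt(mean((seg$fp - mean(seg$fp))^2))
  c(ais = sqrt(su^2 + sv^2), std_ft = su, std_fp = sv,
    avg_ft = mean(seg$ft), avg_fp = mean(seg$fp))
}

#' Activation ellipse zone (AEZ)
#'
#' Area of the confidence ellipse (default 95%) of the mean-centered segment
#' samples: `2 * pi * F(conf; 2, N-2) * sqrt(s_u^2 s_v^2 - s_uv^2)` with
#' sample (co)variances s. Degenerate (collinear) samples give area 0 with a
#' warning.
#'
#' @param seg trajectory segment, N >= 3 frames.
#' @param cfg a [metric_config()].
#' @return area in mm^2.
#' @export
roa_aez <- function(seg, cfg = metric_config()) {
  n <- nrow(seg)
  if (n < 3) stop("ellipse area needs at least 3 frames")
  su2 <- stats::var(seg$ft)
  sv2 <- stats::var(seg$fp)
  suv <- stats::cov(seg$ft, seg$fp)
  det <- su2 * sv2 - suv^2
  if (det <= 0) {
    warning("degenerate (collinear) trajectory; ellipse area set to 0")
    return(0)
  }
  2 * pi * stats::qf(cfg$ellipse_confidence, 2, n - 2) * sqrt(det)
}

#' Activation circle zone (ACZ)
#'
#' Area of the confidence circle: with RD the distances of the mean-centered
#' samples from the origin, radius `mean(RD) + circle_z * sd(RD)`
#' (default z = 1.645, the 95% one-sided bound).
#'
#' @param seg trajectory segment, N >= 2 frames.
#' @param cfg a [metric_config()].
#' @return area in mm^2.
#' @export
roa_acz <- function(seg, cfg = metric_config()) {
  if (nrow(seg) < 2) stop("circle area needs at least 2 frames")
  x <- seg$ft - mean(seg$ft)
  y <- seg$fp - mean(seg$fp)
  rd <- sqrt(x^2 + y^2)
  r <- mean(rd) + cfg$circle_z * stats::sd(rd)
  pi * r^2
}

#' Activation movement zone (AMZ)
#'
#' Area swept by the centroid about its segment mean per unit time (the
#' sway-area analog): `1/(2T) * sum |x[n] y[n-1] - x[n-1] y[n]|` over
#' consecutive mean-centered samples.
#'
#' @param seg trajectory segment, N >= 3 frames.
#' @return swept area rate in mm^2/s.
#' @export
roa_amz <- function(seg) {
  n <- nrow(seg)
  if (n < 3) stop("swept area needs at least 3 frames")
  T <- traj_duration(seg)
  x <- seg$ft - mean(seg$ft)
  y <- seg$fp - mean(seg$fp)
  i <- 2:n
  sum(abs(x[i] * y[i - 1] - x[i - 1] * y[i])) / (2 * T)
}

#' Displacement of the centroid between contraction start and end
#'
#' Euclidean distance between the mean centroid position over T1 and over T3.
#'
#' @param traj full-region trajectory.
#' @param region an [analysis_region()].
#' @return displacement in mm.
#' @export
roa_displacement <- function(traj, region) {
  segs <- region$segments
  s1 <- traj_window(traj, segs$start_s[segs$label == "T1"],
                    segs$end_s[segs$label == "T1"])
  s3 <- traj_window(traj, segs$start_s[segs$label == "T3"],
                    segs$end_s[segs$label == "T3"])
  if (nrow(s1) < 1 || nrow(s3) < 1) stop("T1 or T3 contains no valid frame")
  sqrt((mean(s3$ft) - mean(s1$ft))^2 + (mean(s3$fp) - mean(s1$fp))^2)
}

metric_vars <- c("torque_mean", "torque_cov", "envelope_mean", "aif",
                 "aid", "aid_fp", "aid_ft", "aip", "aip_fp", "aip_ft",
                 "aiv", "aiv_fp", "aiv_ft", "aez", "amz", "acz",
                 "ais", "std_ft", "std_fp", "avg_ft", "avg_fp")

#' All per-segment metrics of one contraction
#'
#' Evaluates every variable of the metric suite on the three 10-s segments
#' T1/T2/T3 -- torque level and variability, grid-average envelope, grid AIF,
#' and the full spatial suite on the centroid trajectory -- plus the
#' per-variable maximum across segments (the predictor used for
#' endurance-time regression) and the T1-to-T3 displacement.
#'
#' The AID family is referenced to the initial centroid position (mean over
#' the first `cfg$baseline_s` seconds of the region) under the default
#' `"baseline"` policy; the spread and area metrics are always mean-centered
#' per segment. Segments whose trajectory has a gap longer than
#' `cfg$max_gap_s` get NA path metrics.
#'
#' @param traj full-region centroid trajectory (from [roa_trajectory()]).
#' @param env an [rms_envelope()] result.
#' @param sp an [aif_series()] result.
#' @param tq the low-pass filtered [torque_trace()].
#' @param region an [analysis_region()].
#' @param layout the recording's `grid_layout`.
#' @param cfg a [metric_config()].
#' @param bad optional extra (row, col) bad-channel matrix.
#' @return list with `metrics` (data.frame, one row per segment, all
#'   variables), `maxima` (named numeric, per-variable max across segments),
#'   `displacement` (mm), `reference` (the AID reference point used).
#' @export
segment_metrics <- function(traj, env, sp, tq, region, layout,
                            cfg = metric_config(), bad = NULL) {
  stopifnot(inherits(region, "analysis_region"))
  segs <- region$segments
  tstats <- torque_segment_stats(tq, region)
  estats <- envelope_segment_mean(env, region, layout, bad)
  astats <- aif_segment_mean(sp, region, layout, bad)

  base <- traj_window(traj, region$start_s, region$start_s + cfg$baseline_s)
  if (nrow(base) < 1) stop("no valid frames in the baseline window")
  ref_base <- c(ft = mean(base$ft), fp = mean(base$fp))

  rows <- lapply(seq_len(nrow(segs)), function(i) {
    seg <- traj_window(traj, segs$start_s[i], segs$end_s[i])
    if (nrow(seg) < 3) {
      warning("segment ", segs$label[i], " has fewer than 3 valid frames")
      spatial <- stats::setNames(rep(NA_real_, 17),
                                 c("aid", "aid_ft", "aid_fp", "aip", "aip_ft",
                                   "aip_fp", "aiv", "aiv_ft", "aiv_fp", "aez",
                                   "amz", "acz", "ais", "std_ft", "std_fp",
                                   "avg_ft", "avg_fp"))
    } else {
      ref <- if (cfg$reference_policy == "baseline") ref_base
             else c(ft = mean(seg$ft), fp = mean(seg$fp))
      ok_path <- path_valid(seg, cfg$max_gap_s)
      if (!ok_path)
        warning("gap > ", cfg$max_gap_s, " s in segment ", segs$label[i],
                "; path metrics set to NA")
      p <- if (ok_path) roa_aip(seg) else c(aip = NA, aip_ft = NA, aip_fp = NA)
      v <- if (ok_path) roa_aiv(seg) else c(aiv = NA, aiv_ft = NA, aiv_fp = NA)
      z <- if (ok_path) roa_amz(seg) else NA_real_
      spatial <- c(roa_aid(seg, ref), p, v,
                   aez = roa_aez(seg, cfg), amz = z, acz = roa_acz(seg, cfg),
                   roa_spread(seg))
    }
    data.frame(label = segs$label[i],
               torque_mean = tstats$torque_mean[i],
               torque_cov = tstats$torque_cov[i],
               envelope_mean = estats$envelope_mean[i],
               aif = astats$aif[i],
               t(spatial))
  })
  metrics <- do.call(rbind, rows)
  metrics <- metrics[, c("label", metric_vars)]
  maxima <- apply(metrics[, metric_vars], 2, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  list(metrics = metrics, maxima = maxima,
       displacement = roa_displacement(traj, region),
       reference = ref_base)
}
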