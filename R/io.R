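#' Write / read a recording as delimited text plus JSON sidecar
#'
#' The canonical interchange is transparent text: a channels x samples CSV
#' (no header, one row per channel) and a JSON sidecar holding the sampling
#' and grid metadata: `{fs_hz, n_rows, n_cols, ied_fp_mm, ied_ft_mm,
#' missing: [[row, col], ...], bad: [[row, col], ...]}` (1-based lattice
#' indices).
#'
#' @param rec an [emg_recording()].
#' @param matrix_path path of the signal CSV.
#' @param sidecar_path path of the JSON sidecar.
#' @return invisibly, the two paths.
#' @export
write_recording <- function(rec, matrix_path, sidecar_path) {
  stopifnot(inherits(rec, "emg_recording"))
  utils::write.table(format_num(rec$signals), matrix_path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  lay <- rec$layout
  side <- list(fs_hz = rec$fs, n_rows = lay$n_rows, n_cols = lay$n_cols,
               ied_fp_mm = lay$ied_fp, ied_ft_mm = lay$ied_ft,
               missing = unname(lay$missing), bad = unname(lay$bad))
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(c(matrix_path, sidecar_path))
}

#' @rdname write_recording
#' @return `read_recording`: an [emg_recording()].
#' @export
read_recording <- function(matrix_path, sidecar_path) {
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  need <- c("fs_hz", "n_rows", "n_cols", "ied_fp_mm", "ied_ft_mm")
  miss <- setdiff(need, names(side))
  if (length(miss)) stop("sidecar is missing fields: ", paste(miss, collapse = ", "))
  layout <- grid_layout(side$n_rows, side$n_cols,
                        ied_fp = side$ied_fp_mm, ied_ft = side$ied_ft_mm,
                        missing = side$missing, bad = side$bad)
  sig <- as.matrix(utils::read.table(matrix_path, sep = ",", header = FALSE))
  dimnames(sig) <- NULL
  nc <- n_channels(layout)
  if (nrow(sig) != nc)
    stop(sprintf("shape mismatch: matrix is %d x %d but sidecar layout (%dx%d, %d missing) implies %d channels",
                 nrow(sig), ncol(sig), layout$n_rows, layout$n_cols,
                 nrow(layout$missing), nc))
  emg_recording(sig, side$fs_hz, layout)
}

#' Write / read a torque trace as CSV
#'
#' Two columns `time_s, torque_nm`; MVT and the target fraction travel as
#' arguments (or a header comment written by [write_torque()]).
#'
#' @param tq a [torque_trace()].
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
write_torque <- function(tq, path) {
  stopifnot(inherits(tq, "torque_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mvt_nm=%s target_fraction=%s fs_hz=%s",
                     format_num(tq$mvt), format_num(tq$target_fraction),
                     format_num(tq$fs)), con)
  writeLines("time_s,torque_nm", con)
  tt <- sample_times(length(tq$torque), tq$fs)
  writeLines(paste(format_num(tt), format_num(tq$torque), sep = ","), con)
  invisible(path)
}

#' @rdname write_torque
#' @param mvt,target_fraction metadata overriding the header comment.
#' @return `read_torque`: a [torque_trace()].
#' @export
read_torque <- function(path, mvt = NULL, target_fraction = NULL) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[0-9.eE+-]+", first))[[1]]
    meta <- stats::setNames(
      as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
    if (is.null(mvt)) mvt <- meta[["mvt_nm"]]
    if (is.null(target_fraction)) target_fraction <- meta[["target_fraction"]]
  }
  if (is.null(mvt)) stop("mvt must be given (no header metadata found)")
  if (is.null(target_fraction)) target_fraction <- 0.60
  d <- utils::read.csv(path, comment.char = "#")
  fs <- 1 / stats::median(diff(d$time_s))
  torque_trace(d$torque_nm, fs, mvt, target_fraction)
}

format_num <- function(x) {
  out <- sprintf("%.9g", x)
  dim(out) <- dim(x)
  out
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis chain with the defaults
#' used throughout: the filter bank, SNR floor for bad-channel detection,
#' segmentation windows, RoA threshold, frame rates, metric configuration and
#' test alpha levels.
#'
#' @param filters a [filter_spec()].
#' @param snr_floor_db bad-channel SNR floor, dB.
#' @param quasi_zero_s,guard_s,segment_length_s see [segment_contraction()].
#' @param threshold_fraction RoA activity threshold, see [roa()].
#' @param frame_rate_hz envelope/map frame rate, Hz.
#' @param aif_frame_s spectrogram frame, s.
#' @param metrics a [metric_config()].
#' @param gate_alpha Friedman gate for post hoc tests.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(filters = filter_spec(), snr_floor_db = 10,
                            quasi_zero_s = 4, guard_s = 2,
                            segment_length_s = 10, threshold_fraction = 0.7,
                            frame_rate_hz = 10, aif_frame_s = 0.5,
                            metrics = metric_config(), gate_alpha = 0.05) {
  structure(list(filters = filters, snr_floor_db = snr_floor_db,
                 quasi_zero_s = quasi_zero_s, guard_s = guard_s,
                 segment_length_s = segment_length_s,
                 threshold_fraction = threshold_fraction,
                 frame_rate_hz = frame_rate_hz, aif_frame_s = aif_frame_s,
                 metrics = metrics, gate_alpha = gate_alpha),
            class = "pipeline_config")
}

#' Analyse one subject end to end
#'
#' preprocess -> features -> topography -> metrics for a single recording and
#' torque trace: torque low-pass and contraction segmentation, endurance
#' time, EMG filtering and bad-channel detection (quiet reference taken
#' before the ascending quasi-zero window when available), RMS envelope and
#' AIF, amplitude maps and RoA trajectory, and the full per-segment metric
#' suite.
#'
#' @param rec an [emg_recording()].
#' @param tq a [torque_trace()].
#' @param cfg a [pipeline_config()].
#' @return list with region, endurance, bad, trajectory, metrics, maxima,
#'   displacement, envelope, aif.
#' @export
analyze_subject <- function(rec, tq, cfg = pipeline_config()) {
  tqf <- filter_torque(tq, cfg$filters)
  region <- segment_contraction(tqf, cfg$quasi_zero_s, cfg$guard_s,
                                cfg$segment_length_s)
  et <- endurance_time(tqf)
  recf <- filter_emg(rec, cfg$filters)
  quiet <- if (region$windows["ascending", 1] > 0.5)
    c(0, region$windows["ascending", 1]) else NULL
  bad <- detect_bad_channels(recf, cfg$snr_floor_db,
                             hold_window = c(region$start_s, region$end_s),
                             quiet_window = quiet)
  env <- rms_envelope(recf, frame_rate_hz = cfg$frame_rate_hz)
  sp <- aif_series(recf, frame_s = cfg$aif_frame_s, band = cfg$filters$band)
  maps <- maps_from_envelope(env, rec$layout, bad)
  traj <- roa_trajectory(maps, cfg$threshold_fraction)
  sm <- segment_metrics(traj, env, sp, tqf, region, rec$layout,
                        cfg$metrics, bad)
  list(region = region, endurance = et, bad = bad, trajectory = traj,
       metrics = sm$metrics, maxima = sm$maxima,
       displacement = sm$displacement, envelope = env, aif = sp)
}

#' Run the full multi-subject pipeline and write its artifact directory
#'
#' Runs [analyze_subject()] for every subject, then -- when at least three
#' subjects are present -- the repeated-measures battery per variable and the
#' endurance-time regression over metric maxima. Writes `metrics.csv`,
#' `maxima.csv`, `trajectory.csv`, `stats.json`, `regression.csv` and
#' `run_log.txt` (config echo, package version, config hash, findings) to
#' `out_dir`. All numeric output is formatted at 9 significant digits, so
#' reruns with identical inputs are byte-identical.
#'
#' @param subjects list of subjects, each a list with elements `rec` (an
#'   [emg_recording()]) and `torque` (a [torque_trace()]).
#' @param out_dir output directory (created if absent).
#' @param cfg a [pipeline_config()].
#' @return invisibly, the per-subject analysis list.
#' @export
run_pipeline <- function(subjects, out_dir, cfg = pipeline_config()) {
  if (!is.null(subjects$rec)) subjects <- list(subjects)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- vector("list", length(subjects))
  log <- c(sprintf("roatrack %s", as.character(utils::packageVersion("roatrack"))),
           sprintf("config_hash %s", config_hash(cfg)),
           sprintf("subjects %d", length(subjects)))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    res[[i]] <- withCallingHandlers(
      analyze_subject(s$rec, s$torque, cfg),
      warning = function(w) {
        log <<- c(log, sprintf("subject %d warning: %s", i, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    log <- c(log, sprintf("subject %d: region [%s, %s] s, endurance %s s, %d bad channels",
                          i, format_num(res[[i]]$region$start_s),
                          format_num(res[[i]]$region$end_s),
                          format_num(res[[i]]$endurance$endurance_s),
                          nrow(res[[i]]$bad)))
  }

  metrics <- do.call(rbind, lapply(seq_along(res), function(i)
    cbind(subject = i, res[[i]]$metrics)))
  write_csv9(metrics, file.path(out_dir, "metrics.csv"))

  maxima <- do.call(rbind, lapply(res, function(r)
    as.data.frame(t(r$maxima))))
  maxima <- cbind(subject = seq_along(res), maxima,
                  displacement = vapply(res, `[[`, numeric(1), "displacement"),
                  endurance_s = vapply(res, function(r)
                    r$endurance$endurance_s, numeric(1)))
  write_csv9(maxima, file.path(out_dir, "maxima.csv"))

  traj <- do.call(rbind, lapply(seq_along(res), function(i)
    cbind(subject = i, res[[i]]$trajectory,
          kind = attr(res[[i]]$trajectory, "kind"))))
  write_csv9(traj, file.path(out_dir, "trajectory.csv"))

  if (length(res) >= 3) {
    stats_out <- lapply(metric_vars, function(v) {
      tab <- do.call(rbind, lapply(res, function(r)
        stats::setNames(r$metrics[[v]], r$metrics$label)))
      if (anyNA(tab)) return(list(variable = v, skipped = "missing cells"))
      b <- stats_battery(tab, cfg$gate_alpha)
      list(variable = v, shapiro = b$shapiro,
           friedman = b$friedman[c("chi2", "df", "p", "p_exact",
                                   "kendall_w", "effect_label")],
           pairwise = b$pairwise)
    })
    names(stats_out) <- metric_vars
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = 9, pretty = TRUE,
                         na = "null")
    reg <- endurance_regression(
      maxima[, c(metric_vars, "displacement")], maxima$endurance_s)
    write_csv9(reg, file.path(out_dir, "regression.csv"))
  }
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(res)
}

write_csv9 <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], format_num)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_all(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

unclass_all <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_all) else x
}
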