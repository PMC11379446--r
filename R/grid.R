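#' Electrode grid geometry
#'
#' Describes the lattice of a high-density surface EMG (HD-sEMG) electrode
#' grid: its size, inter-electrode distances (IED) along the two anatomical
#' directions, and which lattice positions carry no physical electrode
#' (`missing`) or were flagged as low-SNR (`bad`).
#'
#' The coordinate frame puts the origin at lattice position (row 1, col 1):
#' columns run along the fiber-transverse (FT, x) direction and rows along the
#' fiber-parallel (FP, y) direction, so a 26x5 grid with 8 mm IED spans
#' 32 x 200 mm. Row 1 is taken as the cranial end and column 1 as the medial
#' edge; this orientation is a documented convention, not a measurement.
#'
#' @param n_rows,n_cols lattice size; rows are fiber-parallel, columns
#'   fiber-transverse.
#' @param ied_fp,ied_ft inter-electrode distance in mm between adjacent rows
#'   (FP) and adjacent columns (FT).
#' @param missing integer matrix with columns (row, col): lattice positions
#'   with no physical electrode.
#' @param bad integer matrix with columns (row, col): positions flagged
#'   low-SNR. May overlap `missing`.
#' @return object of class `grid_layout`.
#' @seealso [default_grid_layout()] for the fused 26x5 layout.
#' @export
grid_layout <- function(n_rows, n_cols, ied_fp = 8, ied_ft = 8,
                        missing = NULL, bad = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, ied_fp > 0, ied_ft > 0)
  missing <- as_rc_matrix(missing)
  bad <- as_rc_matrix(bad)
  for (m in list(missing, bad)) {
    if (nrow(m) &&
        (any(m[, 1] < 1 | m[, 1] > n_rows) || any(m[, 2] < 1 | m[, 2] > n_cols)))
      stop("missing/bad positions must lie on the ", n_rows, "x", n_cols, " lattice")
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 ied_fp = ied_fp, ied_ft = ied_ft,
                 missing = missing, bad = bad),
            class = "grid_layout")
}

as_rc_matrix <- function(x) {
  if (is.null(x) || length(x) == 0)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  x <- matrix(as.integer(x), ncol = 2, dimnames = list(NULL, c("row", "col")))
  unique(x)
}

#' Fused 26x5 layout of two 13x5 grids
#'
#' Two 13x5 electrode grids placed end to end along the muscle fibers are
#' analysed as one 26x5 matrix. Each constituent grid lacks one electrode in
#' its upper corner (used to mark grid orientation); by default that corner is
#' placed at the last column of the first row of each constituent grid, i.e.
#' lattice positions (1, 5) and (14, 5), leaving 128 physical channels. The
#' grid spans 200 x 32 mm at the default 8 mm IED.
#'
#' @param ied mm between adjacent electrodes (both directions).
#' @param missing override for the absent-corner positions, as a 2-column
#'   (row, col) matrix.
#' @return `grid_layout` with 26 rows, 5 columns and two missing positions.
#' @export
default_grid_layout <- function(ied = 8, missing = rbind(c(1L, 5L), c(14L, 5L))) {
  grid_layout(26, 5, ied_fp = ied, ied_ft = ied, missing = missing)
}

#' Physical coordinates of a lattice position
#'
#' @param layout a `grid_layout`.
#' @param row,col 1-based lattice indices (vectorised).
#' @return matrix with columns `ft`, `fp` in mm: `ft = (col-1)*ied_ft`,
#'   `fp = (row-1)*ied_fp`.
#' @export
coords_of <- function(layout, row, col) {
  stopifnot(inherits(layout, "grid_layout"))
  if (any(row < 1 | row > layout$n_rows | col < 1 | col > layout$n_cols) ||
      any(row != as.integer(row)) || any(col != as.integer(col)))
    stop("lattice index out of range")
  cbind(ft = (col - 1) * layout$ied_ft, fp = (row - 1) * layout$ied_fp)
}

#' Channel map of a layout
#'
#' Enumerates the physical channels row-major over the non-missing lattice
#' positions, assigning channel index, lattice position and mm coordinates.
#'
#' @param layout a `grid_layout`.
#' @return data.frame with columns channel, row, col, ft, fp.
#' @export
channel_map <- function(layout) {
  stopifnot(inherits(layout, "grid_layout"))
  pos <- expand.grid(col = seq_len(layout$n_cols), row = seq_len(layout$n_rows))
  pos <- pos[, c("row", "col")]
  if (nrow(layout$missing)) {
    key <- paste(pos$row, pos$col)
    drop <- key %in% paste(layout$missing[, 1], layout$missing[, 2])
    pos <- pos[!drop, ]
  }
  xy <- coords_of(layout, pos$row, pos$col)
  data.frame(channel = seq_len(nrow(pos)), row = pos$row, col = pos$col,
             ft = xy[, "ft"], fp = xy[, "fp"], row.names = NULL)
}

n_channels <- function(layout) layout$n_rows * layout$n_cols - nrow(layout$missing)

#' Multichannel monopolar EMG recording
#'
#' @param signals channels x samples numeric matrix (mV); channel i corresponds
#'   to row i of `channel_map(layout)`.
#' @param fs sampling rate, Hz.
#' @param layout the `grid_layout` the channels live on.
#' @return object of class `emg_recording` with fields signals, fs, layout,
#'   map (the channel map data.frame).
#' @export
emg_recording <- function(signals, fs, layout) {
  stopifnot(is.matrix(signals), is.numeric(signals), fs > 0,
            inherits(layout, "grid_layout"))
  rec <- structure(list(signals = signals, fs = fs, layout = layout,
                        map = channel_map(layout)),
                   class = "emg_recording")
  finds <- validate_recording(rec)
  if (length(finds)) stop("invalid recording: ", paste(finds, collapse = "; "))
  rec
}

#' Check an EMG recording against its type invariants
#'
#' Reports, rather than throws: one finding string per violated invariant
#' (channel count vs layout, sampling rate vs the 450 Hz bandpass edge,
#' non-finite samples). An empty character vector means the recording is
#' well formed.
#'
#' @param rec list with fields signals, fs, layout (as in [emg_recording()]).
#' @return character vector of findings (possibly empty).
#' @export
validate_recording <- function(rec) {
  finds <- character(0)
  nc <- n_channels(rec$layout)
  if (nrow(rec$signals) != nc)
    finds <- c(finds, sprintf(
      "channel count mismatch: %d signal rows but layout has %d channels",
      nrow(rec$signals), nc))
  if (rec$fs <= 2 * 450)
    finds <- c(finds, sprintf("fs %g Hz below 2 x 450 Hz bandpass edge", rec$fs))
  if (anyNA(rec$signals) || any(!is.finite(rec$signals)))
    finds <- c(finds, "non-finite samples present")
  finds
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%.1f s), grid %dx%d\n",
              nrow(x$signals), ncol(x$signals), x$fs, ncol(x$signals) / x$fs,
              x$layout$n_rows, x$layout$n_cols))
  invisible(x)
}

#' Torque trace of an isometric contraction
#'
#' @param torque torque samples, N*m.
#' @param fs sampling rate, Hz (> 20).
#' @param mvt maximum voluntary torque, N*m.
#' @param target_fraction contraction target as a fraction of MVT
#'   (default 0.60).
#' @return object of class `torque_trace`.
#' @export
torque_trace <- function(torque, fs, mvt, target_fraction = 0.60) {
  stopifnot(is.numeric(torque), fs > 20, mvt > 0,
            target_fraction > 0, target_fraction < 1)
  structure(list(torque = as.numeric(torque), fs = fs, mvt = mvt,
                 target_fraction = target_fraction),
            class = "torque_trace")
}

#' Analysis region with its three 10-second segments
#'
#' The region between the two quasi-zero windows of the contraction, with the
#' beginning / middle / end segments T1, T2, T3 used for metric averaging:
#' T1 starts at the region start, T3 ends at the region end, and T2 is centered
#' at the region midpoint.
#'
#' @param start_s,end_s region bounds in seconds.
#' @param segment_length_s segment length (default 10 s).
#' @return object of class `analysis_region` with fields start_s, end_s and a
#'   data.frame `segments` (label, start_s, end_s).
#' @export
analysis_region <- function(start_s, end_s, segment_length_s = 10) {
  stopifnot(start_s < end_s)
  len <- end_s - start_s
  if (len < segment_length_s)
    stop("no contraction region long enough for a single ",
         segment_length_s, " s segment")
  if (len < 3 * segment_length_s)
    warning("analysis region shorter than three segments; T2 overlaps T1/T3")
  mid <- (start_s + end_s) / 2
  segs <- data.frame(
    label = c("T1", "T2", "T3"),
    start_s = c(start_s, mid - segment_length_s / 2, end_s - segment_length_s),
    end_s = c(start_s + segment_length_s, mid + segment_length_s / 2, end_s))
  structure(list(start_s = start_s, end_s = end_s,
                 segment_length_s = segment_length_s, segments = segs),
            class = "analysis_region")
}
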