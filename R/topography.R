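#' Amplitude topographies from an envelope series
#'
#' One rows x cols amplitude map per envelope frame. Missing and bad lattice
#' positions are left undefined (NA), never zero: zeros would drag weighted
#' centroids toward dead electrodes.
#'
#' @param env an [rms_envelope()] result.
#' @param layout the recording's `grid_layout`.
#' @param bad optional extra (row, col) bad-channel matrix (e.g. from
#'   [detect_bad_channels()]).
#' @return list of class `activation_maps`: `maps` (list of rows x cols
#'   matrices, mV) and `t` (frame times, s).
#' @export
maps_from_envelope <- function(env, layout, bad = NULL) {
  stopifnot(inherits(env, "envelope_series"), inherits(layout, "grid_layout"))
  map <- channel_map(layout)
  good <- good_channels(layout, bad)
  template <- matrix(NA_real_, nrow = layout$n_rows, ncol = layout$n_cols)
  lin <- (map$col - 1) * layout$n_rows + map$row
  maps <- lapply(seq_along(env$t), function(fr) {
    m <- template
    m[lin[good]] <- env$values[good, fr]
    m
  })
  structure(list(maps = maps, t = env$t, layout = layout),
            class = "activation_maps")
}

map_cells <- function(map, layout) {
  idx <- which(!is.na(map), arr.ind = TRUE)
  if (!nrow(idx)) stop("map has no defined cells")
  xy <- coords_of(layout, idx[, 1], idx[, 2])
  list(amp = map[idx], ft = xy[, "ft"], fp = xy[, "fp"])
}

#' Region-of-activation centroid of one amplitude map
#'
#' The RoA is the amplitude-weighted centroid of the cells whose amplitude is
#' at least `threshold_fraction` of the map's local maximum (the largest
#' defined cell of the whole fused grid). Ties at the threshold are included.
#' With `threshold_fraction = 0` every defined cell is active and the result
#' is the centre of gravity (CoG).
#'
#' @param map rows x cols amplitude matrix with NA at undefined positions.
#' @param layout the `grid_layout` giving cell coordinates.
#' @param threshold_fraction activity threshold relative to the local maximum
#'   (default 0.7).
#' @return named numeric `c(ft, fp)` in mm.
#' @export
roa <- function(map, layout, threshold_fraction = 0.7) {
  stopifnot(inherits(layout, "grid_layout"),
            threshold_fraction >= 0, threshold_fraction <= 1)
  cells <- map_cells(map, layout)
  L <- max(cells$amp)
  act <- cells$amp >= threshold_fraction * L
  a <- cells$amp[act]
  w <- if (sum(a) > 0) a / sum(a) else rep(1 / sum(act), sum(act))
  c(ft = sum(w * cells$ft[act]), fp = sum(w * cells$fp[act]))
}

#' Centre of gravity of one amplitude map
#'
#' Amplitude-weighted centroid over all defined cells (threshold-free RoA).
#'
#' @inheritParams roa
#' @return named numeric `c(ft, fp)` in mm.
#' @export
cog <- function(map, layout) roa(map, layout, threshold_fraction = 0)

#' Centroid trajectory over a sequence of maps
#'
#' Applies [roa()] (or [cog()]) to each frame. Frames where the centroid is
#' undefined (no defined cells) are kept as NA and excluded downstream.
#'
#' @param maps a [maps_from_envelope()] result.
#' @param threshold_fraction see [roa()]; 0 gives the CoG trajectory.
#' @return data.frame of class `roa_trajectory` with columns t, ft, fp and
#'   attribute `kind` ("RoA" or "CoG").
#' @export
roa_trajectory <- function(maps, threshold_fraction = 0.7) {
  stopifnot(inherits(maps, "activation_maps"))
  xy <- t(vapply(maps$maps, function(m) {
    tryCatch(roa(m, maps$layout, threshold_fraction),
             error = function(e) c(ft = NA_real_, fp = NA_real_))
  }, numeric(2)))
  out <- data.frame(t = maps$t, ft = xy[, "ft"], fp = xy[, "fp"])
  class(out) <- c("roa_trajectory", "data.frame")
  attr(out, "kind") <- if (threshold_fraction > 0) "RoA" else "CoG"
  out
}

#' Fill undefined map cells from their neighbours (visualization only)
#'
#' Replaces each undefined cell by the mean of its defined 4-neighbours;
#' cells with no defined neighbour stay undefined. Used only for plotting,
#' never by [roa()] or [cog()].
#'
#' @param map rows x cols amplitude matrix with NA holes.
#' @return matrix with holes filled where possible.
#' @export
interpolate_bad <- function(map) {
  holes <- which(is.na(map), arr.ind = TRUE)
  if (!nrow(holes)) return(map)
  out <- map
  nr <- nrow(map); nc <- ncol(map)
  for (k in seq_len(nrow(holes))) {
    r <- holes[k, 1]; c <- holes[k, 2]
    nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc, ,
             drop = FALSE]
    v <- map[nb]
    if (any(!is.na(v))) out[r, c] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Plot one amplitude topography
#'
#' Displays a single activation map (bad/missing cells interpolated for
#' display) with the RoA marked.
#'
#' @param map rows x cols amplitude matrix.
#' @param layout the `grid_layout`.
#' @param threshold_fraction RoA threshold, see [roa()].
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted RoA coordinates.
#' @export
plot_map <- function(map, layout, threshold_fraction = 0.7, ...) {
  shown <- interpolate_bad(map)
  ft <- (seq_len(layout$n_cols) - 1) * layout$ied_ft
  fp <- (seq_len(layout$n_rows) - 1) * layout$ied_fp
  graphics::image(ft, fp, t(shown)[, rev(seq_along(fp)), drop = FALSE],
                  xlab = "FT (mm)", ylab = "FP (mm)", ...)
  ctr <- roa(map, layout, threshold_fraction)
  graphics::points(ctr["ft"], max(fp) - ctr["fp"], pch = 4, cex = 2, lwd = 2)
  invisible(ctr)
}
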