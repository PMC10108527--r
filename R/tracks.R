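#' Project longitude/latitude to local planar metres
#'
#' Spherical transverse-Mercator projection centred on the detection
#' centroid (or a supplied origin). Over the few hundred metres a
#' fine-scale array spans, curvature is negligible and planar Euclidean
#' distances are accurate to well under a millimetre.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param origin optional length-2 `c(lon0, lat0)`; defaults to the centroid.
#' @param radius earth radius (m).
#' @return data.frame with columns `x`, `y` (m) and attribute `origin`.
#' @export
project_lonlat <- function(lon, lat, origin = NULL, radius = 6371000) {
  if (is.null(origin)) origin <- c(mean(lon), mean(lat))
  lam <- (lon - origin[1]) * pi / 180
  phi <- lat * pi / 180
  phi0 <- origin[2] * pi / 180
  x <- radius * atanh(cos(phi) * sin(lam))
  y <- radius * (atan2(tan(phi), cos(lam)) - phi0)
  out <- data.frame(x = x, y = y)
  attr(out, "origin") <- origin
  out
}

#' Split detections into gap-free tracks
#'
#' Cuts each tag's detection series wherever the interval between
#' consecutive detections exceeds 4 times the interpolation interval
#' (strictly greater than; e.g. 60 min at a 15-min interval), then discards
#' segments with fewer than `min_length` detections. Long gaps are not
#' interpolated across because consecutive predictions within them would
#' fabricate straight, constant movement; short segments are excluded for
#' numerical stability and limited behavioural information.
#'
#' @param detections data.frame with columns `tag_id`, `time` (s), `x`,
#'   `y` (m) and optionally `accel`; sorted defensively per tag.
#' @param delta_min interpolation interval in minutes (5, 10 or 15).
#' @param min_length minimum number of detections per retained track.
#' @return list of track data.frames (columns `time`, `x`, `y`, `accel`),
#'   each with attributes `tag_id` and `track_id`
#'   (`"<tag_id>_<ordinal>"`, numbered over retained tracks per tag).
#' @export
split_tracks <- function(detections, delta_min, min_length = 100) {
  if (!delta_min %in% c(5, 10, 15))
    stop("'delta_min' must be one of 5, 10, 15")
  if (nrow(detections) == 0) return(list())
  if (is.null(detections$accel)) detections$accel <- NA_real_
  max_gap <- 4 * delta_min * 60
  out <- list()
  for (tag in unique(detections$tag_id)) {
    d <- detections[detections$tag_id == tag, , drop = FALSE]
    d <- d[order(d$time), , drop = FALSE]
    if (anyDuplicated(d$time)) d <- d[!duplicated(d$time), , drop = FALSE]
    seg <- cumsum(c(0, diff(d$time) > max_gap))
    ord <- 0L
    for (s in unique(seg)) {
      piece <- d[seg == s, c("time", "x", "y", "accel"), drop = FALSE]
      if (nrow(piece) < min_length) next
      ord <- ord + 1L
      rownames(piece) <- NULL
      attr(piece, "tag_id") <- tag
      attr(piece, "track_id") <- paste0(tag, "_", ord)
      out[[length(out) + 1L]] <- piece
    }
  }
  out
}
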