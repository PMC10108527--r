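#' Derive step lengths and turning angles on a regular grid
#'
#' Step length at time t is the Euclidean distance between the positions at
#' t and t+1 (missing at the track end); the turning angle at t is the
#' signed change between the headings of the moves (t-1, t) and (t, t+1),
#' wrapped into `(-pi, pi]` (0 = straight-line movement, +pi = course
#' reversal). The first and last angles of a track are missing, and the
#' angle is missing wherever a heading is undefined because consecutive
#' positions coincide (the step there is 0).
#'
#' @param series a `"regular_series"` (or any data.frame with `time`, `x`,
#'   `y` on a regular grid).
#' @return the input with `step` and `angle` columns appended.
#' @export
compute_steps_angles <- function(series) {
  n <- nrow(series)
  step <- rep(NA_real_, n)
  angle <- rep(NA_real_, n)
  if (n >= 2) {
    dx <- diff(series$x); dy <- diff(series$y)
    step[-n] <- sqrt(dx^2 + dy^2)
    heading <- atan2(dy, dx)          # heading of move t -> t+1, length n-1
    heading[step[-n] == 0] <- NA      # duplicate positions: undefined
    if (n >= 3)
      angle[2:(n - 1)] <- wrap_angle(heading[-1] - heading[-(n - 1)])
  }
  series$step <- step
  series$angle <- angle
  series
}

#' Aggregate transmitted acceleration onto the regular grid
#'
#' Per grid interval `[t, t + delta)`, the mean of the RMS acceleration
#' values transmitted within it; missing when no transmission fell in the
#' interval (missing observations simply do not contribute to the HMM
#' likelihood downstream).
#'
#' @param track detection data.frame with `time` (s) and `accel`.
#' @param grid a `"regular_series"` (attribute `delta_min`) or a data.frame
#'   with a `time` column on a regular grid.
#' @param delta_min grid interval in minutes; defaults to the grid attribute.
#' @return numeric vector of per-interval mean accelerations, aligned with
#'   the grid rows.
#' @export
aggregate_acceleration <- function(track, grid,
                                   delta_min = attr(grid, "delta_min")) {
  if (is.null(delta_min)) stop("'delta_min' is required")
  delta_s <- delta_min * 60
  track <- track[order(track$time), , drop = FALSE]
  vapply(grid$time, function(t0) {
    a <- track$accel[track$time >= t0 & track$time < t0 + delta_s]
    a <- a[is.finite(a)]
    if (length(a) == 0) NA_real_ else mean(a)
  }, numeric(1))
}

#' Tide height and 15-min tide difference at grid times
#'
#' Tide height is linearly interpolated at each grid time; the tide
#' difference is a backward difference over a fixed 15-min lag regardless
#' of the grid interval, `h(t) - h(t - 15 min)`, so positive values mean a
#' flood (incoming) tide and negative an ebb tide, with larger magnitudes
#' implying stronger tidal currents. Grid times outside the tide record
#' give missing covariates (flagged via the `outside` attribute).
#'
#' @param tide a `"tide_series"` (columns `time` s, `height` m).
#' @param grid_times numeric grid times (s).
#' @param lag_s backward-difference lag in seconds (default 900).
#' @return data.frame with columns `tide` (m) and `dtide` (m per lag);
#'   attribute `outside` marks rows outside the tide record.
#' @export
build_tide_covariates <- function(tide, grid_times, lag_s = 900) {
  h <- approx(tide$time, tide$height, xout = grid_times, rule = 1)$y
  hlag <- approx(tide$time, tide$height, xout = grid_times - lag_s, rule = 1)$y
  out <- data.frame(tide = h, dtide = h - hlag)
  attr(out, "outside") <- !is.finite(h) | !is.finite(hlag)
  out
}

#' Cyclic time-of-day covariates
#'
#' The harmonic pair `cos(2*pi*t/24)` and `sin(2*pi*t/24)` for local clock
#' hour `t`, encoding a 24-h periodic diel effect.
#'
#' @param t local clock hour of day (reduced modulo 24).
#' @return data.frame with `hour_cos` and `hour_sin`.
#' @export
#' @examples
#' cyclic_time(c(0, 6, 12))
cyclic_time <- function(t) {
  t <- t %% 24
  data.frame(hour_cos = cos(2 * pi * t / 24), hour_sin = sin(2 * pi * t / 24))
}

.point_in_ring <- function(px, py, rx, ry) {
  n <- length(rx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- ry[j] - ry[i]
    crosses <- ((ry[i] > py) != (ry[j] > py)) &
      (px < (rx[j] - rx[i]) * (py - ry[i]) / denom + rx[i])
    inside <- xor(inside, crosses & is.finite(crosses))
    j <- i
  }
  inside
}

.dist_to_ring <- function(px, py, rx, ry) {
  n <- length(rx)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- rx[j]; ay <- ry[j]; bx <- rx[i]; by <- ry[i]
    abx <- bx - ax; aby <- by - ay
    len2 <- abx^2 + aby^2
    tt <- if (len2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - ax) * abx + (py - ay) * aby) / len2, 0), 1)
    dx <- ax + tt * abx - px; dy <- ay + tt * aby - py
    d2 <- pmin(d2, dx^2 + dy^2)
    j <- i
  }
  sqrt(d2)
}

.validate_polygon <- function(poly, idx) {
  cc <- poly$coords
  if (!is.matrix(cc) || ncol(cc) < 2 || nrow(cc) < 3 || any(!is.finite(cc)))
    stop("invalid habitat polygon ", idx, " ('", poly$category,
         "'): need >= 3 finite vertices")
  invisible(TRUE)
}

#' Assign habitat categories to positions
#'
#' A position takes the category of any habitat polygon it falls inside or
#' within `buffer` metres of (the buffer absorbs positioning error and edge
#' effects around meadows); overlaps are resolved by a fixed priority
#' (seagrass > mangrove > saltmarsh by default), and positions matching no
#' polygon are `"unvegetated"`.
#'
#' @param x,y positions (m).
#' @param polygons list of polygons, each `list(category = "seagrass",
#'   coords = <n x 2 matrix>)` (ring closure optional); see
#'   [read_habitat_geojson()].
#' @param buffer dilation distance in metres (default 1.26, a typical
#'   median array positioning error).
#' @param priority category priority for overlaps, highest first.
#' @return factor with levels `priority` plus `"unvegetated"`.
#' @export
assign_habitat <- function(x, y, polygons, buffer = 1.26,
                           priority = c("seagrass", "mangrove", "saltmarsh")) {
  lev <- c(priority, "unvegetated")
  out <- factor(rep("unvegetated", length(x)), levels = lev)
  rank <- rep(Inf, length(x))
  for (idx in seq_along(polygons)) {
    poly <- polygons[[idx]]
    .validate_polygon(poly, idx)
    rx <- poly$coords[, 1]; ry <- poly$coords[, 2]
    if (rx[1] == rx[length(rx)] && ry[1] == ry[length(ry)] && length(rx) > 3) {
      rx <- rx[-length(rx)]; ry <- ry[-length(ry)]
    }
    hit <- .point_in_ring(x, y, rx, ry) |
      (.dist_to_ring(x, y, rx, ry) <= buffer)
    pr <- match(poly$category, priority)
    if (is.na(pr)) pr <- length(priority) + 0.5
    upd <- hit & pr < rank
    out[upd] <- poly$category
    rank[upd] <- pr
  }
  out
}

#' Read habitat polygons from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection whose features carry a `habitat`
#' property and Polygon/MultiPolygon geometries (outer rings only).
#'
#' @param path path to a GeoJSON file.
#' @return list of polygons as expected by [assign_habitat()].
#' @export
read_habitat_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (f in gj$features) {
    cat_ <- f$properties$habitat
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
      stop("unsupported geometry type: ", geom$type))
    for (ring in rings) {
      cc <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      out[[length(out) + 1L]] <- list(category = cat_, coords = cc)
    }
  }
  out
}

#' Assemble the model-ready observation table
#'
#' Joins the regularized positions, derived movement streams, aggregated
#' acceleration and environmental covariates into one table with one row
#' per grid interval per track, ready for [fit_hmm()].
#'
#' @param series_list list of `"regular_series"` (one per track, with
#'   `track_id` attributes), e.g. from [predict_regular()].
#' @param tracks optional list of detection tracks aligned with
#'   `series_list`, used to aggregate transmitted acceleration.
#' @param tide optional `"tide_series"` for tide covariates.
#' @param temperature optional data.frame (`time` s, `temp` degrees C),
#'   linearly interpolated.
#' @param habitat optional polygon list for [assign_habitat()].
#' @param habitat_buffer buffer passed to [assign_habitat()].
#' @param tz_offset_hours offset added to UTC time to obtain local clock
#'   hour (diel behaviour follows local solar time).
#' @return data.frame with columns `id`, `track_id`, `time`, `x`, `y`,
#'   `step`, `angle`, `accel` and any of `tide`, `dtide`, `hour_cos`,
#'   `hour_sin`, `habitat`, `temp`.
#' @export
prepare_hmm_data <- function(series_list, tracks = NULL, tide = NULL,
                             temperature = NULL, habitat = NULL,
                             habitat_buffer = 1.26, tz_offset_hours = 10) {
  rows <- vector("list", length(series_list))
  for (k in seq_along(series_list)) {
    ser <- series_list[[k]]
    ser <- compute_steps_angles(ser)
    tid <- attr(ser, "track_id")
    if (is.null(tid)) tid <- paste0("track", k)
    d <- data.frame(id = sub("_[0-9]+$", "", tid), track_id = tid,
                    time = ser$time, x = ser$x, y = ser$y,
                    step = ser$step, angle = ser$angle)
    d$accel <- if (!is.null(tracks))
      aggregate_acceleration(tracks[[k]], ser) else NA_real_
    if (!is.null(tide)) {
      tc <- build_tide_covariates(tide, ser$time)
      d$tide <- tc$tide; d$dtide <- tc$dtide
    }
    ct <- cyclic_time((d$time / 3600 + tz_offset_hours) %% 24)
    d$hour_cos <- ct$hour_cos; d$hour_sin <- ct$hour_sin
    if (!is.null(temperature))
      d$temp <- approx(temperature$time, temperature$temp,
                       xout = ser$time, rule = 1)$y
    if (!is.null(habitat))
      d$habitat <- assign_habitat(ser$x, ser$y, habitat, habitat_buffer)
    rows[[k]] <- d
  }
  do.call(rbind, rows)
}
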