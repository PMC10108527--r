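#' Coppens shallow-water sound speed
#'
#' Evaluates the Coppens (1981) polynomial for the speed of sound in
#' seawater as a function of temperature, salinity and depth. Valid for
#' 0-35 degrees C, 0-45 psu; out-of-range inputs trigger a warning but a
#' value is still returned.
#'
#' @param temperature water temperature (degrees C).
#' @param salinity salinity (psu).
#' @param depth depth (m).
#' @return sound speed in m s^-1.
#' @export
#' @examples
#' coppens_sound_speed(0, 35, 0)  # 1449.05
coppens_sound_speed <- function(temperature, salinity, depth = 0) {
  if (any(temperature < 0 | temperature > 35, na.rm = TRUE) ||
      any(salinity < 0 | salinity > 45, na.rm = TRUE))
    warning("temperature/salinity outside the Coppens validity range")
  t <- temperature / 10
  D <- depth / 1000
  c0 <- 1449.05 + 45.7 * t - 5.21 * t^2 + 0.23 * t^3 +
    (1.333 - 0.126 * t + 0.009 * t^2) * (salinity - 35)
  c0 + (16.23 + 0.253 * t) * D + (0.213 - 0.1 * t) * D^2 +
    (0.016 + 0.0002 * (salinity - 35)) * (salinity - 35) * t * D
}

.as_receiver_matrix <- function(array) {
  m <- as.matrix(as.data.frame(array)[, intersect(c("x", "y", "z"),
                                                  names(as.data.frame(array))), drop = FALSE])
  if (!all(c("x", "y") %in% colnames(m)))
    stop("receiver array must have 'x' and 'y' coordinates")
  if (!"z" %in% colnames(m)) m <- cbind(m, z = 0)
  m
}

#' Simulate signal arrival times at a receiver array
#'
#' Arrival time at receiver i is `t0 + distance_i / sound_speed`, optionally
#' plus Gaussian timing noise and per-receiver linear clock skew
#' (`skew_s_per_day * elapsed_days`).
#'
#' @param array receiver positions: data.frame/matrix with columns `x`, `y`
#'   (and optionally `z`), metres.
#' @param position true tag position, length 2 (x, y) or 3 (x, y, z), m.
#' @param t0 transmission time (s).
#' @param sound_speed signal propagation speed (m s^-1).
#' @param noise_sd timing noise SD (s).
#' @param skew per-receiver clock skew rates (s per day), recycled.
#' @param elapsed_days time since clock synchronization (days).
#' @return numeric vector of arrival times (s), one per receiver.
#' @export
simulate_arrival_times <- function(array, position, t0 = 0,
                                   sound_speed = 1500, noise_sd = 0,
                                   skew = 0, elapsed_days = 0) {
  m <- .as_receiver_matrix(array)
  pos <- c(position, 0)[1:3]
  d <- sqrt((m[, "x"] - pos[1])^2 + (m[, "y"] - pos[2])^2 +
              (m[, "z"] - pos[3])^2)
  t0 + d / sound_speed + rnorm(nrow(m), 0, noise_sd) +
    rep_len(skew, nrow(m)) * elapsed_days
}

#' Position a transmitter by time-difference-of-arrival multilateration
#'
#' Least-squares hyperbolic positioning: finds the planar position whose
#' predicted time differences of arrival (relative to the first receiver)
#' best match the observed ones, for detections at 3 or more receivers.
#' Each receiver pair constrains the source to a hyperbola; the solver
#' minimizes squared TDOA residuals with `optim` (Nelder-Mead, then BFGS
#' polish) starting at the array centroid.
#'
#' @param array receiver positions (data.frame/matrix, columns `x`, `y`,
#'   optional `z`, metres).
#' @param arrival_times arrival time at each receiver (s), aligned with the
#'   array rows.
#' @param sound_speed signal propagation speed (m s^-1, > 0).
#' @param tag_depth assumed transmitter depth (m) when receivers have `z`.
#' @param init optional starting position (defaults to the centroid).
#' @return list with `position` (length-2), `rms_residual_s` (RMS TDOA
#'   residual, s), `converged` (logical).
#' @export
tdoa_solve <- function(array, arrival_times, sound_speed = 1500,
                       tag_depth = 0, init = NULL) {
  m <- .as_receiver_matrix(array)
  ok <- is.finite(arrival_times)
  m <- m[ok, , drop = FALSE]
  tt <- arrival_times[ok]
  if (nrow(m) < 3) stop("TDOA positioning requires detections at >= 3 receivers")
  if (any(duplicated(m[, c("x", "y")])))
    stop("receiver positions must be pairwise distinct")
  if (sound_speed <= 0) stop("'sound_speed' must be > 0")
  dtd <- tt[-1] - tt[1]
  resid_fn <- function(p) {
    d <- sqrt((m[, "x"] - p[1])^2 + (m[, "y"] - p[2])^2 +
                (m[, "z"] - tag_depth)^2)
    (d[-1] - d[1]) / sound_speed - dtd
  }
  obj <- function(p) sum(resid_fn(p)^2)
  if (is.null(init)) init <- c(mean(m[, "x"]), mean(m[, "y"]))
  f1 <- optim(init, obj, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-14))
  f2 <- suppressWarnings(optim(f1$par, obj, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-14)))
  best <- if (f2$value <= f1$value) f2 else f1
  list(position = unname(best$par),
       rms_residual_s = sqrt(best$value / (nrow(m) - 1)),
       converged = best$convergence == 0)
}

#' Estimate and remove linear receiver clock skew using a sync tag
#'
#' Receiver clocks can drift by several seconds per day; transmissions from
#' a synchronization tag at a known position (whose true arrival times are
#' therefore known) are used to fit a linear skew model
#' `observed - true ~ observed`, which is then subtracted from arbitrary
#' detection times on the same receiver.
#'
#' @param times detection times to correct (s).
#' @param observed_sync observed sync-tag arrival times on this receiver (s).
#' @param true_sync true sync-tag arrival times (s).
#' @return corrected `times` (s).
#' @export
correct_clock_skew <- function(times, observed_sync, true_sync) {
  if (length(observed_sync) < 2) stop("need >= 2 sync detections")
  fit <- stats::lm(offset ~ obs,
                   data = data.frame(offset = observed_sync - true_sync,
                                     obs = observed_sync))
  times - stats::predict(fit, newdata = data.frame(obs = times))
}

#' Audit positioning error against a fixed reference tag
#'
#' Summarizes the horizontal distance between estimated positions of a tag
#' at a known, fixed location and that location: the standard array
#' performance check. Also returns the isotropic bivariate-Gaussian
#' measurement-error covariance implied by the errors, suitable for the
#' movement state-space model.
#'
#' @param estimates detections data.frame with columns `x`, `y` (m).
#' @param known_position true tag position, length 2 (m).
#' @return object of class `"array_audit"`: list with `n`, `mean`, `sd`,
#'   `median`, `iqr`, `frac_within_5m`, `errors` and `error_cov` (2x2, m^2).
#' @export
audit_reference_tag <- function(estimates, known_position) {
  if (nrow(estimates) < 1) stop("need at least one position estimate")
  err <- sqrt((estimates$x - known_position[1])^2 +
                (estimates$y - known_position[2])^2)
  s2 <- mean(err^2) / 2  # per-axis variance under isotropy
  out <- list(n = length(err), mean = mean(err), sd = sd(err),
              median = median(err), iqr = stats::IQR(err),
              frac_within_5m = mean(err <= 5),
              error_cov = diag(s2, 2), errors = err)
  class(out) <- "array_audit"
  out
}

#' @export
print.array_audit <- function(x, ...) {
  cat("Reference-tag positioning audit (n =", x$n, ")\n")
  cat(sprintf("  horizontal error: mean %.2f m (SD %.2f), median %.2f m (IQR %.2f)\n",
              x$mean, x$sd, x$median, x$iqr))
  cat(sprintf("  within 5 m: %.1f%%\n", 100 * x$frac_within_5m))
  cat(sprintf("  implied isotropic error variance: %.3f m^2 per axis\n",
              x$error_cov[1, 1]))
  invisible(x)
}
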