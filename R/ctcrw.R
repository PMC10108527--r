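# Continuous-time correlated random walk: integrated Ornstein-Uhlenbeck
# velocity process observed with Gaussian positional error, handled by a
# linear-Gaussian state-space model (Kalman filter / RTS smoother).
#
# State per axis: (position, velocity); velocity follows
# dv = -beta_ou * v dt + sigma dW, position integrates velocity. Time is
# internally in hours, so beta_ou is h^-1 and sigma the velocity volatility
# on the hour scale. The full state is (x, vx, y, vy) so a correlated 2x2
# measurement-error covariance is supported.

.ctcrw_axis_mats <- function(dt, beta, sigma2) {
  eb <- exp(-beta * dt)
  Phi <- matrix(c(1, 0, (1 - eb) / beta, eb), 2, 2)
  qvv <- sigma2 * (1 - eb^2) / (2 * beta)
  qxv <- sigma2 * (1 - eb)^2 / (2 * beta^2)
  qxx <- sigma2 / beta^2 * (dt - 2 * (1 - eb) / beta + (1 - eb^2) / (2 * beta))
  list(Phi = Phi, Q = matrix(c(qxx, qxv, qxv, qvv), 2, 2))
}

.ctcrw_full_mats <- function(dt, beta, sigma2) {
  ax <- .ctcrw_axis_mats(dt, beta, sigma2)
  F4 <- matrix(0, 4, 4); Q4 <- matrix(0, 4, 4)
  F4[1:2, 1:2] <- ax$Phi; F4[3:4, 3:4] <- ax$Phi
  Q4[1:2, 1:2] <- ax$Q; Q4[3:4, 3:4] <- ax$Q
  list(F = F4, Q = Q4)
}

.ctcrw_H <- matrix(c(1, 0, 0, 0,
                     0, 0, 1, 0), nrow = 2, byrow = TRUE)

.ctcrw_init <- function(z1, beta, sigma2, pos_var = 1e6) {
  vv <- sigma2 / (2 * beta)  # stationary velocity variance
  list(a = c(z1[1], 0, z1[2], 0),
       P = diag(c(pos_var, vv, pos_var, vv)))
}

# Kalman filter (and optional RTS smoother) over a merged time grid.
# times: strictly increasing (hours); obs: n x 2 matrix with NA rows where
# no observation is available; R: 2x2 measurement covariance.
.ctcrw_kalman <- function(times, obs, R, beta, sigma2, smooth = FALSE) {
  n <- length(times)
  H <- .ctcrw_H
  first_obs <- which(is.finite(obs[, 1]))[1]
  init <- .ctcrw_init(obs[first_obs, ], beta, sigma2)
  a <- init$a; P <- init$P
  ll <- 0
  a_pred <- matrix(NA_real_, n, 4); a_filt <- matrix(NA_real_, n, 4)
  P_pred <- array(NA_real_, c(4, 4, n)); P_filt <- array(NA_real_, c(4, 4, n))
  F_list <- vector("list", n)
  for (t in seq_len(n)) {
    if (t > 1) {
      dt <- times[t] - times[t - 1]
      m <- .ctcrw_full_mats(dt, beta, sigma2)
      a <- drop(m$F %*% a)
      P <- m$F %*% P %*% t(m$F) + m$Q
      F_list[[t]] <- m$F
    }
    a_pred[t, ] <- a; P_pred[, , t] <- P
    if (is.finite(obs[t, 1])) {
      v <- obs[t, ] - drop(H %*% a)
      S <- H %*% P %*% t(H) + R
      cS <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(cS)) return(list(loglik = -Inf))
      Sinv_v <- backsolve(cS, forwardsolve(t(cS), v))
      ll <- ll - 0.5 * (2 * log(2 * pi) + 2 * sum(log(diag(cS))) +
                          sum(v * Sinv_v))
      K <- P %*% t(H) %*% chol2inv(cS)
      a <- a + drop(K %*% v)
      P <- P - K %*% H %*% P
      P <- (P + t(P)) / 2
    }
    a_filt[t, ] <- a; P_filt[, , t] <- P
  }
  out <- list(loglik = ll)
  if (smooth) {
    a_s <- a_filt; P_s <- P_filt
    if (n > 1) {
      for (t in (n - 1):1) {
        Pp <- P_pred[, , t + 1]
        J <- P_filt[, , t] %*% t(F_list[[t + 1]]) %*% solve(Pp)
        a_s[t, ] <- a_filt[t, ] + drop(J %*% (a_s[t + 1, ] - a_pred[t + 1, ]))
        P_s[, , t] <- P_filt[, , t] +
          J %*% (P_s[, , t + 1] - Pp) %*% t(J)
      }
    }
    out$a_smooth <- a_s
    out$P_smooth <- P_s
  }
  out
}

.check_error_cov <- function(error_cov) {
  error_cov <- as.matrix(error_cov)
  if (!all(dim(error_cov) == c(2, 2)) ||
      any(abs(error_cov - t(error_cov)) > 1e-10) ||
      any(eigen(error_cov, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    stop("'error_cov' must be a symmetric positive semi-definite 2x2 matrix")
  error_cov
}

#' Continuous-time correlated random walk log-likelihood
#'
#' Kalman-filter log-likelihood of a track under the integrated
#' Ornstein-Uhlenbeck velocity model with Gaussian measurement error. The
#' initial state is centred on the first observation with a diffuse
#' position prior and the stationary velocity prior.
#'
#' @param track data.frame with columns `time` (s), `x`, `y` (m).
#' @param beta_ou velocity autocorrelation decay rate (h^-1, > 0).
#' @param sigma velocity volatility (> 0; hour time scale).
#' @param error_cov 2x2 measurement-error covariance (m^2).
#' @return log-likelihood (scalar).
#' @export
ctcrw_loglik <- function(track, beta_ou, sigma, error_cov) {
  if (beta_ou <= 0 || sigma <= 0) stop("'beta_ou' and 'sigma' must be > 0")
  error_cov <- .check_error_cov(error_cov)
  th <- (track$time - track$time[1]) / 3600
  if (any(diff(th) <= 0)) stop("track times must be strictly increasing")
  obs <- cbind(track$x, track$y)
  .ctcrw_kalman(th, obs, error_cov, beta_ou, sigma^2)$loglik
}

#' Simulate a continuous-time correlated random walk
#'
#' Draws true positions from the integrated-OU model at given times and
#' adds Gaussian measurement error; used for parameter-recovery checks.
#'
#' @param times observation times (s), strictly increasing.
#' @param beta_ou,sigma model parameters (hour time scale).
#' @param error_cov 2x2 measurement-error covariance (m^2).
#' @param start starting position (m).
#' @param seed optional integer seed.
#' @return data.frame with `time`, `x`, `y` (observed) and `x_true`,
#'   `y_true`.
#' @export
simulate_ctcrw <- function(times, beta_ou, sigma, error_cov = diag(0, 2),
                           start = c(0, 0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  error_cov <- .check_error_cov(error_cov)
  th <- (times - times[1]) / 3600
  n <- length(times)
  sigma2 <- sigma^2
  state <- matrix(NA_real_, n, 4)
  vsd <- sqrt(sigma2 / (2 * beta_ou))
  state[1, ] <- c(start[1], rnorm(1, 0, vsd), start[2], rnorm(1, 0, vsd))
  for (t in 2:n) {
    m <- .ctcrw_full_mats(th[t] - th[t - 1], beta_ou, sigma2)
    cc <- chol(m$Q + diag(1e-12, 4))
    state[t, ] <- drop(m$F %*% state[t - 1, ]) + drop(t(cc) %*% rnorm(4))
  }
  ce <- chol(error_cov + diag(1e-12, 2))
  err <- matrix(rnorm(2 * n), n, 2) %*% ce
  data.frame(time = times,
             x = state[, 1] + err[, 1], y = state[, 3] + err[, 2],
             x_true = state[, 1], y_true = state[, 3])
}

#' Fit the continuous-time correlated random walk to a track
#'
#' Maximizes the Kalman-filter likelihood over the velocity autocorrelation
#' decay `beta_ou` and volatility `sigma` (both on the log scale, bounded)
#' from multiple randomly perturbed starts, retaining the best. Starts are
#' moment-based (empirical velocity variance and sampling rate) and
#' restarts apply multiplicative log-normal perturbations (SD 0.5 on the
#' log scale).
#'
#' @param track data.frame with columns `time` (s), `x`, `y` (m); attribute
#'   `track_id` if available.
#' @param error_cov 2x2 measurement-error covariance (m^2), e.g. from
#'   [audit_reference_tag()].
#' @param n_restarts number of random restarts.
#' @param seed optional integer seed.
#' @return object of class `"ctcrw"`: list with `par` (named `beta_ou`,
#'   `sigma`), `loglik`, `error_cov`, `track`, `restart_log`, `convergence`,
#'   `boundary`.
#' @export
fit_ctcrw <- function(track, error_cov, n_restarts = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  error_cov <- .check_error_cov(error_cov)
  track <- track[order(track$time), , drop = FALSE]
  if (anyDuplicated(track$time)) stop("track times must be strictly increasing")
  th <- (track$time - track$time[1]) / 3600
  dth <- diff(th)
  vx <- diff(track$x) / dth; vy <- diff(track$y) / dth
  v_var <- (var(vx) + var(vy)) / 2
  degenerate <- !is.finite(v_var) || v_var < 1e-12
  beta0 <- min(max(1 / median(dth), 1e-2), 100)
  sigma2_0 <- if (degenerate) 1e-6 else max(v_var * 2 * beta0, 1e-8)
  start0 <- log(c(beta0, sigma2_0))
  lower <- log(c(1e-4, 1e-10)); upper <- log(c(1e4, 1e12))
  obs <- cbind(track$x, track$y)
  nll <- function(w) {
    ll <- .ctcrw_kalman(th, obs, error_cov, exp(w[1]), exp(w[2]))$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  logs <- vector("list", n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    w0 <- if (r == 1) start0 else start0 + rnorm(2, 0, 0.5)
    w0 <- pmin(pmax(w0, lower), upper)
    fit <- tryCatch(
      optim(w0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) {
      logs[[r]] <- data.frame(restart = r, converged = FALSE,
                              loglik = NA_real_)
      next
    }
    logs[[r]] <- data.frame(restart = r, converged = fit$convergence == 0,
                            loglik = -fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all CTCRW restarts failed; check the track data")
  w <- best$par
  boundary <- any(abs(w - lower) < 1e-6) || any(abs(w - upper) < 1e-6)
  if (degenerate)
    warning("track has (near-)identical positions; sigma is at its lower bound")
  out <- list(par = c(beta_ou = exp(w[1]), sigma = sqrt(exp(w[2]))),
              loglik = -best$value, error_cov = error_cov, track = track,
              restart_log = do.call(rbind, logs),
              convergence = best$convergence == 0,
              boundary = boundary || degenerate,
              n_restarts = n_restarts)
  class(out) <- "ctcrw"
  out
}

#' @export
print.ctcrw <- function(x, ...) {
  cat("Continuous-time correlated random walk fit\n")
  cat(sprintf("  beta_ou = %.4g h^-1, sigma = %.4g\n",
              x$par["beta_ou"], x$par["sigma"]))
  cat(sprintf("  log-likelihood %.3f over %d detections (%d restarts)\n",
              x$loglik, nrow(x$track), x$n_restarts))
  if (x$boundary) cat("  note: estimate at or near a parameter bound\n")
  invisible(x)
}

#' @export
coef.ctcrw <- function(object, ...) object$par

#' @export
logLik.ctcrw <- function(object, ...) {
  structure(object$loglik, df = 2, class = "logLik")
}

#' Predict temporally regular locations from a fitted CTCRW
#'
#' Runs the Kalman smoother over the union of detection times and a regular
#' grid (anchored at the first detection time rounded up to the interval)
#' and returns the smoothed positions and their prediction variances at the
#' grid times. Two-sided (smoothed) prediction is used since locations are
#' interpolated within a track.
#'
#' @param track data.frame with `time` (s), `x`, `y` (m).
#' @param params a fitted `"ctcrw"` object, or a list with elements
#'   `par["beta_ou"]`, `par["sigma"]` and `error_cov`.
#' @param delta_min grid interval in minutes.
#' @return data.frame of class `"regular_series"` with `time`, `x`, `y`,
#'   `var_x`, `var_y`; attributes `track_id`, `delta_min`. Empty when the
#'   track spans less than one interval.
#' @export
predict_regular <- function(track, params, delta_min) {
  track <- track[order(track$time), , drop = FALSE]
  delta_s <- delta_min * 60
  t0 <- ceiling(track$time[1] / delta_s) * delta_s
  tn <- track$time[nrow(track)]
  if (t0 > tn) {
    out <- data.frame(time = numeric(0), x = numeric(0), y = numeric(0),
                      var_x = numeric(0), var_y = numeric(0))
  } else {
    grid <- seq(t0, tn, by = delta_s)
    all_t <- sort(unique(c(track$time, grid)))
    obs <- matrix(NA_real_, length(all_t), 2)
    m <- match(track$time, all_t)
    obs[m, 1] <- track$x; obs[m, 2] <- track$y
    th <- (all_t - all_t[1]) / 3600
    kf <- .ctcrw_kalman(th, obs, .check_error_cov(params$error_cov),
                        params$par[["beta_ou"]], params$par[["sigma"]]^2,
                        smooth = TRUE)
    gi <- match(grid, all_t)
    out <- data.frame(time = grid,
                      x = kf$a_smooth[gi, 1], y = kf$a_smooth[gi, 3],
                      var_x = pmax(kf$P_smooth[1, 1, gi], 0),
                      var_y = pmax(kf$P_smooth[3, 3, gi], 0))
  }
  attr(out, "track_id") <- attr(track, "track_id")
  attr(out, "delta_min") <- delta_min
  class(out) <- c("regular_series", "data.frame")
  out
}

#' @export
predict.ctcrw <- function(object, delta_min = 15, ...) {
  predict_regular(object$track, object, delta_min)
}
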