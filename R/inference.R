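# Post-fit inference: decoding, equilibrium behaviour, residual
# diagnostics, model selection and occupancy summaries.

.fit_spec_for <- function(object, data) {
  if (is.null(data)) object$spec else
    hmm_spec(data, object$n_states, object$formula, object$K,
             object$spec$prior_sd)
}

# MAP mixture component per individual (K > 1); NULL for K = 1.
.map_components <- function(object, spec) {
  if (object$K == 1) return(NULL)
  ll_mat <- vapply(seq_len(object$K), function(k)
    vapply(spec$tracks, .track_loglik, numeric(1),
           emission = object$par$emission, beta = object$par$beta[[k]],
           n_states = object$n_states, streams = spec$streams),
    numeric(length(spec$tracks)))
  ll_mat <- matrix(ll_mat, nrow = length(spec$tracks))
  comp <- vapply(unique(spec$ids), function(m) {
    which.max(colSums(ll_mat[spec$ids == m, , drop = FALSE]) +
                log(object$par$weights))
  }, integer(1))
  setNames(comp, unique(spec$ids))
}

.track_beta <- function(object, comp, id) {
  if (object$K == 1) object$par$beta else object$par$beta[[comp[[as.character(id)]]]]
}

.gamma_slice <- function(tg, t) {
  if (tg$homogeneous) tg$gamma[, , 1] else tg$gamma[, , t]
}

# log-space forward and backward variables for one track.
.track_fb <- function(L, tg, delta) {
  T_ <- nrow(L); N <- ncol(L)
  la <- matrix(-Inf, T_, N); lb <- matrix(0, T_, N)
  la[1, ] <- log(delta) + L[1, ]
  for (t in 2:T_) {
    lg <- log(.gamma_slice(tg, t - 1))
    for (j in seq_len(N)) {
      v <- la[t - 1, ] + lg[, j]
      mx <- max(v)
      la[t, j] <- if (is.finite(mx)) mx + log(sum(exp(v - mx))) else -Inf
      la[t, j] <- la[t, j] + L[t, j]
    }
  }
  for (t in (T_ - 1):1) {
    lg <- log(.gamma_slice(tg, t))
    for (i in seq_len(N)) {
      v <- lg[i, ] + L[t + 1, ] + lb[t + 1, ]
      mx <- max(v)
      lb[t, i] <- if (is.finite(mx)) mx + log(sum(exp(v - mx))) else -Inf
    }
  }
  mx <- max(la[T_, ])
  ll <- mx + log(sum(exp(la[T_, ] - mx)))
  list(la = la, lb = lb, loglik = ll)
}

#' Viterbi decoding of behavioural states
#'
#' Computes, per track, the globally most likely state sequence given the
#' observations and fitted model (dynamic programming in log space; ties
#' broken toward the lower state index), together with the smoothed
#' per-interval state probabilities from the forward-backward algorithm.
#' With a mixture random effect, each individual is decoded under its
#' maximum a posteriori component.
#'
#' @param object a fitted `"crab_hmm"`.
#' @param data optional new model-ready data (defaults to the fitting
#'   data).
#' @return data.frame of class `"hmm_decode"`: `track_id`, `time`,
#'   `state`, and smoothed probabilities `p_state1..N`.
#' @export
viterbi <- function(object, data = NULL) {
  spec <- .fit_spec_for(object, data)
  comp <- .map_components(object, spec)
  out <- vector("list", length(spec$tracks))
  for (i in seq_along(spec$tracks)) {
    tr <- spec$tracks[[i]]
    beta <- .track_beta(object, comp, tr$id)
    L <- .hmm_logdens(tr$obs, object$par$emission, object$n_states,
                      spec$streams)
    tg <- .track_gamma(list(design = tr$design), beta, object$n_states)
    delta <- .track_delta(tg$first)
    T_ <- nrow(L); N <- ncol(L)
    v <- log(delta) + L[1, ]
    back <- matrix(0L, T_, N)
    if (T_ > 1) {
      for (t in 2:T_) {
        lg <- log(.gamma_slice(tg, t - 1))
        vn <- numeric(N)
        for (j in seq_len(N)) {
          cand <- v + lg[, j]
          back[t, j] <- which.max(cand)
          vn[j] <- cand[back[t, j]] + L[t, j]
        }
        v <- vn
      }
    }
    st <- integer(T_)
    st[T_] <- which.max(v)
    if (T_ > 1) for (t in (T_ - 1):1) st[t] <- back[t + 1, st[t + 1]]
    fb <- .track_fb(L, tg, delta)
    pr <- exp(fb$la + fb$lb - fb$loglik)
    pr <- pr / rowSums(pr)
    d <- data.frame(track_id = spec$track_ids[i], time = tr$time,
                    state = st)
    for (j in seq_len(N)) d[[paste0("p_state", j)]] <- pr[, j]
    out[[i]] <- d
  }
  res <- do.call(rbind, out)
  attr(res, "n_states") <- object$n_states
  class(res) <- c("hmm_decode", "data.frame")
  res
}

#' Stationary state probabilities along a covariate gradient
#'
#' Solves `pi %*% P = pi` for the transition matrix realized at each value
#' of one covariate, other covariates held at their mean (numeric) or
#' modal level (factors), or averaged over the observed rows
#' (`fix = "average"`). 95% confidence intervals come from the delta
#' method on the working-scale transition coefficients (finite-difference
#' Jacobian of the stationary solve), truncated to `[0, 1]`.
#'
#' @param object a fitted `"crab_hmm"` with `K = 1`.
#' @param covariate name of the covariate to vary.
#' @param values grid of covariate values (default 50 points over the
#'   observed range).
#' @param fix `"mean"` (fix other covariates) or `"average"` (average the
#'   stationary probabilities over all observed rows).
#' @param level confidence level.
#' @param se compute delta-method intervals? (Requires the working-scale
#'   covariance; skipped for `fix = "average"`.)
#' @return data.frame of class `"stationary_curve"`: `value`, `state`,
#'   `prob`, `lower`, `upper`.
#' @export
stationary_probabilities <- function(object, covariate, values = NULL,
                                     fix = c("mean", "average"),
                                     level = 0.95, se = TRUE) {
  fix <- match.arg(fix)
  if (object$K > 1)
    stop("stationary curves are defined for K = 1 fits")
  data <- object$data
  if (!covariate %in% names(data)) stop("covariate '", covariate, "' not in data")
  if (is.null(values))
    values <- seq(min(data[[covariate]], na.rm = TRUE),
                  max(data[[covariate]], na.rm = TRUE), length.out = 50)
  N <- object$n_states
  vars <- setdiff(all.vars(object$formula), covariate)
  pi_at <- function(beta, design_rows) {
    G <- build_transition_matrices(beta, design_rows, N)
    ps <- vapply(seq_len(dim(G)[3]),
                 function(t) stationary_dist(G[, , t]), numeric(N))
    rowMeans(matrix(ps, nrow = N))
  }
  design_for <- function(v) {
    nd <- data[rep(1, 1), , drop = FALSE]
    if (fix == "average") nd <- data
    nd[[covariate]] <- v
    if (fix == "mean") {
      for (nm in vars) {
        nd[[nm]] <- if (is.numeric(data[[nm]])) mean(data[[nm]], na.rm = TRUE)
        else {
          tb <- table(data[[nm]])
          factor(names(tb)[which.max(tb)], levels = levels(factor(data[[nm]])))
        }
      }
    }
    mf <- stats::model.frame(object$formula, nd, na.action = stats::na.pass)
    stats::model.matrix(object$formula, mf)
  }
  beta <- object$par$beta
  do_se <- se && fix == "mean"
  if (do_se) {
    V <- vcov(object)
    bidx <- grep("^beta\\.", names(object$working))
    Vb <- V[bidx, bidx, drop = FALSE]
  }
  z <- qnorm(1 - (1 - level) / 2)
  rows <- vector("list", length(values))
  for (vi in seq_along(values)) {
    X <- design_for(values[vi])
    p0 <- pi_at(beta, X)
    lo <- up <- rep(NA_real_, N)
    if (do_se) {
      h <- 1e-5
      J <- matrix(0, N, length(bidx))
      for (b in seq_along(bidx)) {
        bp <- beta; bm <- beta
        bp[b] <- bp[b] + h; bm[b] <- bm[b] - h
        J[, b] <- (pi_at(bp, X) - pi_at(bm, X)) / (2 * h)
      }
      sev <- sqrt(pmax(diag(J %*% Vb %*% t(J)), 0))
      lo <- pmax(p0 - z * sev, 0); up <- pmin(p0 + z * sev, 1)
    }
    rows[[vi]] <- data.frame(value = values[vi], state = seq_len(N),
                             prob = p0, lower = lo, upper = up)
  }
  out <- do.call(rbind, rows)
  attr(out, "covariate") <- covariate
  class(out) <- c("stationary_curve", "data.frame")
  out
}

#' @export
plot.stationary_curve <- function(x, ...) {
  cov_name <- attr(x, "covariate")
  N <- max(x$state)
  cols <- c("#E6A800", "#5C4B8A", "#2E7D32")
  plot(NULL, xlim = range(x$value), ylim = c(0, 1),
       xlab = cov_name, ylab = "stationary probability")
  for (i in seq_len(N)) {
    xi <- x[x$state == i, ]
    if (all(is.finite(xi$lower)))
      polygon(c(xi$value, rev(xi$value)), c(xi$lower, rev(xi$upper)),
              col = adjustcolor(cols[i], 0.2), border = NA)
    lines(xi$value, xi$prob, col = cols[i], lwd = 2)
  }
  legend("topright", legend = paste("state", seq_len(N)),
         col = cols[seq_len(N)], lwd = 2, bty = "n")
  invisible(x)
}

#' Forecast pseudo-residuals of a fitted movement HMM
#'
#' One-step-ahead probability-integral-transform residuals per stream,
#' mapped through the standard normal quantile: under a correctly
#' specified model they are standard normal and serially independent.
#' The forecast state distribution conditions on all streams up to the
#' previous interval; zero-inflation atoms are handled by randomized
#' quantile residuals (a uniform draw within the atom's forecast mass,
#' reproducible under `seed`). Missing observations give missing
#' residuals.
#'
#' @param object a fitted `"crab_hmm"`.
#' @param data optional new model-ready data.
#' @param seed optional integer seed for the randomized residuals.
#' @return data.frame of class `"hmm_residuals"` with one residual column
#'   per stream.
#' @export
pseudo_residuals <- function(object, data = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- .fit_spec_for(object, data)
  comp <- .map_components(object, spec)
  em <- object$par$emission
  N <- object$n_states
  out <- vector("list", length(spec$tracks))
  for (i in seq_along(spec$tracks)) {
    tr <- spec$tracks[[i]]
    beta <- .track_beta(object, comp, tr$id)
    L <- .hmm_logdens(tr$obs, em, N, spec$streams)
    tg <- .track_gamma(list(design = tr$design), beta, N)
    delta <- .track_delta(tg$first)
    T_ <- nrow(L)
    # scaled forward (normalized state filters)
    phi <- matrix(NA_real_, T_, N)
    w <- matrix(NA_real_, T_, N)  # forecast weights
    w[1, ] <- delta
    p <- delta * exp(L[1, ] - max(L[1, ]))
    phi[1, ] <- p / sum(p)
    if (T_ > 1) for (t in 2:T_) {
      w[t, ] <- drop(phi[t - 1, ] %*% .gamma_slice(tg, t - 1))
      p <- w[t, ] * exp(L[t, ] - max(L[t, ]))
      phi[t, ] <- p / sum(p)
    }
    res <- data.frame(track_id = spec$track_ids[i], time = tr$time)
    for (s in spec$streams) {
      x <- tr$obs[[s]]
      u <- rep(NA_real_, T_)
      ok <- which(is.finite(x))
      for (t in ok) {
        if (s == "angle") {
          u[t] <- sum(w[t, ] * pwrpcauchy(x[t], 0, em$angle$concentration))
        } else {
          zm <- em[[s]]$zeromass
          if (x[t] == 0) {
            atop <- sum(w[t, ] * zm)
            u[t] <- if (atop > 0) runif(1, 0, atop) else NA_real_
          } else {
            u[t] <- sum(w[t, ] * (zm + (1 - zm) *
                                    pgamma(x[t],
                                           shape = (em[[s]]$mean / em[[s]]$sd)^2,
                                           rate = em[[s]]$mean / em[[s]]$sd^2)))
          }
        }
      }
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      res[[s]] <- qnorm(u)
    }
    out[[i]] <- res
  }
  res <- do.call(rbind, out)
  class(res) <- c("hmm_residuals", "data.frame")
  res
}

#' Rank fitted models by AIC
#'
#' Candidates must be fitted to identical data (same interpolation
#' interval and rows); ranking is by ascending AIC with ties broken by
#' fewer parameters.
#'
#' @param ... fitted `"crab_hmm"` objects, or a single list of them.
#' @return data.frame of class `"hmm_selection"`: model label, `n_states`,
#'   `K`, `npar`, `loglik`, `AIC`, `dAIC`, sorted best first.
#' @export
select_model <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "crab_hmm")) fits <- fits[[1]]
  if (!all(vapply(fits, inherits, logical(1), "crab_hmm")))
    stop("all candidates must be fitted crab_hmm objects")
  fps <- vapply(fits, function(f) f$data_fingerprint, numeric(2))
  if (any(abs(fps - fps[, 1]) > 1e-6 * (1 + abs(fps[, 1]))))
    stop("candidates were fitted on differing data and are not comparable")
  lab <- vapply(fits, function(f)
    paste0(deparse(f$formula), " | N=", f$n_states, ", K=", f$K),
    character(1))
  out <- data.frame(model = lab,
                    n_states = vapply(fits, function(f) f$n_states, numeric(1)),
                    K = vapply(fits, function(f) f$K, numeric(1)),
                    npar = vapply(fits, function(f) f$npar, numeric(1)),
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    AIC = vapply(fits, function(f) f$aic, numeric(1)))
  out <- out[order(out$AIC, out$npar), , drop = FALSE]
  out$dAIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  class(out) <- c("hmm_selection", "data.frame")
  out
}

#' Enumerate candidate transition-covariate formulas
#'
#' All combinations of covariate blocks, with the tidal covariates (tide
#' height, 15-min tide difference and their interaction) always entering
#' together as a single block.
#'
#' @param tide,hour,habitat,temp logical: consider this block?
#' @return list of formulas, starting with the null model `~1`.
#' @export
#' @examples
#' covariate_formulas(tide = TRUE, hour = TRUE)
covariate_formulas <- function(tide = TRUE, hour = TRUE, habitat = FALSE,
                               temp = FALSE) {
  blocks <- c(
    if (tide) "tide * dtide",
    if (hour) "hour_cos + hour_sin",
    if (habitat) "habitat",
    if (temp) "temp")
  out <- list(~1)
  if (length(blocks) == 0) return(out)
  for (n in seq_along(blocks)) {
    combs <- utils::combn(blocks, n, simplify = FALSE)
    for (cb in combs)
      out[[length(out) + 1L]] <-
        stats::as.formula(paste("~", paste(cb, collapse = " + ")))
  }
  out
}

.peak_score_12h <- function(x, delta_min, halfwidth = 20) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 64) return(NA_real_)
  sp <- spec.pgram(x, taper = 0, detrend = TRUE, plot = FALSE, fast = FALSE)
  f0 <- delta_min / 720  # cycles per sample at a 12 h period
  i0 <- which.min(abs(sp$freq - f0))
  centre <- max(sp$spec[max(1, i0 - 1):min(length(sp$spec), i0 + 1)])
  flank_idx <- setdiff(max(1, i0 - halfwidth):min(length(sp$spec), i0 + halfwidth),
                       (i0 - 2):(i0 + 2))
  centre / median(sp$spec[flank_idx])
}

#' Residual diagnostics across interpolation intervals
#'
#' Per residual set and stream: the Kolmogorov-Smirnov distance from the
#' standard normal, short-lag autocorrelation (up to lag 96), and a
#' 12-h-period spectral peak score — the periodogram ordinate at the
#' frequency of a 12 h cycle relative to the median of its neighbours
#' (about 1 for white noise; a score above `threshold` flags unmodelled
#' semidiurnal periodicity).
#'
#' @param sets named list; each element either an `"hmm_residuals"` or a
#'   list `list(residuals = <data.frame>, delta_min = <minutes>)`.
#' @param delta_min grid interval(s) in minutes, recycled over `sets`,
#'   used when an element does not carry its own.
#' @param threshold peak-score detection threshold.
#' @return data.frame with one row per set and stream: `set`, `delta_min`,
#'   `stream`, `n`, `ks_stat`, `lag1_acf`, `max_abs_acf`, `acf_bound`
#'   (approximate white-noise bound `3/sqrt(n)`), `peak_12h`,
#'   `periodic_12h`.
#' @export
residual_diagnostics <- function(sets, delta_min = NULL, threshold = 10) {
  if (inherits(sets, "data.frame")) sets <- list(sets)
  delta_min <- if (is.null(delta_min)) rep(NA_real_, length(sets)) else
    rep_len(delta_min, length(sets))
  nm <- names(sets)
  if (is.null(nm)) nm <- paste0("set", seq_along(sets))
  rows <- list()
  for (k in seq_along(sets)) {
    el <- sets[[k]]
    resid <- if (!is.null(el$residuals)) el$residuals else el
    dm <- if (!is.null(el$delta_min)) el$delta_min else delta_min[k]
    streams <- intersect(c("step", "angle", "accel"), names(resid))
    for (s in streams) {
      x <- resid[[s]]
      r <- x[is.finite(x)]
      n <- length(r)
      if (n < 8) next
      ks <- suppressWarnings(as.numeric(ks.test(r, "pnorm")$statistic))
      ac <- acf(r, lag.max = min(96, n - 2), plot = FALSE)$acf[-1]
      pk <- if (is.finite(dm)) .peak_score_12h(x, dm) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        set = nm[k], delta_min = dm, stream = s, n = n, ks_stat = ks,
        lag1_acf = ac[1], max_abs_acf = max(abs(ac)),
        acf_bound = 3 / sqrt(n), peak_12h = pk,
        periodic_12h = is.finite(pk) && pk > threshold)
    }
  }
  do.call(rbind, rows)
}

#' Pooled per-state occupancy from decoded sequences
#'
#' Fraction of intervals assigned to each state across all tracks (from
#' Viterbi decodes, matching the usual "time spent per behaviour"
#' summary).
#'
#' @param decoded an `"hmm_decode"` data.frame (or list of them).
#' @return named numeric vector of state fractions summing to 1.
#' @export
occupancy <- function(decoded) {
  if (is.list(decoded) && !inherits(decoded, "data.frame"))
    decoded <- do.call(rbind, decoded)
  if (nrow(decoded) == 0) stop("decoded sequences are empty")
  N <- attr(decoded, "n_states")
  if (is.null(N)) N <- max(decoded$state)
  tb <- table(factor(decoded$state, levels = seq_len(N)))
  setNames(as.numeric(tb) / sum(tb), paste0("state", seq_len(N)))
}
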