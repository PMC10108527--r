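# Working-scale parameterization and multi-restart maximum penalized
# likelihood fitting of the movement HMM.

#' Describe the working-scale parameterization of a movement HMM
#'
#' Inspects the data once and fixes the estimation layout: which streams
#' enter (step always; angle/accel when present), whether a zero mass is
#' estimated per stream (only when exact zeros are observed, otherwise it
#' is fixed at 0), the transition design matrix implied by `formula`, and
#' the mixture dimension `K`. Working scale: log means and SDs, logit zero
#' masses and angle concentrations, raw transition coefficients, and
#' multinomial logits for mixture weights.
#'
#' @inheritParams forward_loglik
#' @param K number of transition-matrix mixture components (1 = no random
#'   effect).
#' @param prior_sd SD of the zero-mean normal prior applied to the
#'   working-scale (log) SD parameters to keep estimates off the boundary.
#' @return object of class `"hmm_spec"` used by [penalized_objective()] and
#'   [fit_hmm()].
#' @export
hmm_spec <- function(data, n_states = 2, formula = ~1, K = 1,
                     prior_sd = 100) {
  streams <- character(0)
  est_zm <- c(step = FALSE, accel = FALSE)
  if (is.null(data$step)) stop("'data' must contain a 'step' column")
  streams <- "step"
  est_zm["step"] <- any(data$step == 0, na.rm = TRUE)
  if (!is.null(data$angle) && any(is.finite(data$angle)))
    streams <- c(streams, "angle")
  if (!is.null(data$accel) && any(is.finite(data$accel))) {
    streams <- c(streams, "accel")
    est_zm["accel"] <- any(data$accel == 0, na.rm = TRUE)
  }
  tracks <- .hmm_prepare_tracks(data, formula, streams)
  p <- ncol(tracks[[1]]$design)
  N <- n_states
  M <- N * (N - 1)
  nm <- character(0)
  for (s in intersect(c("step", "accel"), streams)) {
    nm <- c(nm, paste0(s, ".logmean.", 1:N), paste0(s, ".logsd.", 1:N))
    if (est_zm[s]) nm <- c(nm, paste0(s, ".logitzm.", 1:N))
  }
  if ("angle" %in% streams) nm <- c(nm, paste0("angle.logitrho.", 1:N))
  pairs <- .offdiag_pairs(N)
  blabs <- paste0(pairs[1, ], "->", pairs[2, ])
  dn <- colnames(tracks[[1]]$design)
  for (k in seq_len(K))
    nm <- c(nm, paste0(if (K > 1) paste0("k", k, ".") else "", "beta.",
                       rep(blabs, each = p), ".", rep(dn, M)))
  if (K > 1) nm <- c(nm, paste0("logitw.", 2:K))
  out <- list(n_states = N, streams = streams, est_zeromass = est_zm,
              p = p, design_names = dn, M = M, K = K, formula = formula,
              prior_sd = prior_sd, par_names = nm, npar = length(nm),
              tracks = tracks,
              track_ids = names(tracks),
              ids = vapply(tracks, function(tr) as.character(tr$id),
                           character(1)))
  out$sd_idx <- grep("\\.logsd\\.", nm)
  # flattened layout for fast repeated likelihood evaluation
  lens <- vapply(tracks, function(tr) length(tr$obs$step), integer(1))
  ends <- cumsum(lens)
  out$ranges <- cbind(start = c(1L, head(ends, -1) + 1L), end = ends)
  out$n_rows <- sum(lens)
  out$design_all <- do.call(rbind, lapply(tracks, `[[`, "design"))
  out$homog_all <- all(abs(sweep(out$design_all, 2,
                                 out$design_all[1, ])) == 0)
  masks <- list()
  cat_obs <- function(s) unlist(lapply(tracks, function(tr) tr$obs[[s]]),
                                use.names = FALSE)
  for (s in intersect(c("step", "accel"), streams)) {
    v <- cat_obs(s)
    masks[[s]] <- list(pos = which(is.finite(v) & v > 0),
                       zero = which(is.finite(v) & v == 0))
    masks[[s]]$vals <- v[masks[[s]]$pos]
    masks[[s]]$logvals <- log(masks[[s]]$vals)
  }
  if ("angle" %in% streams) {
    v <- cat_obs("angle")
    masks$angle <- list(pos = which(is.finite(v)))
    masks$angle$cosv <- cos(v[masks$angle$pos])
  }
  out$masks <- masks
  class(out) <- "hmm_spec"
  out
}

# log emission densities for all rows at once (fitting fast path)
.spec_logdens_all <- function(emission, spec) {
  N <- spec$n_states
  L <- matrix(0, spec$n_rows, N)
  ms <- spec$masks
  for (i in seq_len(N)) {
    li <- numeric(spec$n_rows)
    for (s in intersect(c("step", "accel"), names(ms))) {
      p <- emission[[s]]
      sh <- (p$mean[i] / p$sd[i])^2
      ra <- p$mean[i] / p$sd[i]^2
      # gamma log-density with scalar shape/rate, avoiding dgamma overhead
      li[ms[[s]]$pos] <- li[ms[[s]]$pos] + log1p(-p$zeromass[i]) +
        sh * log(ra) - lgamma(sh) + (sh - 1) * ms[[s]]$logvals -
        ra * ms[[s]]$vals
      if (length(ms[[s]]$zero))
        li[ms[[s]]$zero] <- li[ms[[s]]$zero] + log(p$zeromass[i])
    }
    if (!is.null(ms$angle)) {
      rho <- emission$angle$concentration[i]
      li[ms$angle$pos] <- li[ms$angle$pos] + log1p(-rho^2) - log(2 * pi) -
        log(1 + rho^2 - 2 * rho * ms$angle$cosv)
    }
    L[, i] <- li
  }
  L
}

#' Map natural-scale parameters to the working scale and back
#'
#' `hmm_pack()` and `hmm_unpack()` are mutual inverses for a given spec.
#'
#' @param par natural-scale parameter list: `emission` (as in
#'   [default_emission_pars()]), `beta` (matrix, or list of K matrices) and
#'   `weights` (length K).
#' @param spec an [hmm_spec()].
#' @return `hmm_pack`: named numeric working vector; `hmm_unpack`: the
#'   natural-scale parameter list.
#' @export
hmm_pack <- function(par, spec) {
  N <- spec$n_states
  w <- numeric(0)
  em <- par$emission
  for (s in intersect(c("step", "accel"), spec$streams)) {
    w <- c(w, log(em[[s]]$mean), log(em[[s]]$sd))
    if (spec$est_zeromass[s]) w <- c(w, qlogis(em[[s]]$zeromass))
  }
  if ("angle" %in% spec$streams) w <- c(w, qlogis(em$angle$concentration))
  beta <- par$beta
  if (!is.list(beta)) beta <- list(beta)
  for (k in seq_len(spec$K)) w <- c(w, as.numeric(beta[[k]]))
  if (spec$K > 1) {
    wt <- par$weights
    w <- c(w, log(wt[-1] / wt[1]))
  }
  stats::setNames(w, spec$par_names)
}

#' @rdname hmm_pack
#' @param working named numeric working-scale vector.
#' @export
hmm_unpack <- function(working, spec) {
  N <- spec$n_states
  pos <- 0L
  take <- function(n) {
    out <- working[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  em <- list()
  for (s in intersect(c("step", "accel"), spec$streams)) {
    em[[s]] <- list(mean = exp(take(N)), sd = exp(take(N)),
                    zeromass = if (spec$est_zeromass[s]) plogis(take(N))
                               else rep(0, N))
    em[[s]] <- lapply(em[[s]], unname)
  }
  if ("angle" %in% spec$streams)
    em$angle <- list(concentration = unname(plogis(take(N))))
  beta <- lapply(seq_len(spec$K), function(k)
    matrix(take(spec$p * spec$M), spec$p, spec$M,
           dimnames = list(spec$design_names, NULL)))
  weights <- if (spec$K > 1) {
    lw <- c(0, take(spec$K - 1))
    exp(lw) / sum(exp(lw))
  } else 1
  list(emission = em, beta = if (spec$K == 1) beta[[1]] else beta,
       weights = unname(weights))
}

.spec_loglik <- function(par, spec) {
  L <- .spec_logdens_all(par$emission, spec)
  N <- spec$n_states
  betas <- if (spec$K == 1) list(par$beta) else par$beta
  ntr <- nrow(spec$ranges)
  ll_mat <- matrix(NA_real_, ntr, spec$K)
  for (k in seq_len(spec$K)) {
    if (spec$homog_all) {
      G1 <- build_transition_matrices(betas[[k]],
                                      spec$design_all[1, , drop = FALSE],
                                      N)[, , 1]
      delta <- .track_delta(G1)
      gam <- as.numeric(G1)
      for (tr in seq_len(ntr)) {
        rows <- spec$ranges[tr, 1]:spec$ranges[tr, 2]
        ll_mat[tr, k] <- forward_loglik_cpp(L[rows, , drop = FALSE],
                                            delta, gam, TRUE)
      }
    } else {
      G <- build_transition_matrices(betas[[k]], spec$design_all, N)
      for (tr in seq_len(ntr)) {
        a <- spec$ranges[tr, 1]; b <- spec$ranges[tr, 2]
        delta <- .track_delta(G[, , a])
        gam <- if (b > a) as.numeric(G[, , a:(b - 1), drop = FALSE]) else
          as.numeric(G[, , a])
        ll_mat[tr, k] <- forward_loglik_cpp(L[a:b, , drop = FALSE],
                                            delta, gam, b == a)
      }
    }
  }
  if (spec$K == 1) return(sum(ll_mat[, 1]))
  total <- 0
  for (m in unique(spec$ids)) {
    lk <- colSums(ll_mat[spec$ids == m, , drop = FALSE]) + log(par$weights)
    mx <- max(lk)
    total <- total + mx + log(sum(exp(lk - mx)))
  }
  total
}

#' Penalized negative log-likelihood on the working scale
#'
#' The negative log-likelihood minus the log-density of a zero-mean normal
#' prior (SD `spec$prior_sd`, default 100) on the working-scale SD
#' parameters of the emission distributions — a numerical device keeping
#' scale estimates off the boundary, negligible away from it (the penalty
#' difference between working values 0 and 1 is 5e-5). Non-finite
#' likelihoods return a large value so optimizers can recover.
#'
#' @param working named working-scale parameter vector.
#' @param spec an [hmm_spec()] (which carries the prepared data).
#' @return scalar objective value (to be minimized).
#' @export
penalized_objective <- function(working, spec) {
  if (any(!is.finite(working))) return(1e10)
  par <- hmm_unpack(working, spec)
  # parameter excursions during optimization can overflow exp(); the
  # resulting non-finite likelihoods are mapped to a large objective
  ll <- tryCatch(suppressWarnings(.spec_loglik(par, spec)),
                 error = function(e) -Inf)
  pen <- -sum(dnorm(working[spec$sd_idx], 0, spec$prior_sd, log = TRUE))
  out <- -ll + pen
  if (!is.finite(out)) 1e10 else out
}

# Moment-based data-driven starting values: cluster the (log) observation
# streams with k-means, take per-cluster moments, order clusters by
# descending step mean.
.hmm_starts <- function(data, spec) {
  N <- spec$n_states
  feat <- cbind(log1p(data$step),
                if ("accel" %in% spec$streams) log1p(data$accel))
  ok <- complete.cases(feat)
  km <- tryCatch(kmeans(feat[ok, , drop = FALSE], centers = N, nstart = 5),
                 error = function(e) NULL)
  cl <- rep(NA_integer_, nrow(data))
  if (!is.null(km)) {
    cl[ok] <- km$cluster
  } else {
    # degenerate clustering: quantile split on step
    qs <- quantile(data$step, probs = seq(0, 1, length.out = N + 1),
                   na.rm = TRUE)
    cl <- as.integer(cut(data$step, unique(c(-Inf, qs[-c(1, N + 1)], Inf))))
    cl[is.na(cl)] <- 1L
  }
  mom <- function(x, cl) {
    mn <- sdv <- zm <- numeric(N)
    for (i in seq_len(N)) {
      xi <- x[which(cl == i & is.finite(x))]
      pos <- xi[xi > 0]
      mn[i] <- if (length(pos)) mean(pos) else max(mean(xi), 1e-3)
      sdv[i] <- if (length(pos) > 1) max(sd(pos), mn[i] / 10) else mn[i]
      zm[i] <- min(max(mean(xi == 0), 1e-3), 0.5)
    }
    list(mean = pmax(mn, 1e-6), sd = pmax(sdv, 1e-6), zeromass = zm)
  }
  st <- mom(data$step, cl)
  ord <- order(st$mean, decreasing = TRUE)
  relab <- match(cl, ord)
  em <- list(step = lapply(mom(data$step, relab), function(v) v))
  if ("accel" %in% spec$streams) em$accel <- mom(data$accel, relab)
  if ("angle" %in% spec$streams) {
    rho <- numeric(N)
    for (i in seq_len(N)) {
      ai <- data$angle[which(relab == i & is.finite(data$angle))]
      rho[i] <- if (length(ai) > 3)
        min(max(sqrt(mean(cos(ai))^2 + mean(sin(ai))^2), 0.05), 0.95)
      else 0.5
    }
    em$angle <- list(concentration = rho)
  }
  if (!spec$est_zeromass["step"]) em$step$zeromass <- rep(0, N)
  if ("accel" %in% spec$streams && !spec$est_zeromass["accel"])
    em$accel$zeromass <- rep(0, N)
  beta0 <- matrix(0, spec$p, spec$M)
  beta0[1, ] <- log(0.1 / 0.9)  # mildly persistent states
  list(emission = em,
       beta = if (spec$K == 1) beta0 else rep(list(beta0), spec$K),
       weights = if (spec$K == 1) 1 else rep(1 / spec$K, spec$K))
}

.check_tide_together <- function(formula) {
  v <- all.vars(formula)
  if (xor("tide" %in% v, "dtide" %in% v))
    stop("tidal covariates must enter together: include both 'tide' and ",
         "'dtide' (or neither)")
  invisible(TRUE)
}

.relabel_perm <- function(par, spec, perm) {
  # perm[a] = old state label occupying new position a
  N <- spec$n_states
  em <- par$emission
  for (s in intersect(c("step", "accel"), names(em)))
    em[[s]] <- lapply(em[[s]], function(v) v[perm])
  if (!is.null(em$angle))
    em$angle$concentration <- em$angle$concentration[perm]
  pairs <- .offdiag_pairs(N)
  colmap <- integer(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    oi <- perm[a]; oj <- perm[b]
    colmap[k] <- which(pairs[1, ] == oi & pairs[2, ] == oj)
  }
  remap <- function(B) B[, colmap, drop = FALSE]
  beta <- if (spec$K == 1) remap(par$beta) else lapply(par$beta, remap)
  list(emission = em, beta = beta, weights = par$weights)
}

.num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' Fit the multivariate movement hidden Markov model
#'
#' Maximum (penalized) likelihood estimation by numerical minimization of
#' [penalized_objective()] from `n_restarts` randomly perturbed
#' data-driven starts (k-means moment starts; standard-normal perturbation
#' on the working scale; the first restart is unperturbed), retaining the
#' best. States are relabelled so state 1 has the largest step mean,
#' making parameter comparisons across fits well defined.
#'
#' @param data model-ready data.frame (see [prepare_hmm_data()] or
#'   [simulate_hmm_data()]): `step` required, `angle`/`accel` used when
#'   present, plus `track_id`, `id` and covariates.
#' @param n_states number of behavioural states (2 or 3 are the
#'   biologically defensible choices here; more states tend to fit noise).
#' @param formula transition covariate formula; tidal covariates `tide`
#'   and `dtide` must enter together.
#' @param K number of transition-matrix mixture components (discrete
#'   individual-level random effect); `K = 1` is a standard HMM.
#' @param n_restarts number of random restarts of the optimizer.
#' @param seed optional integer seed (restart perturbations and k-means).
#' @param maxit maximum BFGS iterations per restart.
#' @param hessian compute and store the working-scale covariance matrix
#'   (inverse observed information) at the optimum?
#' @param prior_sd SD of the boundary-avoidance prior on working-scale SD
#'   parameters.
#' @return object of class `"crab_hmm"`; see also [viterbi()],
#'   [pseudo_residuals()], [stationary_probabilities()], [select_model()].
#' @export
#' @examples
#' d <- simulate_hmm_data(2, 200, seed = 1)
#' fit <- fit_hmm(d, n_states = 2, n_restarts = 2, seed = 1, maxit = 100)
#' fit
fit_hmm <- function(data, n_states = 2, formula = ~1, K = 1,
                    n_restarts = 50, seed = NULL, maxit = 300,
                    hessian = FALSE, prior_sd = 100) {
  cl <- match.call()
  if (!n_states %in% 2:3)
    warning("n_states outside {2, 3}; state proxies beyond 3 rarely map to ",
            "interpretable behaviours")
  .check_tide_together(formula)
  if (!is.null(seed)) set.seed(seed)
  spec <- hmm_spec(data, n_states, formula, K, prior_sd)
  start_par <- .hmm_starts(data, spec)
  w0 <- hmm_pack(start_par, spec)
  obj <- function(w) penalized_objective(w, spec)
  logs <- vector("list", n_restarts)
  starts <- matrix(NA_real_, n_restarts, spec$npar)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    wr <- if (r == 1) w0 else w0 + rnorm(spec$npar)
    starts[r, ] <- wr
    fit <- tryCatch(
      optim(wr, obj, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) {
      logs[[r]] <- data.frame(restart = r, converged = FALSE,
                              objective = NA_real_)
      next
    }
    logs[[r]] <- data.frame(restart = r, converged = fit$convergence == 0,
                            objective = fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  restart_log <- do.call(rbind, logs)
  if (is.null(best) || best$value >= 1e10)
    stop("no HMM restart converged to a finite objective; see the restart log")
  par <- hmm_unpack(best$par, spec)
  perm <- order(par$emission$step$mean, decreasing = TRUE)
  par <- .relabel_perm(par, spec, perm)
  working <- hmm_pack(par, spec)
  loglik <- .spec_loglik(par, spec)
  grad <- tryCatch(.num_grad(obj, working), error = function(e) rep(NA_real_, spec$npar))
  boundary <- any(abs(working) > 15 & grepl("logit|logsd", names(working)))
  out <- list(call = cl, par = par, working = working, spec = spec,
              n_states = n_states, formula = formula, K = K,
              loglik = loglik, penalized = best$value,
              npar = spec$npar, aic = -2 * loglik + 2 * spec$npar,
              convergence = best$convergence == 0,
              grad_norm = sqrt(sum(grad^2)),
              boundary = boundary,
              restart_log = restart_log, restart_starts = starts,
              data = data,
              data_fingerprint = .data_fingerprint(data),
              seed = seed)
  if (hessian) out$vcov <- .hmm_vcov(out)
  class(out) <- "crab_hmm"
  out
}

.data_fingerprint <- function(data) {
  num <- vapply(data, is.numeric, logical(1))
  c(nrow = nrow(data),
    sums = sum(vapply(data[num], function(v) sum(v, na.rm = TRUE), numeric(1))))
}

.hmm_vcov <- function(object) {
  obj <- function(w) penalized_objective(w, object$spec)
  H <- optimHess(object$working, obj)
  V <- tryCatch(solve(H), error = function(e) {
    sv <- svd(H)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
  })
  dimnames(V) <- list(names(object$working), names(object$working))
  V
}

#' @export
vcov.crab_hmm <- function(object, ...) {
  if (!is.null(object$vcov)) object$vcov else .hmm_vcov(object)
}

#' @export
logLik.crab_hmm <- function(object, ...) {
  structure(object$loglik, df = object$npar,
            nobs = object$data_fingerprint["nrow"], class = "logLik")
}

#' @export
coef.crab_hmm <- function(object, ...) object$par

#' @export
print.crab_hmm <- function(x, digits = 3, ...) {
  cat("Movement hidden Markov model (", x$n_states, " states, K = ", x$K,
      ")\n", sep = "")
  cat("  transition formula:", deparse(x$formula), "\n")
  cat(sprintf("  log-likelihood %.2f, %d parameters, AIC %.2f\n",
              x$loglik, x$npar, x$aic))
  em <- x$par$emission
  tab <- rbind(step_mean = em$step$mean, step_sd = em$step$sd,
               step_zeromass = em$step$zeromass,
               angle_concentration = if (!is.null(em$angle))
                 em$angle$concentration)
  if (!is.null(em$accel))
    tab <- rbind(tab, accel_mean = em$accel$mean, accel_sd = em$accel$sd,
                 accel_zeromass = em$accel$zeromass)
  colnames(tab) <- paste("state", seq_len(x$n_states))
  print(round(tab, digits))
  if (!x$convergence) cat("  warning: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
summary.crab_hmm <- function(object, ...) {
  beta <- object$par$beta
  if (!is.list(beta)) beta <- list(beta)
  pairs <- .offdiag_pairs(object$n_states)
  for (k in seq_along(beta))
    colnames(beta[[k]]) <- paste0(pairs[1, ], "->", pairs[2, ])
  G1 <- build_transition_matrices(
    beta[[1]], matrix(colMeans(object$spec$tracks[[1]]$design), 1),
    object$n_states)[, , 1]
  out <- list(fit = object, beta = beta, weights = object$par$weights,
              mean_trmat = G1,
              restart_summary = c(
                n = nrow(object$restart_log),
                converged = sum(object$restart_log$converged, na.rm = TRUE)))
  class(out) <- "summary.crab_hmm"
  out
}

#' @export
print.summary.crab_hmm <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nTransition coefficients (working scale):\n")
  for (k in seq_along(x$beta)) {
    if (length(x$beta) > 1)
      cat(sprintf(" component %d (weight %.3f):\n", k, x$weights[k]))
    print(round(x$beta[[k]], digits))
  }
  cat("\nTransition matrix at mean covariates:\n")
  print(round(x$mean_trmat, digits))
  cat(sprintf("\nRestarts: %d (%d converged); |grad| = %.2e\n",
              x$restart_summary["n"], x$restart_summary["converged"],
              x$fit$grad_norm))
  invisible(x)
}

#' Simulate data from a fitted movement HMM
#'
#' Draws state sequences (per track, using the track's own covariate
#' design; for `K > 1` each individual first draws a mixture component)
#' and observation streams from the fitted state-dependent distributions.
#' Track structure, times and covariates are those of the fitting data.
#'
#' @param object a fitted `"crab_hmm"`.
#' @param nsim number of replicate data sets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data.frame (`nsim = 1`) or list of data.frames shaped like
#'   the fitting data, with a true `state` column.
#' @export
simulate.crab_hmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  spec <- object$spec
  em <- object$par$emission
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    comp <- if (object$K > 1)
      setNames(sample.int(object$K, length(unique(spec$ids)), replace = TRUE,
                          prob = object$par$weights), unique(spec$ids))
    else NULL
    pieces <- vector("list", length(spec$tracks))
    for (i in seq_along(spec$tracks)) {
      tr <- spec$tracks[[i]]
      beta <- if (object$K == 1) object$par$beta else
        object$par$beta[[comp[[as.character(tr$id)]]]]
      st <- simulate_state_sequence(tr$design, beta, object$n_states)
      T_ <- length(st)
      d <- data.frame(id = tr$id, track_id = spec$track_ids[i],
                      time = tr$time, state = st)
      d$step <- rzigamma(T_, em$step$mean[st], em$step$sd[st])
      d$step[runif(T_) < em$step$zeromass[st]] <- 0
      if ("angle" %in% spec$streams)
        d$angle <- vapply(em$angle$concentration[st],
                          function(r) rwrpcauchy(1, 0, r), numeric(1))
      if ("accel" %in% spec$streams) {
        d$accel <- rzigamma(T_, em$accel$mean[st], em$accel$sd[st])
        d$accel[runif(T_) < em$accel$zeromass[st]] <- 0
      }
      d$step[!is.finite(tr$obs$step)] <- NA
      if ("angle" %in% spec$streams) d$angle[!is.finite(tr$obs$angle)] <- NA
      if ("accel" %in% spec$streams) d$accel[!is.finite(tr$obs$accel)] <- NA
      pieces[[i]] <- d
    }
    out[[s]] <- do.call(rbind, pieces)
  }
  if (nsim == 1) out[[1]] else out
}

#' Plot state-dependent distributions over the observations
#'
#' Histograms of each observation stream with the fitted state-dependent
#' densities overlaid (weighted by the decoded time spent in each state).
#'
#' @param x a fitted `"crab_hmm"`.
#' @param which streams to plot.
#' @param breaks histogram breaks.
#' @param ... unused.
#' @export
plot.crab_hmm <- function(x, which = x$spec$streams, breaks = 40, ...) {
  dec <- viterbi(x)
  wts <- as.numeric(table(factor(dec$state, seq_len(x$n_states)))) /
    nrow(dec)
  em <- x$par$emission
  cols <- c("#E6A800", "#5C4B8A", "#2E7D32")
  old <- par(mfrow = c(1, length(which)))
  on.exit(par(old))
  for (s in which) {
    v <- x$data[[s]]
    v <- v[is.finite(v)]
    if (s == "angle") {
      hist(v, breaks = breaks, freq = FALSE, main = "turning angle",
           xlab = "radians", col = "grey85", border = "white")
      for (i in seq_len(x$n_states))
        curve(wts[i] * dwrpcauchy(t, 0, em$angle$concentration[i]),
              xname = "t", add = TRUE, col = cols[i], lwd = 2, n = 400)
    } else {
      vq <- quantile(v, 0.97)
      hist(v[v <= vq], breaks = breaks, freq = FALSE,
           main = s, xlab = if (s == "step") "m" else "m s^-2",
           col = "grey85", border = "white")
      for (i in seq_len(x$n_states))
        curve(wts[i] * (1 - em[[s]]$zeromass[i]) *
                dgamma(t, shape = (em[[s]]$mean[i] / em[[s]]$sd[i])^2,
                       rate = em[[s]]$mean[i] / em[[s]]$sd[i]^2),
              xname = "t", add = TRUE, col = cols[i], lwd = 2, n = 400)
    }
  }
  invisible(x)
}

#' @export
residuals.crab_hmm <- function(object, seed = NULL, ...) {
  pseudo_residuals(object, seed = seed)
}

#' @export
predict.crab_hmm <- function(object, type = c("states", "stateprobs"), ...) {
  type <- match.arg(type)
  dec <- viterbi(object)
  if (type == "states") dec$state else
    dec[, grep("^p_state", names(dec)), drop = FALSE]
}
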