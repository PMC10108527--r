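# Independent oracles used across tests: exhaustive path enumeration for
# the HMM, direct joint-normal assembly for the CTCRW, and quadrature for
# the emission densities. These deliberately avoid the package's forward /
# Kalman implementations.

# log-likelihood by brute-force summation over all N^T state paths
brute_forward <- function(L, delta, G) {
  T_ <- nrow(L)
  N <- ncol(L)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), T_)))
  lp <- apply(paths, 1, function(s) {
    out <- log(delta[s[1]]) + L[1, s[1]]
    if (T_ > 1) for (t in 2:T_) out <- out + log(G[s[t - 1], s[t]]) + L[t, s[t]]
    out
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# most likely path by brute-force argmax over all N^T state paths
brute_viterbi <- function(L, delta, G) {
  T_ <- nrow(L)
  N <- ncol(L)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), T_)))
  lp <- apply(paths, 1, function(s) {
    out <- log(delta[s[1]]) + L[1, s[1]]
    if (T_ > 1) for (t in 2:T_) out <- out + log(G[s[t - 1], s[t]]) + L[t, s[t]]
    out
  })
  unname(paths[which.max(lp), ])
}

# emission log-density matrix computed with the package's densities but
# outside its likelihood plumbing (used to feed the oracles)
logdens_matrix <- function(d, em, n_states) {
  L <- matrix(0, nrow(d), n_states)
  for (i in seq_len(n_states)) {
    if (!is.null(d$step)) {
      ok <- is.finite(d$step)
      L[ok, i] <- L[ok, i] + dzigamma(d$step[ok], em$step$mean[i],
                                      em$step$sd[i], em$step$zeromass[i],
                                      log = TRUE)
    }
    if (!is.null(d$angle)) {
      ok <- is.finite(d$angle)
      L[ok, i] <- L[ok, i] + dwrpcauchy(d$angle[ok], 0,
                                        em$angle$concentration[i], log = TRUE)
    }
    if (!is.null(d$accel) && !is.null(em$accel)) {
      ok <- is.finite(d$accel)
      L[ok, i] <- L[ok, i] + dzigamma(d$accel[ok], em$accel$mean[i],
                                      em$accel$sd[i], em$accel$zeromass[i],
                                      log = TRUE)
    }
  }
  L
}

# random valid HMM parameters for property-style tests
random_hmm_pars <- function(n_states, with_accel = TRUE) {
  em <- list(
    step = list(mean = sort(exp(runif(n_states, -1, 3)), decreasing = TRUE),
                sd = exp(runif(n_states, -1, 2)),
                zeromass = runif(n_states, 0, 0.3)),
    angle = list(concentration = runif(n_states, 0, 0.9)))
  if (with_accel)
    em$accel <- list(mean = exp(runif(n_states, -3, 0)),
                     sd = exp(runif(n_states, -3, 0)),
                     zeromass = runif(n_states, 0, 0.3))
  P <- matrix(runif(n_states^2, 0.05, 1), n_states)
  P <- P / rowSums(P)
  list(emission = em, trmat = P, beta = trmat_to_beta(P))
}

# CTCRW likelihood via the analytically assembled joint normal density of
# all observations (covariances propagated state-by-state, then one
# multivariate normal evaluation)
joint_normal_ctcrw_loglik <- function(track, beta, sigma, R) {
  th <- (track$time - track$time[1]) / 3600
  n <- length(th)
  H <- matrix(c(1, 0, 0, 0, 0, 0, 1, 0), 2, 4, byrow = TRUE)
  init <- crabHMM:::.ctcrw_init(c(track$x[1], track$y[1]), beta, sigma^2)
  mean_s <- matrix(NA_real_, n, 4)
  mean_s[1, ] <- init$a
  Cov <- array(NA_real_, c(4, 4, n, n))
  Cov[, , 1, 1] <- init$P
  for (t in 2:n) {
    m <- crabHMM:::.ctcrw_full_mats(th[t] - th[t - 1], beta, sigma^2)
    mean_s[t, ] <- m$F %*% mean_s[t - 1, ]
    Cov[, , t, t] <- m$F %*% Cov[, , t - 1, t - 1] %*% t(m$F) + m$Q
    for (s in 1:(t - 1)) {
      Cov[, , s, t] <- Cov[, , s, t - 1] %*% t(m$F)
      Cov[, , t, s] <- t(Cov[, , s, t])
    }
  }
  mu <- as.vector(t(mean_s %*% t(H)))
  Sig <- matrix(NA_real_, 2 * n, 2 * n)
  for (s in 1:n) for (t in 1:n)
    Sig[(2 * s - 1):(2 * s), (2 * t - 1):(2 * t)] <-
      H %*% Cov[, , s, t] %*% t(H) + (if (s == t) R else 0)
  z <- as.vector(t(cbind(track$x, track$y)))
  cc <- chol(Sig)
  v <- backsolve(cc, z - mu, transpose = TRUE)
  -0.5 * (2 * n * log(2 * pi)) - sum(log(diag(cc))) - 0.5 * sum(v^2)
}

# wrap a parameter set into a decodable fit object without fitting
fake_fit <- function(data, emission, beta, n_states = 2, formula = ~1,
                     K = 1, weights = 1) {
  spec <- hmm_spec(data, n_states, formula, K)
  structure(list(par = list(emission = emission, beta = beta,
                            weights = weights),
                 spec = spec, n_states = n_states, formula = formula,
                 K = K, data = data,
                 data_fingerprint = crabHMM:::.data_fingerprint(data)),
            class = "crab_hmm")
}
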