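test_that("multinomial-logit transition matrices are exact where invertible by hand", {
  # zero coefficients: maximally mixing
  G <- build_transition_matrices(matrix(0, 1, 2), matrix(1, 3, 1), 2)
  expect_equal(G[, , 2], matrix(0.5, 2, 2))
  # inverting the 2-state logit reproduces a printed dwell structure
  beta <- matrix(c(log(0.09 / 0.91), log(0.04 / 0.96)), 1)
  G2 <- build_transition_matrices(beta, matrix(1, 1, 1), 2)[, , 1]
  expect_equal(G2, matrix(c(0.91, 0.09, 0.04, 0.96), 2, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(G2, default_transition_matrix(), tolerance = 1e-12)
  # a zero covariate coefficient makes the matrices covariate-invariant
  X <- cbind(1, c(-2, 0, 3))
  beta3 <- rbind(c(-1, -2), c(0, 0))
  G3 <- build_transition_matrices(beta3, X, 2)
  expect_equal(G3[, , 1], G3[, , 3])
  expect_error(build_transition_matrices(matrix(0, 2, 2), matrix(1, 3, 1), 2),
               "mismatch")
})

test_that("realized transition matrices are row-stochastic for random coefficients", {
  set.seed(91)
  for (rep_ in 1:20) {
    N <- sample(2:4, 1)
    p <- sample(1:4, 1)
    X <- cbind(1, matrix(rnorm(9 * (p - 1), 0, 2), 9))
    beta <- matrix(rnorm(p * N * (N - 1), 0, 3), p)
    G <- build_transition_matrices(beta, X, N)
    sums <- apply(G, 3, rowSums)
    expect_lt(max(abs(sums - 1)), 1e-12)
    expect_true(all(G >= 0))
  }
})

test_that("forward likelihood equals exhaustive path enumeration", {
  set.seed(92)
  for (rep_ in 1:12) {
    N <- sample(2:3, 1)
    T_ <- sample(2:8, 1)
    pars <- random_hmm_pars(N)
    st <- sample.int(N, T_, replace = TRUE)
    path <- simulate_observations(st, pars$emission)
    d <- data.frame(track_id = "t1", step = path$step, angle = path$angle,
                    accel = path$accel)
    d$step[sample(T_, 1)] <- NA  # missing streams contribute a unit factor
    ll <- forward_loglik(d, pars$emission, pars$beta, N)
    L <- logdens_matrix(d, pars$emission, N)
    expect_equal(ll, brute_forward(L, stationary_dist(pars$trmat),
                                   pars$trmat), tolerance = 1e-10)
  }
})

test_that("forward likelihood satisfies its structural contracts", {
  pars <- random_hmm_pars(2)
  set.seed(93)
  path <- simulate_observations(c(1L, 2L, 2L), pars$emission)
  d1 <- data.frame(track_id = "a", step = path$step[1], angle = NA,
                   accel = path$accel[1])
  # single observation: log of the delta-weighted emission mixture
  delta <- stationary_dist(pars$trmat)
  f <- dzigamma(d1$step, pars$emission$step$mean, pars$emission$step$sd,
                pars$emission$step$zeromass) *
    dzigamma(d1$accel, pars$emission$accel$mean, pars$emission$accel$sd,
             pars$emission$accel$zeromass)
  expect_equal(forward_loglik(d1, pars$emission, pars$beta, 2),
               log(sum(delta * f)), tolerance = 1e-12)
  # duplicating a track doubles the log-likelihood
  d <- data.frame(track_id = "a", step = path$step, angle = path$angle,
                  accel = path$accel)
  d2 <- rbind(d, transform(d, track_id = "b"))
  expect_equal(forward_loglik(d2, pars$emission, pars$beta, 2),
               2 * forward_loglik(d, pars$emission, pars$beta, 2),
               tolerance = 1e-10)
  # everything missing: zero log-likelihood with a warning
  dna <- data.frame(track_id = "a", step = rep(NA_real_, 4),
                    angle = NA_real_, accel = NA_real_)
  expect_warning(ll0 <- forward_loglik(dna, pars$emission, pars$beta, 2),
                 "missing")
  expect_equal(ll0, 0)
})

test_that("likelihood is invariant under state relabelling", {
  set.seed(94)
  d <- simulate_hmm_data(2, 40, seed = 95)
  em <- default_emission_pars()
  beta <- trmat_to_beta(default_transition_matrix())
  ll <- forward_loglik(d, em, beta, 2)
  # swap state labels everywhere
  em2 <- list(step = lapply(em$step, rev),
              angle = list(concentration = rev(em$angle$concentration)),
              accel = lapply(em$accel, rev))
  beta2 <- beta[, 2:1, drop = FALSE]
  expect_equal(forward_loglik(d, em2, beta2, 2), ll, tolerance = 1e-10)
})

test_that("mixture likelihood collapses, degenerates and matches the hand oracle", {
  d <- simulate_hmm_data(4, 6, n_ids = 2, seed = 96)
  em <- default_emission_pars()
  b1 <- trmat_to_beta(default_transition_matrix())
  b2 <- trmat_to_beta(matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE))
  # K = 1 collapses to the plain forward likelihood
  expect_equal(mixture_loglik(d, em, list(b1), 1, 2),
               forward_loglik(d, em, b1, 2), tolerance = 1e-12)
  # identical components: weights are irrelevant
  expect_equal(mixture_loglik(d, em, list(b1, b1), c(0.9, 0.1), 2),
               mixture_loglik(d, em, list(b1, b1), c(0.2, 0.8), 2),
               tolerance = 1e-12)
  # hand-computed mixture of per-individual enumerated likelihoods
  w <- c(0.6, 0.4)
  hand <- 0
  for (m in unique(d$id)) {
    dm <- d[d$id == m, ]
    lks <- vapply(list(b1, b2), function(b) {
      sum(vapply(unique(dm$track_id), function(tid) {
        dt <- dm[dm$track_id == tid, ]
        L <- logdens_matrix(dt, em, 2)
        G <- build_transition_matrices(b, matrix(1, 1, 1), 2)[, , 1]
        brute_forward(L, stationary_dist(G), G)
      }, numeric(1)))
    }, numeric(1))
    hand <- hand + log(sum(w * exp(lks)))
  }
  expect_equal(mixture_loglik(d, em, list(b1, b2), w, 2), hand,
               tolerance = 1e-10)
  expect_warning(mixture_loglik(d, em, list(b1, b2, b2), c(.3, .3, .4), 2),
                 "weakly identified")
})

test_that("working and natural scales are mutual inverses", {
  set.seed(97)
  d <- simulate_hmm_data(2, 60, seed = 98)
  d$step[c(3, 40)] <- 0   # ensure both zero masses are estimated
  d$accel[c(7, 55)] <- 0
  for (K in c(1, 2)) {
    spec <- hmm_spec(d, 2, ~1, K)
    pars <- random_hmm_pars(2)
    par <- list(emission = pars$emission,
                beta = if (K == 1) pars$beta else
                  list(pars$beta, pars$beta * 0.5),
                weights = if (K == 1) 1 else c(0.3, 0.7))
    w <- hmm_pack(par, spec)
    par2 <- hmm_unpack(w, spec)
    for (s in c("step", "accel"))
      expect_equal(par2$emission[[s]], par$emission[[s]], tolerance = 1e-12)
    expect_equal(par2$emission$angle, par$emission$angle, tolerance = 1e-12)
    if (K == 1) expect_equal(unname(par2$beta), unname(par$beta),
                             tolerance = 1e-12)
    else {
      expect_equal(unname(par2$beta[[2]]), unname(par$beta[[2]]),
                   tolerance = 1e-12)
      expect_equal(par2$weights, par$weights, tolerance = 1e-12)
    }
    expect_equal(unname(hmm_pack(par2, spec)), unname(w), tolerance = 1e-12)
  }
})

test_that("the boundary-avoidance prior is negligible away from the boundary", {
  # emission without zero inflation so the spec layout matches the
  # parameter list exactly (no zeros observed, zero masses fixed at 0)
  em0 <- default_emission_pars()
  em0$step$zeromass <- c(0, 0)
  em0$accel$zeromass <- c(0, 0)
  d <- simulate_hmm_data(1, 50, emission = em0, seed = 99)
  spec <- hmm_spec(d, 2, ~1, 1)
  par <- list(emission = em0, beta =
                trmat_to_beta(default_transition_matrix()), weights = 1)
  w <- hmm_pack(par, spec)
  base <- penalized_objective(w, spec)
  w1 <- w
  sd1 <- spec$sd_idx[1]
  # closed form: moving one SD working parameter from its value v to v+1
  # changes the penalty by ((v+1)^2 - v^2) / (2 * 100^2)
  w1[sd1] <- w1[sd1] + 1
  dpen <- (w1[sd1]^2 - w[sd1]^2) / (2 * 100^2)
  obj1 <- penalized_objective(w1, spec)
  ll0 <- forward_loglik(d, par$emission, par$beta, 2)
  ll1 <- forward_loglik(d, hmm_unpack(w1, spec)$emission,
                        hmm_unpack(w1, spec)$beta, 2)
  expect_equal(unname((obj1 - base) - (ll0 - ll1)), unname(dpen),
               tolerance = 1e-9)
  # and the objective differs from the plain NLL by a bounded constant
  expect_equal(base, -ll0 - sum(dnorm(w[spec$sd_idx], 0, 100, log = TRUE)),
               tolerance = 1e-9)
})

test_that("fitting recovers well-separated parameters and honours the argmin contract", {
  d <- simulate_hmm_data(4, 500, seed = 101)
  fit <- suppressWarnings(fit_hmm(d, n_states = 2, n_restarts = 3,
                                  seed = 102))
  # argmin contract
  expect_true(all(fit$penalized <= fit$restart_log$objective + 1e-6,
                  na.rm = TRUE))
  expect_true(fit$convergence)
  # canonical ordering: state 1 is the fast state
  expect_gt(fit$par$emission$step$mean[1], fit$par$emission$step$mean[2])
  truth <- default_emission_pars()
  expect_equal(fit$par$emission$step$mean, truth$step$mean, tolerance = 0.1)
  expect_equal(fit$par$emission$accel$mean, truth$accel$mean,
               tolerance = 0.1)
  expect_equal(fit$par$emission$angle$concentration,
               truth$angle$concentration, tolerance = 0.1)
  # AIC identity
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$npar)
  expect_equal(AIC(fit), fit$aic)
  # tidal covariates must enter together
  expect_error(fit_hmm(transform(d, tide = 1), formula = ~tide),
               "together")
})

test_that("fit methods expose coherent summaries, decoding and simulation", {
  d <- simulate_hmm_data(2, 300, seed = 103)
  fit <- suppressWarnings(fit_hmm(d, n_states = 2, n_restarts = 2,
                                  seed = 104))
  expect_output(print(fit), "Movement hidden Markov model")
  expect_output(print(summary(fit)), "Transition matrix")
  expect_named(coef(fit), c("emission", "beta", "weights"))
  expect_s3_class(logLik(fit), "logLik")
  sim <- simulate(fit, seed = 105)
  expect_equal(nrow(sim), nrow(d))
  expect_true(all(c("step", "angle", "accel", "state") %in% names(sim)))
  expect_identical(simulate(fit, seed = 105), sim)
  st <- predict(fit)
  expect_true(all(st %in% 1:2))
})
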