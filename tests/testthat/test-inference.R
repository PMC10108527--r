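test_that("Viterbi matches exhaustive argmax and dominates pointwise decoding", {
  set.seed(111)
  for (rep_ in 1:8) {
    N <- sample(2:3, 1)
    T_ <- sample(3:8, 1)
    pars <- random_hmm_pars(N)
    st <- sample.int(N, T_, replace = TRUE)
    path <- simulate_observations(st, pars$emission)
    d <- data.frame(track_id = "t", step = path$step, angle = path$angle,
                    accel = path$accel)
    fit <- fake_fit(d, pars$emission, pars$beta, N)
    dec <- viterbi(fit)
    L <- logdens_matrix(d, pars$emission, N)
    delta <- stationary_dist(pars$trmat)
    expect_equal(dec$state, brute_viterbi(L, delta, pars$trmat))
    # smoothed probabilities are a proper distribution
    P <- as.matrix(dec[, paste0("p_state", seq_len(N))])
    expect_equal(rowSums(P), rep(1, T_), tolerance = 1e-10)
    # global path scores at least as high as the pointwise-MAP path
    score <- function(s) {
      out <- log(delta[s[1]]) + L[1, s[1]]
      for (t in seq_len(T_)[-1]) out <- out +
          log(pars$trmat[s[t - 1], s[t]]) + L[t, s[t]]
      out
    }
    expect_gte(score(dec$state), score(apply(P, 1, which.max)) - 1e-10)
  }
})

test_that("decoding degenerates correctly at the information extremes", {
  # identical emissions: the path follows the stickier state's equilibrium
  em_same <- list(step = list(mean = c(1, 1), sd = c(1, 1),
                              zeromass = c(0, 0)),
                  angle = list(concentration = c(0.5, 0.5)))
  P <- matrix(c(0.99, 0.01, 0.2, 0.8), 2, byrow = TRUE)
  set.seed(112)
  d <- data.frame(track_id = "t", step = rgamma(40, 1), angle =
                    rwrpcauchy(40, 0, 0.5))
  fit <- fake_fit(d, em_same, trmat_to_beta(P), 2)
  expect_true(all(viterbi(fit)$state == 1))
  # disjoint supports: decoding recovers the generating states exactly
  em_sep <- list(step = list(mean = c(1000, 0.01), sd = c(50, 0.005),
                             zeromass = c(0, 0)),
                 angle = list(concentration = c(0.2, 0.2)))
  st <- simulate_state_sequence(matrix(1, 300, 1),
                                trmat_to_beta(default_transition_matrix()),
                                2, seed = 113)
  path <- simulate_observations(st, em_sep, seed = 114)
  d2 <- data.frame(track_id = "t", step = path$step, angle = path$angle)
  fit2 <- fake_fit(d2, em_sep, trmat_to_beta(default_transition_matrix()), 2)
  expect_equal(viterbi(fit2)$state, st)
})

test_that("stationary probabilities solve pi P = pi with closed-form checks", {
  # printed two-state dwell structure: pi = (0.04, 0.09) / 0.13
  expect_equal(stationary_dist(default_transition_matrix()),
               c(0.04 / 0.13, 0.09 / 0.13), tolerance = 1e-12)
  # symmetric near-identity matrix: equal occupancy
  Ps <- matrix(c(1 - 1e-4, 1e-4, 1e-4, 1 - 1e-4), 2)
  expect_equal(stationary_dist(Ps), c(0.5, 0.5))
  expect_error(stationary_dist(matrix(c(1, 0, 0, 1), 2)), "stationary")
})

test_that("stationary curves are coherent and carry delta-method intervals", {
  set.seed(115)
  n <- 1200
  tide <- 1 + sin(2 * pi * (1:n) * 900 / (12.42 * 3600))
  dtide <- c(0, diff(tide))
  X <- cbind(1, tide, dtide)
  beta_true <- rbind(trmat_to_beta(default_transition_matrix()),
                     c(0.8, -0.5), c(4, -2))
  s <- simulate_state_sequence(X, beta_true, 2, seed = 116)
  path <- simulate_observations(s, default_emission_pars(), seed = 117)
  d <- data.frame(id = "c", track_id = "t", time = (1:n - 1) * 900,
                  step = path$step, angle = path$angle, accel = path$accel,
                  tide = tide, dtide = dtide)
  fit <- suppressWarnings(fit_hmm(d, 2, formula = ~ tide + dtide,
                                  n_restarts = 2, seed = 118))
  sc <- stationary_probabilities(fit, "tide", values = c(0, 0.5, 1, 1.5, 2))
  for (v in unique(sc$value))
    expect_equal(sum(sc$prob[sc$value == v]), 1, tolerance = 1e-10)
  expect_true(all(sc$lower >= 0 & sc$upper <= 1))
  expect_true(all(sc$lower <= sc$prob & sc$prob <= sc$upper))
  # foraging is favoured at low tide under the generating coefficients
  p1 <- sc$prob[sc$state == 1]
  expect_gt(p1[1], p1[length(p1)])
})

test_that("pseudo-residuals of a well-specified model are standard normal and white", {
  d <- simulate_hmm_data(1, 10000, seed = 119)
  fit <- fake_fit(d, default_emission_pars(),
                  trmat_to_beta(default_transition_matrix()), 2)
  pr <- pseudo_residuals(fit, seed = 120)
  for (s in c("step", "angle", "accel")) {
    r <- pr[[s]]
    r <- r[is.finite(r)]
    expect_gt(suppressWarnings(ks.test(r, "pnorm"))$p.value, 0.01)
    # whiteness over 20 lags x 3 streams: Bonferroni-adjusted normal bound
    ac <- acf(r, lag.max = 20, plot = FALSE)$acf[-1]
    expect_lt(max(abs(ac)), 4 / sqrt(length(r)))
  }
  # randomized residuals are reproducible under the seed
  expect_identical(pseudo_residuals(fit, seed = 120), pr)
})

test_that("pseudo-residuals detect a misspecified emission model", {
  d <- simulate_hmm_data(1, 4000, seed = 121)
  wrong <- default_emission_pars()
  wrong$step$mean <- wrong$step$mean * 3
  fit <- fake_fit(d, wrong, trmat_to_beta(default_transition_matrix()), 2)
  pr <- pseudo_residuals(fit, seed = 122)
  r <- pr$step[is.finite(pr$step)]
  expect_lt(suppressWarnings(ks.test(r, "pnorm"))$p.value, 0.01)
})

test_that("AIC ranking selects parsimonious truth and is order-invariant", {
  d <- simulate_hmm_data(4, 400, seed = 123)
  fit0 <- suppressWarnings(fit_hmm(d, 2, n_restarts = 2, seed = 124))
  d$fake <- rnorm(nrow(d))
  fit1 <- suppressWarnings(fit_hmm(d, 2, formula = ~fake, n_restarts = 2,
                                   seed = 125))
  sel <- select_model(fit0, fit1)
  # the generating (null) model wins on AIC over the noise covariate
  expect_equal(sel$model[1], paste0(deparse(fit0$formula), " | N=2, K=1"))
  expect_equal(sel$dAIC[1], 0)
  sel2 <- select_model(fit1, fit0)
  expect_equal(sel$model, sel2$model)
  # identical candidates tie and keep the smaller parameter count first
  selt <- select_model(fit0, fit0)
  expect_equal(selt$dAIC, c(0, 0))
  # differing data refuse to rank
  d2 <- simulate_hmm_data(4, 401, seed = 126)
  fit2 <- suppressWarnings(fit_hmm(d2, 2, n_restarts = 1, seed = 127))
  expect_error(select_model(fit0, fit2), "not comparable")
})

test_that("mixtures beyond the generating K = 1 cost AIC", {
  d <- simulate_hmm_data(6, 250, n_ids = 3, seed = 128)
  f1 <- suppressWarnings(fit_hmm(d, 2, K = 1, n_restarts = 2, seed = 129))
  f2 <- suppressWarnings(fit_hmm(d, 2, K = 2, n_restarts = 2, seed = 130))
  sel <- select_model(f1, f2)
  expect_equal(sel$K[1], 1)
  expect_gt(f2$aic, f1$aic)
})

test_that("candidate formula enumeration keeps tidal covariates together", {
  fl <- covariate_formulas(tide = TRUE, hour = TRUE, habitat = TRUE,
                           temp = TRUE)
  expect_length(fl, 16)  # all subsets of 4 blocks
  for (f in fl) {
    v <- all.vars(f)
    expect_false(xor("tide" %in% v, "dtide" %in% v))
    if ("tide" %in% v)
      expect_true(any(grepl("tide:dtide|tide \\* dtide",
                            deparse(f))))
  }
  expect_length(covariate_formulas(FALSE, FALSE, FALSE, FALSE), 1)
})

test_that("the periodogram diagnostic scores semidiurnal residual structure", {
  set.seed(131)
  n <- 3000
  white <- data.frame(step = rnorm(n), angle = rnorm(n))
  dg <- residual_diagnostics(list(white = white), delta_min = 15)
  expect_true(all(dg$peak_12h < 10))
  expect_false(any(dg$periodic_12h))
  expect_true(all(dg$ks_stat < 0.05))
  # inject a 12 h sinusoid (period 48 samples at 15 min)
  per <- data.frame(step = rnorm(n) + 1.5 * sin(2 * pi * (1:n) / 48))
  dg2 <- residual_diagnostics(list(periodic = per), delta_min = 15)
  expect_gt(dg2$peak_12h, 50)
  expect_true(dg2$periodic_12h)
  # a shifted period is not flagged at the 12 h line
  off <- data.frame(step = rnorm(n) + 1.5 * sin(2 * pi * (1:n) / 17))
  dg3 <- residual_diagnostics(list(off = off), delta_min = 15)
  expect_false(dg3$periodic_12h)
})

test_that("occupancy pools decoded fractions and matches the ergodic limit", {
  dec <- data.frame(track_id = "t", time = 1:5, state = c(2, 2, 2, 2, 2))
  attr(dec, "n_states") <- 2
  expect_equal(occupancy(dec), c(state1 = 0, state2 = 1))
  # long homogeneous chain: occupancy approaches the stationary law
  em_sep <- list(step = list(mean = c(1000, 0.01), sd = c(50, 0.005),
                             zeromass = c(0, 0)),
                 angle = list(concentration = c(0.2, 0.2)))
  st <- simulate_state_sequence(matrix(1, 20000, 1),
                                trmat_to_beta(default_transition_matrix()),
                                2, seed = 132)
  path <- simulate_observations(st, em_sep, seed = 133)
  d <- data.frame(track_id = "t", step = path$step, angle = path$angle)
  fit <- fake_fit(d, em_sep, trmat_to_beta(default_transition_matrix()), 2)
  occ <- occupancy(viterbi(fit))
  expect_equal(unname(occ), c(0.04 / 0.13, 0.09 / 0.13), tolerance = 0.05)
  expect_equal(sum(occ), 1)
})
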