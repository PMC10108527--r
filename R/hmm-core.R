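# Core likelihood machinery of the multivariate movement HMM.
#
# Observation streams: step length and RMS acceleration (zero-inflated
# gamma, log links on mean/SD, logit link on the zero mass) and turning
# angle (wrapped Cauchy, mean fixed at 0, logit link on the concentration).
# Transitions: multinomial logit in time-varying covariates; off-diagonal
# (i, j) entries are ordered row-wise. Optional discrete-mixture random
# effect: K transition coefficient sets with individual-level weights.

.offdiag_pairs <- function(N) {
  out <- matrix(0L, 2, N * (N - 1))
  k <- 0L
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    k <- k + 1L
    out[, k] <- c(i, j)
  }
  out
}

#' Build transition probability matrices from the multinomial-logit model
#'
#' For each design row, off-diagonal entries are
#' `P_ij = exp(eta_ij) / (1 + sum_j' exp(eta_ij'))` with `eta_ij` the linear
#' predictor for the (i, j) transition, and the diagonal is the remainder,
#' so every realized matrix is row-stochastic.
#'
#' @param beta coefficient matrix, `p x N(N-1)` (off-diagonals row-wise:
#'   1->2, 1->3, ..., 2->1, ...).
#' @param design numeric design matrix, `T x p`.
#' @param n_states number of states `N`.
#' @return array `N x N x T` of transition matrices.
#' @export
#' @examples
#' build_transition_matrices(matrix(0, 1, 2), matrix(1, 3, 1), 2)
build_transition_matrices <- function(beta, design, n_states) {
  design <- as.matrix(design)
  N <- n_states
  M <- N * (N - 1)
  beta <- as.matrix(beta)
  if (ncol(beta) != M) stop("'beta' must have N(N-1) columns")
  if (nrow(beta) != ncol(design))
    stop("design/beta dimension mismatch: ", ncol(design), " design columns vs ",
         nrow(beta), " coefficient rows")
  eta <- design %*% beta
  T_ <- nrow(design)
  G <- array(0, c(N, N, T_))
  for (i in seq_len(N)) {
    cols <- ((i - 1) * (N - 1) + 1):(i * (N - 1))
    e <- eta[, cols, drop = FALSE]
    mx <- pmax(apply(e, 1, max), 0)
    ex <- exp(e - mx)
    denom <- exp(-mx) + rowSums(ex)
    js <- setdiff(seq_len(N), i)
    for (k in seq_along(js)) G[i, js[k], ] <- ex[, k] / denom
    G[i, i, ] <- exp(-mx) / denom
  }
  G
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi %*% P = pi`, `sum(pi) = 1`.
#'
#' @param P an `N x N` row-stochastic matrix (irreducible, aperiodic).
#' @return numeric vector of stationary probabilities.
#' @export
stationary_dist <- function(P) {
  N <- nrow(P)
  pi_ <- tryCatch(solve(t(diag(N) - P + 1), rep(1, N)),
                  error = function(e) NULL)
  if (is.null(pi_) || any(!is.finite(pi_)) || any(pi_ < -1e-8))
    stop("transition matrix has no valid stationary distribution")
  pi_ <- pmax(pi_, 0)
  pi_ / sum(pi_)
}

# log emission density matrix (T x N); missing streams contribute 0.
.hmm_logdens <- function(obs, emission, n_states, streams) {
  T_ <- length(obs$step)
  L <- matrix(0, T_, n_states)
  for (i in seq_len(n_states)) {
    li <- numeric(T_)
    if ("step" %in% streams) {
      ok <- is.finite(obs$step)
      li[ok] <- li[ok] + dzigamma(obs$step[ok], emission$step$mean[i],
                                  emission$step$sd[i],
                                  emission$step$zeromass[i], log = TRUE)
    }
    if ("angle" %in% streams) {
      ok <- is.finite(obs$angle)
      li[ok] <- li[ok] + dwrpcauchy(obs$angle[ok], 0,
                                    emission$angle$concentration[i],
                                    log = TRUE)
    }
    if ("accel" %in% streams) {
      ok <- is.finite(obs$accel)
      li[ok] <- li[ok] + dzigamma(obs$accel[ok], emission$accel$mean[i],
                                  emission$accel$sd[i],
                                  emission$accel$zeromass[i], log = TRUE)
    }
    L[, i] <- li
  }
  L
}

# Split model-ready data into per-track prepared pieces (obs vectors,
# design matrix, individual id), validating alignment once.
.hmm_prepare_tracks <- function(data, formula, streams) {
  if (is.null(data$track_id)) data$track_id <- "track1"
  if (is.null(data$id)) data$id <- data$track_id
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  design <- stats::model.matrix(formula, mf)
  if (anyNA(design))
    stop("covariates used in the transition formula contain missing values; ",
         "drop or impute those intervals before fitting")
  idx <- split(seq_len(nrow(data)), data$track_id)
  idx <- idx[unique(data$track_id)]  # preserve first-appearance order
  lapply(idx, function(ii) {
    if (!is.null(data$time) && is.unsorted(data$time[ii]))
      ii <- ii[order(data$time[ii])]
    list(obs = list(step = data$step[ii],
                    angle = if ("angle" %in% names(data)) data$angle[ii] else rep(NA_real_, length(ii)),
                    accel = if ("accel" %in% names(data)) data$accel[ii] else rep(NA_real_, length(ii))),
         design = design[ii, , drop = FALSE],
         id = data$id[ii[1]],
         time = if (is.null(data$time)) seq_along(ii) else data$time[ii])
  })
}

.track_gamma <- function(track, beta, n_states) {
  design <- track$design
  homog <- nrow(design) == 1 ||
    all(abs(sweep(design, 2, design[1, ])) < 1e-300)
  if (homog) {
    G <- build_transition_matrices(beta, design[1, , drop = FALSE], n_states)
    list(gamma = G, homogeneous = TRUE, first = G[, , 1])
  } else {
    G <- build_transition_matrices(beta, design, n_states)
    list(gamma = G, homogeneous = FALSE, first = G[, , 1])
  }
}

.track_delta <- function(G1) {
  tryCatch(stationary_dist(G1),
           error = function(e) rep(1 / nrow(G1), nrow(G1)))
}

.track_loglik <- function(track, emission, beta, n_states, streams) {
  L <- .hmm_logdens(track$obs, emission, n_states, streams)
  tg <- .track_gamma(track, beta, n_states)
  delta <- .track_delta(tg$first)
  gam <- if (tg$homogeneous) as.numeric(tg$gamma[, , 1]) else {
    T_ <- nrow(L)
    # slices 1..T-1 govern transitions into times 2..T
    as.numeric(tg$gamma[, , seq_len(max(T_ - 1, 1)), drop = FALSE])
  }
  forward_loglik_cpp(L, delta, gam, tg$homogeneous)
}

#' Forward-algorithm log-likelihood of the movement HMM
#'
#' Scaled forward recursion summed over tracks. Per time step the emission
#' density is the product over available streams (missing observations
#' contribute a factor of 1); each track's initial state distribution is
#' the stationary distribution of its first interval's transition matrix.
#'
#' @param data model-ready data.frame: columns `step`, optionally `angle`
#'   and `accel`, optionally `track_id`, `id`, `time`, plus any covariates
#'   named in `formula`.
#' @param emission state-dependent parameters (see
#'   [default_emission_pars()]); streams present in both `emission` and
#'   `data` enter the likelihood.
#' @param beta transition coefficient matrix, `p x N(N-1)`.
#' @param n_states number of states.
#' @param formula transition covariate formula (RHS only), e.g.
#'   `~ tide * dtide`.
#' @return total log-likelihood (scalar).
#' @export
forward_loglik <- function(data, emission, beta,
                           n_states = length(emission$step$mean),
                           formula = ~1) {
  emission <- validate_emission(emission, n_states)
  streams <- .active_streams(data, emission)
  tracks <- .hmm_prepare_tracks(data, formula, streams)
  if (all(vapply(tracks, function(tr)
    all(!is.finite(tr$obs$step)) && all(!is.finite(tr$obs$angle)) &&
      all(!is.finite(tr$obs$accel)), logical(1)))) {
    warning("all observation streams are missing everywhere; log-likelihood is 0")
  }
  sum(vapply(tracks, .track_loglik, numeric(1),
             emission = emission, beta = beta, n_states = n_states,
             streams = streams))
}

.active_streams <- function(data, emission) {
  streams <- character(0)
  if (!is.null(data$step)) streams <- c(streams, "step")
  if (!is.null(data$angle)) streams <- c(streams, "angle")
  if (!is.null(data$accel) && any(is.finite(data$accel)) &&
      !is.null(emission$accel)) streams <- c(streams, "accel")
  streams
}

#' Mixture (discrete random effect) log-likelihood
#'
#' Individual-level discrete random effect on the transition dynamics: the
#' behavioural dynamics of each individual are governed by one of `K`
#' transition coefficient sets, so the likelihood of individual m is
#' `sum_k w_k * L_m(beta_k)`, combined on the log scale with log-sum-exp
#' stabilization and summed over individuals.
#'
#' @inheritParams forward_loglik
#' @param beta_list list of `K` coefficient matrices.
#' @param weights mixture weights (length `K`, summing to 1).
#' @param id_col column of `data` identifying individuals.
#' @return total log-likelihood (scalar).
#' @export
mixture_loglik <- function(data, emission, beta_list, weights,
                           n_states = length(emission$step$mean),
                           formula = ~1, id_col = "id") {
  K <- length(beta_list)
  if (length(weights) != K || abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must have length K and sum to 1")
  if (!id_col %in% names(data)) stop("column '", id_col, "' not found")
  data$id <- data[[id_col]]
  emission <- validate_emission(emission, n_states)
  streams <- .active_streams(data, emission)
  tracks <- .hmm_prepare_tracks(data, formula, streams)
  ids <- vapply(tracks, function(tr) as.character(tr$id), character(1))
  if (K > length(unique(ids)))
    warning("K exceeds the number of individuals; mixture weights are weakly identified")
  ll_mat <- vapply(seq_len(K), function(k)
    vapply(tracks, .track_loglik, numeric(1), emission = emission,
           beta = beta_list[[k]], n_states = n_states, streams = streams),
    numeric(length(tracks)))
  ll_mat <- matrix(ll_mat, nrow = length(tracks))
  total <- 0
  for (m in unique(ids)) {
    lk <- colSums(ll_mat[ids == m, , drop = FALSE]) + log(weights)
    mx <- max(lk)
    total <- total + mx + log(sum(exp(lk - mx)))
  }
  total
}
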