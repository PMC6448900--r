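# Intensity matrix, Weibull operational-time transition probabilities and the
# interval-censored panel likelihood.

#' Build the 4x4 transition intensity matrix for one covariate vector
#'
#' Each permitted intensity is the log-linear predictor
#' `lambda_ij = exp(b0_ij + sum_C b_ij^C (C - center_C))`; forbidden entries
#' are 0 and each diagonal entry makes its row sum to zero. Intensities are
#' per year of operational time `u = t^alpha`.
#'
#' @param model A [transition_model()].
#' @param covariates Named list or vector with a complete (non-missing) value
#'   for every covariate active in the model.
#' @return A 4x4 generator matrix `Q`.
#' @export
build_intensity_matrix <- function(model, covariates = NULL) {
  active <- colnames(model$coefficients)
  eta <- model$intercepts
  if (length(active)) {
    x <- unlist(covariates)[active]
    if (anyNA(x) || length(x) != length(active))
      stop("missing covariate value(s) for: ",
           paste(active[is.na(x) | !(active %in% names(unlist(covariates)))],
                 collapse = ", "),
           "; impute before building intensities (see worst_case_impute or ",
           "multiple_impute)")
    eta <- eta + as.vector(model$coefficients %*% (x - model$centering[active]))
  }
  lam <- pmax(exp(eta), 1e-12)
  tr <- dr_transitions()
  Q <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
  Q[tr] <- lam
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix over an interval in operational time
#'
#' `P(t1, t2) = expm(Q (t2^alpha - t1^alpha))`: operational time
#' `u = t^alpha` accumulates from the subject's baseline, making the process
#' a homogeneous Markov chain in `u`. With `t1 = 0` this is the one-argument
#' matrix `P(t) = expm(Q t^alpha)`.
#'
#' @param Q 4x4 generator from [build_intensity_matrix()].
#' @param t1,t2 Interval endpoints in years, `0 <= t1 <= t2`.
#' @param alpha Weibull shape parameter.
#' @return A 4x4 stochastic matrix; row `i` is the distribution over states
#'   at `t2` given state `i` at `t1`.
#' @export
transition_probability <- function(Q, t1 = 0, t2, alpha = 0.9) {
  if (t2 < t1) stop("t2 must be >= t1")
  if (t1 < 0) stop("times must be non-negative")
  if (alpha <= 0) stop("alpha must be positive")
  du <- t2^alpha - t1^alpha
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * du)))
  # numerical cleanup: entries may stray from [0,1] by rounding error only
  stopifnot(all(P > -1e-9), all(P < 1 + 1e-9))
  P <- pmin(pmax(P, 0), 1)
  dimnames(P) <- list(1:4, 1:4)
  P
}

#' State occupancy distribution after t years
#'
#' @param Q 4x4 generator.
#' @param t Elapsed time in years from baseline.
#' @param alpha Weibull shape parameter.
#' @param start_state Integer state 1-4 occupied at time 0.
#' @return Probability vector over the four states at time `t`.
#' @export
state_occupancy <- function(Q, t, alpha = 0.9, start_state) {
  start_state <- as.integer(start_state)
  if (!start_state %in% 1:4) stop("start_state must be in 1..4")
  transition_probability(Q, 0, t, alpha)[start_state, ]
}

# Flatten a panel into one row per observation interval: subject, from-state,
# to-state, endpoint times, covariates at the left endpoint (piecewise
# constant between episodes).
.interval_frame <- function(data, covariates = character(0),
                            baseline_duration = TRUE) {
  df <- as.data.frame(data)
  if (baseline_duration) df <- .fix_baseline_duration(df)
  n <- nrow(df)
  same <- df$subject_id[-1L] == df$subject_id[-n]
  left <- which(same)
  out <- data.frame(subject_id = df$subject_id[left],
                    from = df$state[left],
                    to = df$state[left + 1L],
                    t1 = df$time_years[left],
                    t2 = df$time_years[left + 1L],
                    stringsAsFactors = FALSE)
  for (cv in covariates) {
    if (!cv %in% names(df)) stop("panel lacks covariate column ", cv)
    out[[cv]] <- df[[cv]][left]
  }
  out
}

.nll_eval <- function(iv, X, beta0, B, alpha, want_grad = FALSE) {
  .panel_nll_cpp(beta0, B, alpha,
                 as.integer(iv$from), as.integer(iv$to),
                 iv$t1, iv$t2, X, want_grad)
}

#' Interval-censored panel log-likelihood
#'
#' Sum over all subjects and observation intervals of
#' `log P[s_k-1, s_k](t_k-1, t_k)`, with the generator rebuilt from the
#' covariates recorded at each interval's left endpoint. Arrival in the
#' screen-positive state is interval-censored like any other move: its
#' contribution is the `(s, 4)` entry of the interval transition matrix, so
#' the unknown true transition time never enters.
#'
#' @param data A [panel_data()] with complete covariate values for the
#'   model's active covariates (run imputation first if needed).
#' @param model A [transition_model()].
#' @param baseline_duration Hold `disease_duration` at its baseline value
#'   within each subject (default) rather than updating it per episode.
#' @return The log-likelihood. If any observation interval has probability
#'   zero under the model, `-Inf` is returned with attribute
#'   `"bad_interval"` naming the offending subject and interval.
#' @export
panel_log_likelihood <- function(data, model, baseline_duration = TRUE) {
  active <- colnames(model$coefficients)
  iv <- .interval_frame(data, active, baseline_duration)
  X <- .centered_design(iv, model)
  if (anyNA(X))
    stop("missing covariate values; impute before evaluating the likelihood")
  res <- .nll_eval(iv, X, model$intercepts, model$coefficients, model$alpha)
  ll <- res$loglik
  if (!is.finite(ll) && res$bad_interval > 0) {
    bad <- res$bad_interval
    attr(ll, "bad_interval") <-
      sprintf("subject %s, interval (%.3g, %.3g], states %d -> %d",
              iv$subject_id[bad], iv$t1[bad], iv$t2[bad],
              iv$from[bad], iv$to[bad])
  }
  ll
}

.centered_design <- function(iv, model) {
  active <- colnames(model$coefficients)
  if (!length(active))
    return(matrix(0, nrow(iv), 0))
  X <- as.matrix(iv[active])
  sweep(X, 2L, model$centering[active])
}
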