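# Event-driven cohort simulator.  Generates screening panel datasets with the
# statistical structure the model assumes (four-state progression under
# log-linear intensities and Weibull operational time, observed only at
# roughly annual visits), so fitting, prediction and validation can be
# exercised end to end without patient data.

#' Reference per-unit hazard ratios
#'
#' Central per-unit hazard ratios for the five clinical covariates on each
#' permitted transition, representative of an established UK screening
#' cohort; used as the simulator's default truth.
#'
#' @return 6x5 matrix (transitions by covariates) of hazard ratios.
#' @export
reference_hazard_ratios <- function() {
  m <- rbind(
    "1-2" = c(1.00450, 1.0280,  1.0101,  0.963,  1.00409),
    "2-1" = c(1.00580, 0.983,   0.998,   1.0153, 0.999),
    "2-3" = c(0.989,   1.0261,  1.00621, 0.965,  0.998),
    "2-4" = c(1.0245,  0.989,   1.00554, 1.0231, 1.00342),
    "3-2" = c(1.00839, 0.959,   0.990,   1.0836, 0.997),
    "3-4" = c(0.986,   1.00420, 1.0164,  1.0346, 1.00501))
  colnames(m) <- dr_covariates()
  m
}

#' Reference baseline 1-year transition probabilities
#'
#' Probabilities, at cohort-mean covariates, of each permitted observed
#' transition over one year; the simulator's baseline intensities are
#' calibrated so that `expm(Q)` reproduces them.
#'
#' @return Named numeric vector over the six permitted transitions.
#' @export
reference_transition_probs <- function() {
  c("1-2" = 0.114, "2-1" = 0.552, "2-3" = 0.141,
    "2-4" = 0.0163, "3-2" = 0.283, "3-4" = 0.0574)
}

.default_cov_means <- function() {
  c(age_at_diagnosis = 55, disease_duration = 8, hba1c = 58,
    total_cholesterol = 4.9, systolic_bp = 134)
}

.default_cov_sds <- function() {
  c(age_at_diagnosis = 12, disease_duration = 5.5, hba1c = 14,
    total_cholesterol = 1.1, systolic_bp = 16)
}

.default_cov_corr <- function() {
  covs <- dr_covariates()
  R <- diag(5)
  dimnames(R) <- list(covs, covs)
  R["disease_duration", "hba1c"] <- R["hba1c", "disease_duration"] <- 0.20
  R["age_at_diagnosis", "systolic_bp"] <-
    R["systolic_bp", "age_at_diagnosis"] <- 0.15
  R["hba1c", "total_cholesterol"] <- R["total_cholesterol", "hba1c"] <- 0.10
  R
}

.cov_lower <- c(age_at_diagnosis = 18, disease_duration = 0, hba1c = 25,
                total_cholesterol = 2, systolic_bp = 85)
.cov_upper <- c(age_at_diagnosis = 90, disease_duration = 40, hba1c = 130,
                total_cholesterol = 10, systolic_bp = 220)

#' Calibrate baseline log-intensities to 1-year transition probabilities
#'
#' Finds a generator `Q` with the permitted sparsity pattern whose matrix
#' exponential reproduces the six target 1-year observed-transition
#' probabilities. A principal-matrix-logarithm of a completed probability
#' matrix (projected onto the permitted pattern) provides the starting
#' point; a least-squares refinement over the six log-intensities finishes
#' the job.
#'
#' @param target_probs Named vector over the six transitions (`"1-2"`, ...),
#'   each row's targets summing to less than 1.
#' @param alpha Weibull shape; irrelevant at t = 1 year (operational time 1)
#'   but kept for interface symmetry.
#' @param tol Maximum acceptable absolute residual on any target entry.
#' @return Named vector of baseline log-intensities (intercepts), with
#'   attributes `Q` (the calibrated generator) and `achieved` (the fitted
#'   probabilities).
#' @export
calibrate_baseline_intensities <- function(target_probs, alpha = 0.9,
                                           tol = 1e-3) {
  labs <- .tr_labels()
  if (!all(labs %in% names(target_probs)))
    stop("target_probs must be named by the six permitted transitions")
  p <- target_probs[labs]
  if (any(p <= 0) || any(p >= 1)) stop("target probabilities must be in (0,1)")
  tr <- dr_transitions()
  rowsum_t <- vapply(1:3, function(i) sum(p[tr[, 1L] == i]), 0.0)
  if (any(rowsum_t >= 1))
    stop("infeasible targets: transition probabilities out of state ",
         paste(which(rowsum_t >= 1), collapse = ", "),
         " sum to 1 or more (stochasticity violated)")

  # complete a plausible 1-year probability matrix for the log start point
  P0 <- diag(4)
  P0[1, 2] <- p["1-2"]; P0[1, 3] <- 0.01; P0[1, 4] <- 0.002
  P0[1, 1] <- 1 - sum(P0[1, 2:4])
  P0[2, 1] <- p["2-1"]; P0[2, 3] <- p["2-3"]; P0[2, 4] <- p["2-4"]
  P0[2, 2] <- 1 - P0[2, 1] - P0[2, 3] - P0[2, 4]
  P0[3, 2] <- p["3-2"]; P0[3, 4] <- p["3-4"]; P0[3, 1] <- 0.02
  P0[3, 3] <- 1 - P0[3, 1] - P0[3, 2] - P0[3, 4]
  eg <- eigen(P0)
  L <- Re(eg$vectors %*% diag(log(as.complex(eg$values))) %*%
            solve(eg$vectors))
  lam0 <- pmax(L[tr], 1e-4)

  obj <- function(loglam) {
    Q <- matrix(0, 4, 4)
    Q[tr] <- exp(loglam)
    diag(Q) <- -rowSums(Q)
    sum((.expm_cpp(Q)[tr] - p)^2)
  }
  opt <- stats::nlminb(log(lam0), obj,
                       control = list(iter.max = 500, abs.tol = 1e-18))
  Q <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
  Q[tr] <- exp(opt$par)
  diag(Q) <- -rowSums(Q)
  achieved <- .expm_cpp(Q)[tr]
  resid <- max(abs(achieved - p))
  if (resid > tol)
    stop("no valid generator reproduces the targets within ", tol,
         " (best residual ", format(resid, digits = 3), ")")
  structure(stats::setNames(opt$par, labs),
            Q = Q, achieved = stats::setNames(achieved, labs))
}

.ref_model_cache <- new.env(parent = emptyenv())

#' Reference transition model used as the simulator's default truth
#'
#' Combines the reference per-unit hazard ratios, baseline intensities
#' calibrated to the reference 1-year transition probabilities, the default
#' covariate means as centering constants and Weibull shape `alpha`.
#'
#' @param alpha Weibull shape, default 0.9.
#' @return A [transition_model()].
#' @export
reference_model <- function(alpha = 0.9) {
  key <- format(alpha, digits = 12)
  if (is.null(.ref_model_cache[[key]])) {
    intercepts <- calibrate_baseline_intensities(reference_transition_probs(),
                                                 alpha)
    .ref_model_cache[[key]] <- transition_model(
      intercepts, log(reference_hazard_ratios()), alpha,
      centering = .default_cov_means())
  }
  .ref_model_cache[[key]]
}

#' Simulation configuration
#'
#' Defines the study conditions of a simulated screening cohort: cohort
#' size, the true transition model, covariate distributions (truncated
#' multivariate normal), the visit schedule (roughly annual with jitter) and
#' the missing-at-random covariate masking rate.
#'
#' @param n_subjects Number of subjects.
#' @param model True [transition_model()]; default [reference_model()].
#' @param n_visits Scheduled visits per subject (including baseline),
#'   default 5.
#' @param gap_mean,gap_sd Mean and SD of inter-visit gaps in years (default
#'   1 and 0.15); gaps are truncated below at `gap_min`.
#' @param gap_min Minimum gap, default 0.25 years.
#' @param init_probs Baseline state distribution over states 1-3, default
#'   `c(0.60, 0.25, 0.15)`.
#' @param cov_means,cov_sds Named covariate means and SDs; `cov_sds = 0`
#'   fixes every subject at the means (useful for baseline checks).
#' @param cov_corr 5x5 covariate correlation matrix.
#' @param miss_rate Per-cell MCAR covariate masking probability in
#'   `[0, 0.2]` (the model excludes covariates below 80% completeness).
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects, model = reference_model(),
                       n_visits = 5L, gap_mean = 1.0, gap_sd = 0.15,
                       gap_min = 0.25, init_probs = c(0.60, 0.25, 0.15),
                       cov_means = .default_cov_means(),
                       cov_sds = .default_cov_sds(),
                       cov_corr = .default_cov_corr(),
                       miss_rate = 0, seed = 1L) {
  if (n_subjects < 1L) stop("n_subjects must be positive")
  if (miss_rate < 0 || miss_rate > 0.2)
    stop("miss_rate must lie in [0, 0.2] (80% completeness rule)")
  if (length(init_probs) != 3L || any(init_probs < 0) || sum(init_probs) <= 0)
    stop("init_probs must be three non-negative weights over states 1-3")
  structure(list(n_subjects = as.integer(n_subjects), model = model,
                 n_visits = as.integer(n_visits), gap_mean = gap_mean,
                 gap_sd = gap_sd, gap_min = gap_min,
                 init_probs = init_probs / sum(init_probs),
                 cov_means = cov_means, cov_sds = cov_sds,
                 cov_corr = cov_corr, miss_rate = miss_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.draw_covariates <- function(n, config) {
  covs <- dr_covariates()
  mu <- config$cov_means[covs]
  sd <- if (!is.null(names(config$cov_sds))) config$cov_sds[covs]
        else rep(config$cov_sds, length.out = 5L)
  if (all(sd == 0)) {
    X <- matrix(rep(mu, each = n), nrow = n, dimnames = list(NULL, covs))
    return(as.data.frame(X))
  }
  R <- config$cov_corr[covs, covs]
  Z <- matrix(stats::rnorm(n * 5L), n, 5L) %*% chol(R)
  X <- sweep(sweep(Z, 2L, sd, `*`), 2L, mu, `+`)
  colnames(X) <- covs
  for (cv in covs)
    X[, cv] <- pmin(pmax(X[, cv], .cov_lower[[cv]]), .cov_upper[[cv]])
  as.data.frame(X)
}

#' Simulate a screening cohort
#'
#' Each subject's four-state chain is simulated exactly in operational time
#' `u = t^alpha` by competing exponential clocks with intensities from the
#' true model and the subject's (baseline-fixed) covariates; visit times are
#' drawn from the jittered-annual schedule, the state is recorded only at
#' visits (panel observation), and the sequence is truncated after the first
#' observed screen-positive. MCAR covariate masking is applied last. The
#' whole procedure is deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A [panel_data()] with attribute `truth`: a data.frame of exact
#'   transition times and states per subject (hidden from the fitting path).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  model <- config$model
  alpha <- model$alpha
  set.seed(config$seed)
  n <- config$n_subjects
  covdf <- .draw_covariates(n, config)
  active <- colnames(model$coefficients)
  eta <- matrix(rep(model$intercepts, each = n), n, 6L)
  if (length(active)) {
    Xc <- sweep(as.matrix(covdf[active]), 2L, model$centering[active])
    eta <- eta + Xc %*% t(model$coefficients)
  }
  lam_all <- exp(eta)  # n x 6, per-subject permitted intensities
  if (all(lam_all[, dr_transitions()[, 1L] == 1L] < 1e-14))
    stop("no dynamics: all intensities out of state 1 are zero")
  tr <- dr_transitions()
  out_states <- lapply(1:3, function(s) which(tr[, 1L] == s))
  s0 <- sample.int(3L, n, replace = TRUE, prob = config$init_probs)

  ep <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    # visit schedule
    gaps <- pmax(stats::rnorm(config$n_visits - 1L, config$gap_mean,
                              config$gap_sd), config$gap_min)
    visits <- cumsum(c(0, gaps))
    u_max <- max(visits)^alpha
    lam <- lam_all[i, ]
    # exact chain in operational time
    ev_t <- numeric(0); ev_s <- integer(0)
    s <- s0[i]; u <- 0
    while (s != 4L) {
      ks <- out_states[[s]]
      rates <- lam[ks]
      rtot <- sum(rates)
      if (rtot <= 0) break
      u <- u + stats::rexp(1L, rtot)
      if (u > u_max) break
      s <- tr[ks[sample.int(length(ks), 1L, prob = rates)], 2L]
      ev_t <- c(ev_t, u^(1 / alpha)); ev_s <- c(ev_s, s)
    }
    # observed state at each visit = state after last event before the visit
    st <- vapply(visits, function(tv) {
      k <- sum(ev_t <= tv)
      if (k == 0L) s0[i] else ev_s[k]
    }, 0L)
    pos <- which(st == 4L)
    keep <- if (length(pos)) seq_len(pos[1L]) else seq_along(visits)
    id <- sprintf("S%05d", i)
    ep[[i]] <- data.frame(subject_id = id,
                          time_years = visits[keep],
                          state = st[keep],
                          stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(subject_id = id,
                             time_years = c(0, ev_t),
                             state = c(s0[i], ev_s),
                             stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, ep)
  for (cv in dr_covariates())
    df[[cv]] <- covdf[[cv]][match(df$subject_id, sprintf("S%05d", seq_len(n)))]
  if (config$miss_rate > 0) {
    cells <- as.matrix(df[dr_covariates()])
    mask <- matrix(stats::runif(length(cells)) < config$miss_rate,
                   nrow(cells), ncol(cells))
    cells[mask] <- NA_real_
    df[dr_covariates()] <- cells
  }
  res <- panel_data(df)
  attr(res, "truth") <- do.call(rbind, truth)
  res
}
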