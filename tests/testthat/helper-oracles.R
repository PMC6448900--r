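# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths (matrix exponential, rank formulas) so
# agreement is evidence, not tautology.

# Transition probabilities by uniformization: P(u) = sum_k Pois(k; L u) M^k
# with M = I + Q/L.  Exact up to the truncation of the Poisson tail.
oracle_tpm <- function(Q, u, K = 300L) {
  L <- max(-diag(Q)) * 1.01 + 1e-9
  M <- diag(4) + Q / L
  P <- diag(4) * exp(-L * u)
  term <- diag(4)
  for (k in seq_len(K)) {
    term <- term %*% M
    P <- P + exp(-L * u + k * log(L * u) - lgamma(k + 1)) * term
  }
  P
}

# Panel log-likelihood by summing oracle interval probabilities directly.
oracle_loglik <- function(data, model) {
  df <- as.data.frame(data)
  ll <- 0
  for (id in unique(df$subject_id)) {
    s <- df[df$subject_id == id, , drop = FALSE]
    x <- if (ncol(model$coefficients)) as.list(s[1, dr_covariates()]) else NULL
    Q <- build_intensity_matrix(model, x)
    for (k in 2:nrow(s)) {
      du <- s$time_years[k]^model$alpha - s$time_years[k - 1]^model$alpha
      ll <- ll + log(oracle_tpm(Q, du)[s$state[k - 1], s$state[k]])
    }
  }
  as.numeric(ll)
}

# Concordance by exhaustive double loop over subject pairs.
oracle_cindex <- function(risk, outcomes) {
  o <- outcomes
  r <- risk[o$subject_id]
  conc <- 0; npair <- 0
  for (i in seq_len(nrow(o))) {
    if (!o$positive[i] || is.na(o$event_time[i])) next
    for (j in seq_len(nrow(o))) {
      comparable <-
        (o$positive[j] && !is.na(o$event_time[j]) &&
           o$event_time[j] > o$event_time[i]) ||
        (!o$positive[j] && o$follow_up[j] >= o$event_time[i])
      if (!comparable) next
      npair <- npair + 1
      if (r[i] > r[j]) conc <- conc + 1
      else if (r[i] == r[j]) conc <- conc + 0.5
    }
  }
  conc / npair
}

# AUC by exhaustive case/control pair counting.
oracle_auc <- function(case_risk, control_risk) {
  cnt <- 0
  for (a in case_risk) for (b in control_risk)
    cnt <- cnt + (a > b) + 0.5 * (a == b)
  cnt / (length(case_risk) * length(control_risk))
}

# A tiny hand-built valid panel: `spec` is a list of per-subject lists with
# times, states and optional covariate values recycled across episodes.
toy_panel <- function(spec) {
  rows <- lapply(names(spec), function(id) {
    s <- spec[[id]]
    d <- data.frame(subject_id = id, time_years = s$times, state = s$states,
                    stringsAsFactors = FALSE)
    for (cv in setdiff(names(s), c("times", "states"))) d[[cv]] <- s[[cv]]
    d
  })
  panel_data(do.call(rbind, rows))
}

# Random generator matrix with the permitted sparsity, intensities <= rmax.
random_Q <- function(rmax = 2) {
  tr <- dr_transitions()
  Q <- matrix(0, 4, 4)
  Q[tr] <- stats::runif(6, 0.01, rmax)
  diag(Q) <- -rowSums(Q)
  Q
}
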