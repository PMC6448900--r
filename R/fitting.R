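# Maximum-likelihood estimation, Wald statistics, AICc and the nested
# covariate-selection procedure.

.par_pack <- function(beta0, B, alpha, est_alpha) {
  p <- c(beta0, as.vector(B))
  if (est_alpha) p <- c(p, log(alpha))
  p
}

.par_unpack <- function(par, ncov, est_alpha, alpha_fixed) {
  beta0 <- par[1:6]
  B <- matrix(if (ncov) par[6L + seq_len(6L * ncov)] else numeric(0),
              nrow = 6L, ncol = ncov)
  alpha <- if (est_alpha) exp(par[length(par)]) else alpha_fixed
  list(beta0 = beta0, B = B, alpha = alpha)
}

.par_names <- function(covariates, est_alpha) {
  labs <- .tr_labels()
  nm <- paste0("intercept.", labs)
  for (cv in covariates) nm <- c(nm, paste0("coef.", labs, ".", cv))
  if (est_alpha) nm <- c(nm, "log_alpha")
  nm
}

# Crude occurrence/exposure starting rates: observed one-step panel jumps
# over time at risk in the left-endpoint state.
.crude_start <- function(iv) {
  tr <- dr_transitions()
  dt <- iv$t2 - iv$t1
  expo <- vapply(1:3, function(s) sum(dt[iv$from == s]), 0.0)
  log(vapply(seq_len(6L), function(k) {
    cnt <- sum(iv$from == tr[k, 1L] & iv$to == tr[k, 2L])
    (cnt + 0.5) / (expo[tr[k, 1L]] + 1)
  }, 0.0))
}

#' Fit the progression model by maximum likelihood
#'
#' Maximises the interval-censored panel log-likelihood over the six
#' transition intercepts, the log hazard-ratio coefficients of the requested
#' covariates (each covariate enters all six transitions) and, unless fixed,
#' the Weibull shape `alpha` (searched on the log scale within (0, 2]).
#' Optimisation is quasi-Newton (L-BFGS-B) with analytic gradients; standard
#' errors come from the inverse observed information at the optimum.
#'
#' @param data A [panel_data()] with no missing values in `covariates`.
#' @param covariates Character vector of active covariates (subset of
#'   [dr_covariates()]); empty for the retinopathy-state-only model.
#' @param fix_alpha If non-NULL, hold the Weibull shape at this value.
#' @param baseline_duration Hold disease duration at its baseline value.
#' @param start Optional [transition_model()] supplying starting values.
#' @param control List: `maxit` (default 400), `factr`, `pgtol`.
#' @return An object of class `rce_fit`: the fitted [transition_model()]
#'   (with centering constants set to cohort means at first screening),
#'   maximised log-likelihood, parameter covariance, convergence
#'   diagnostics, `n_subjects` and `n_parameters`.
#' @export
fit_mle <- function(data, covariates = character(0), fix_alpha = NULL,
                    baseline_duration = TRUE, start = NULL,
                    control = list()) {
  covariates <- as.character(covariates)
  bad <- setdiff(covariates, dr_covariates())
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  iv <- .interval_frame(data, covariates, baseline_duration)
  est_alpha <- is.null(fix_alpha)
  ncov <- length(covariates)

  base <- baseline_episodes(data)
  centering <- vapply(covariates, function(cv) mean(base[[cv]], na.rm = TRUE), 0.0)
  X <- if (ncov) sweep(as.matrix(iv[covariates]), 2L, centering)
       else matrix(0, nrow(iv), 0L)
  if (anyNA(X))
    stop("missing covariate values; run multiple_impute first")
  # standardise columns so the optimisation is well conditioned; coefficients
  # are rescaled back to per-unit terms afterwards
  xscale <- if (ncov) pmax(apply(X, 2L, stats::sd), 1e-8) else numeric(0)
  if (ncov) X <- sweep(X, 2L, xscale, `/`)

  if (is.null(start)) {
    beta0 <- .crude_start(iv)
    B <- matrix(0, 6L, ncov)
    alpha0 <- if (est_alpha) 1.0 else fix_alpha
  } else {
    beta0 <- start$intercepts
    B <- matrix(0, 6L, ncov)
    common <- intersect(covariates, colnames(start$coefficients))
    B[, match(common, covariates)] <- start$coefficients[, common]
    B <- sweep(B, 2L, xscale, `*`)
    alpha0 <- if (est_alpha) start$alpha else fix_alpha
  }
  par0 <- .par_pack(beta0, B, alpha0, est_alpha)

  fn <- function(par) {
    th <- .par_unpack(par, ncov, est_alpha, fix_alpha)
    ll <- .nll_eval(iv, X, th$beta0, th$B, th$alpha)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  gr <- function(par) {
    th <- .par_unpack(par, ncov, est_alpha, fix_alpha)
    r <- .nll_eval(iv, X, th$beta0, th$B, th$alpha, want_grad = TRUE)
    if (!is.finite(r$loglik)) return(rep(0, length(par)))
    g <- c(r$grad_beta0, as.vector(r$grad_B))
    if (est_alpha) g <- c(g, r$grad_alpha * th$alpha)  # chain rule, log scale
    -g
  }

  npar <- length(par0)
  lower <- rep(-Inf, npar); upper <- rep(Inf, npar)
  # floor on the log intensities: transitions with no observed events drift
  # to an effectively-zero rate instead of -Inf
  lower[1:6] <- -25
  par0[1:6] <- pmax(par0[1:6], -25)
  if (est_alpha) { lower[npar] <- log(0.05); upper[npar] <- log(2) }
  ctl <- list(maxit = control$maxit %||% 400L,
              factr = control$factr %||% 1e7,
              pgtol = control$pgtol %||% 1e-5)
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper, control = ctl)
  if (opt$convergence > 1L) {
    # a line-search abort near the intensity floor usually clears on a
    # restart (the quasi-Newton memory is reset at the current point)
    opt <- stats::optim(opt$par, fn, gr, method = "L-BFGS-B",
                        lower = lower, upper = upper, control = ctl)
  }
  if (opt$convergence > 1L)
    stop("optimiser failed to converge: ", opt$message,
         " (best log-likelihood ", format(-opt$value), ")")

  th <- .par_unpack(opt$par, ncov, est_alpha, fix_alpha)
  gvec <- gr(opt$par)
  hess <- try(stats::optimHess(opt$par, fn, gr), silent = TRUE)
  vcov <- NULL; se_ok <- FALSE
  if (!inherits(hess, "try-error")) {
    vc <- try(solve(hess), silent = TRUE)
    if (!inherits(vc, "try-error") && all(is.finite(vc)) &&
        all(diag(vc) > 0)) {
      vcov <- (vc + t(vc)) / 2
      se_ok <- TRUE
    }
  }
  if (!se_ok) warning("observed information is singular; standard errors unavailable")

  # map standardised coefficients (and their covariance) back to per-unit scale
  scale_vec <- rep(1, npar)
  if (ncov) scale_vec[6L + seq_len(6L * ncov)] <- rep(1 / xscale, each = 6L)
  th$B <- th$B / matrix(rep(xscale, each = 6L), 6L, ncov)
  opt$par <- opt$par * scale_vec
  if (se_ok) vcov <- vcov * tcrossprod(scale_vec)

  coefs <- if (ncov) {
    dimnames(th$B) <- list(.tr_labels(), covariates); th$B
  } else NULL
  model <- transition_model(th$beta0, coefs, th$alpha, centering)
  pn <- .par_names(covariates, est_alpha)
  if (se_ok) dimnames(vcov) <- list(pn, pn)
  structure(list(model = model,
                 loglik = -opt$value,
                 par = stats::setNames(opt$par, pn),
                 vcov = vcov,
                 se_available = se_ok,
                 convergence = opt$convergence,
                 gradient_norm = max(abs(gvec)),
                 n_subjects = n_subjects(data),
                 n_parameters = 6L + 6L * ncov + as.integer(est_alpha),
                 covariates = covariates,
                 alpha_estimated = est_alpha),
            class = "rce_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rce_fit <- function(x, ...) {
  cat("Panel MLE fit: log-likelihood ", format(x$loglik, digits = 8),
      ", ", x$n_parameters, " parameters, ", x$n_subjects, " subjects\n",
      sep = "")
  print(x$model)
  invisible(x)
}

#' Wald confidence intervals for the per-unit hazard ratios
#' @param fit An [fit_mle()] result with available standard errors.
#' @param level Confidence level, default 0.95.
#' @return Data frame with one row per (transition, covariate): estimate and
#'   confidence bounds on the hazard-ratio scale.
#' @export
hazard_ratio_ci <- function(fit, level = 0.95) {
  if (!fit$se_available) stop("standard errors unavailable for this fit")
  nm <- names(fit$par)
  idx <- grep("^coef\\.", nm)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(fit$vcov))[idx]
  est <- fit$par[idx]
  data.frame(term = nm[idx],
             hr = exp(est),
             lower = exp(est - z * se),
             upper = exp(est + z * se),
             row.names = NULL)
}

#' Joint Wald statistic for one covariate
#'
#' The chi-square form `b' V^-1 b` over the covariate's six
#' transition-specific coefficients, used to rank candidates before building
#' the nested model sequence.
#'
#' @param fit An [fit_mle()] result.
#' @param covariate Covariate name, active in the fit.
#' @return The Wald chi-square statistic (6 degrees of freedom when all six
#'   coefficients are estimated).
#' @export
wald_statistic <- function(fit, covariate) {
  if (!covariate %in% fit$covariates)
    stop("covariate '", covariate, "' is not active in this fit")
  if (!fit$se_available) stop("standard errors unavailable for this fit")
  idx <- grep(paste0("^coef\\..*\\.", covariate, "$"), names(fit$par))
  b <- fit$par[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  as.numeric(t(b) %*% solve(V, b))
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 l + 2k + 2k(k+1)/(n - k - 1)` with `k` the parameter count and
#' `n` the number of subjects (the independent units of a panel).
#'
#' @param fit An [fit_mle()] result.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  k <- fit$n_parameters
  n <- fit$n_subjects
  if (n <= k + 1) stop("AICc undefined: n_subjects <= n_parameters + 1")
  -2 * fit$loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Percentage of explained likelihood along a nested sequence
#'
#' `100 (l_k - l_base) / (l_full - l_base)`, where the base model uses
#' retinopathy state only and the full model carries every candidate
#' covariate. All three fits must be on the same data.
#'
#' @param fit_k,fit_base,fit_full Nested [fit_mle()] results.
#' @return Percentage in `[0, 100]` for a proper nested sequence.
#' @export
explained_likelihood <- function(fit_k, fit_base, fit_full) {
  lb <- if (is.numeric(fit_base)) fit_base else fit_base$loglik
  lf <- if (is.numeric(fit_full)) fit_full else fit_full$loglik
  lk <- if (is.numeric(fit_k)) fit_k else fit_k$loglik
  if (lf == lb) stop("full and base models have equal likelihood")
  100 * (lk - lb) / (lf - lb)
}

#' Wald-ranked nested covariate selection
#'
#' Fits the full model with every candidate covariate, ranks candidates by
#' their joint Wald statistics, then builds the nested sequence: baseline
#' (retinopathy state only), then one model per added covariate in rank
#' order. Each model's AICc is computed; the model with the smallest AICc is
#' selected. The table reports the rescaled AICc (0 at the minimum) and the
#' percentage of explained likelihood relative to the baseline and full
#' models.
#'
#' @param data A complete (imputed) [panel_data()].
#' @param candidates Candidate covariates, default all of [dr_covariates()].
#' @param fix_alpha Optional fixed Weibull shape (speeds up selection runs).
#' @param marginal Rank by one-at-a-time marginal Wald statistics instead of
#'   the joint full-model statistics.
#' @param ... Passed to [fit_mle()].
#' @return A `selection_table`: data.frame with columns `label`, `wald`,
#'   `aicc`, `rescaled_aicc`, `explained_pct`, `selected`, plus attributes
#'   `fits` (the nested fit list) and `selected_covariates`.
#' @export
select_covariates <- function(data, candidates = dr_covariates(),
                              fix_alpha = NULL, marginal = FALSE, ...) {
  fit_full <- fit_mle(data, candidates, fix_alpha = fix_alpha, ...)
  wald <- if (marginal) {
    vapply(candidates, function(cv) {
      f <- fit_mle(data, cv, fix_alpha = fix_alpha, ...)
      wald_statistic(f, cv)
    }, 0.0)
  } else {
    vapply(candidates, function(cv) wald_statistic(fit_full, cv), 0.0)
  }
  ord <- order(wald, decreasing = TRUE)
  ranked <- candidates[ord]

  labels <- c("retinopathy state (baseline)", paste0("+ ", ranked))
  fits <- vector("list", length(ranked) + 1L)
  aiccs <- rep(NA_real_, length(fits))
  lls <- rep(NA_real_, length(fits))
  for (i in seq_along(fits)) {
    active <- if (i == 1L) character(0) else ranked[seq_len(i - 1L)]
    f <- try(fit_mle(data, active, fix_alpha = fix_alpha, ...), silent = TRUE)
    if (inherits(f, "try-error")) next
    fits[[i]] <- f
    aiccs[i] <- aicc(f)
    lls[i] <- f$loglik
  }
  expl <- vapply(lls, function(l) {
    if (is.na(l)) return(NA_real_)
    explained_likelihood(l, lls[1L], fit_full$loglik)
  }, 0.0)
  resc <- aiccs - min(aiccs, na.rm = TRUE)
  sel <- which.min(aiccs)
  tab <- data.frame(label = labels,
                    wald = c(NA_real_, wald[ord]),
                    aicc = aiccs,
                    rescaled_aicc = resc,
                    explained_pct = expl,
                    selected = seq_along(labels) == sel,
                    row.names = NULL)
  attr(tab, "fits") <- fits
  attr(tab, "selected_covariates") <-
    if (sel == 1L) character(0) else ranked[seq_len(sel - 1L)]
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' @export
print.selection_table <- function(x, ...) {
  cat("Nested covariate selection (smallest AICc selected)\n")
  df <- as.data.frame(x)
  df$wald <- round(df$wald, 1)
  df$aicc <- round(df$aicc, 2)
  df$rescaled_aicc <- round(df$rescaled_aicc, 2)
  df$explained_pct <- round(df$explained_pct, 1)
  print(df)
  invisible(x)
}

#' Fit each completed dataset of an imputation set
#'
#' @param imputations An [multiple_impute()] result.
#' @param ... Passed to [fit_mle()].
#' @return List of `rce_fit`, one per completed dataset.
#' @export
fit_imputations <- function(imputations, ...) {
  lapply(imputations$datasets, function(d) fit_mle(d, ...))
}

#' Pool fits across imputed datasets by Rubin's rules
#'
#' Point estimates are averaged; total variance combines within-imputation
#' variance and (1 + 1/m) times the between-imputation variance. The pooled
#' coefficients define the returned model; risk prediction can instead pool
#' predicted probabilities across the per-imputation models via
#' [predict_cohort()].
#'
#' @param fits List of `rce_fit` from [fit_imputations()].
#' @return A list with the pooled `model`, `estimates`, `se` and `m`.
#' @export
pool_fits <- function(fits) {
  m <- length(fits)
  if (m < 2L) stop("pooling needs at least two fits")
  est <- sapply(fits, function(f) f$par)
  qbar <- rowMeans(est)
  within <- rowMeans(sapply(fits, function(f)
    if (f$se_available) diag(f$vcov) else rep(NA_real_, length(f$par))))
  between <- apply(est, 1L, stats::var)
  total <- within + (1 + 1 / m) * between
  th <- .par_unpack(qbar, length(fits[[1L]]$covariates),
                    fits[[1L]]$alpha_estimated, fits[[1L]]$model$alpha)
  coefs <- if (length(fits[[1L]]$covariates)) {
    dimnames(th$B) <- list(.tr_labels(), fits[[1L]]$covariates); th$B
  } else NULL
  model <- transition_model(th$beta0, coefs, th$alpha,
                            fits[[1L]]$model$centering)
  list(model = model,
       estimates = qbar,
       se = sqrt(total),
       m = m)
}
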