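# Fast fitting checks run on small simulated cohorts with a reduced
# covariate set; full-scale parameter recovery lives in the acceptance suite.

make_fit_stub <- function(par, vcov, covariates) {
  structure(list(par = par, vcov = vcov, se_available = TRUE,
                 covariates = covariates),
            class = "rce_fit")
}

test_that("wald_statistic reduces to (b/s)^2, is 0 at 0, matches the quadratic form", {
  labs <- paste0("coef.", c("1-2", "2-1", "2-3", "2-4", "3-2", "3-4"))
  # single active coefficient
  nm <- c(paste0(labs[1], ".hba1c"))
  f1 <- make_fit_stub(stats::setNames(0.8, nm),
                      matrix(0.04, dimnames = list(nm, nm)), "hba1c")
  expect_equal(wald_statistic(f1, "hba1c"), (0.8 / 0.2)^2)
  # zero coefficient vector
  nm6 <- paste0(labs, ".hba1c")
  V6 <- diag(0.1, 6); dimnames(V6) <- list(nm6, nm6)
  f0 <- make_fit_stub(stats::setNames(rep(0, 6), nm6), V6, "hba1c")
  expect_equal(wald_statistic(f0, "hba1c"), 0)
  # two-coefficient case against direct matrix arithmetic
  nm2 <- paste0(labs[1:2], ".systolic_bp")
  b <- stats::setNames(c(0.5, -0.3), nm2)
  V <- matrix(c(0.04, 0.01, 0.01, 0.09), 2, dimnames = list(nm2, nm2))
  f2 <- make_fit_stub(b, V, "systolic_bp")
  expect_equal(wald_statistic(f2, "systolic_bp"),
               drop(t(b) %*% solve(V) %*% b), tolerance = 1e-10)
  expect_error(wald_statistic(f2, "hba1c"), "not active")
})

test_that("AICc formula, limit and guard", {
  f <- structure(list(loglik = -45, n_parameters = 5L, n_subjects = 100L),
                 class = "rce_fit")
  expect_equal(aicc(f), 100 + 60 / 94)
  f$n_subjects <- 10000000L
  expect_equal(aicc(f), -2 * -45 + 2 * 5, tolerance = 1e-4)
  f$n_subjects <- 6L
  expect_error(aicc(f), "undefined")
})

test_that("explained likelihood is an anchored percentage", {
  expect_equal(explained_likelihood(-100, -100, -40), 0)
  expect_equal(explained_likelihood(-40, -100, -40), 100)
  expect_equal(explained_likelihood(-52, -100, -40), 80)
  expect_error(explained_likelihood(-50, -40, -40), "equal")
})

test_that("intercept-only fit recovers the occurrence/exposure rate", {
  # near-degenerate truth: only the 1->2 move is live; finely observed panel
  truth <- transition_model(c(log(0.3), rep(-20, 5)), alpha = 1)
  cfg <- sim_config(300, model = truth, n_visits = 40, gap_mean = 0.1,
                    gap_sd = 0, gap_min = 0.05, init_probs = c(1, 0, 0),
                    cov_sds = 0, seed = 71)
  d <- simulate_cohort(cfg)
  df <- as.data.frame(d)
  # crude occurrence/exposure from the near-exactly-observed paths
  iv <- retscreen:::.interval_frame(df)
  n12 <- sum(iv$from == 1 & iv$to == 2)
  expo <- sum((iv$t2 - iv$t1)[iv$from == 1])
  crude <- n12 / expo
  fit <- suppressWarnings(fit_mle(d, fix_alpha = 1))
  expect_equal(exp(fit$model$intercepts[["1-2"]]), crude, tolerance = 0.05)
})

test_that("the maximised likelihood is a stationary point", {
  cfg <- sim_config(350, seed = 72)
  d <- simulate_cohort(cfg)
  ctl <- list(factr = 1e5)
  f1 <- fit_mle(d, c("disease_duration", "hba1c"), fix_alpha = 0.9,
                control = ctl)
  f2 <- fit_mle(d, c("disease_duration", "hba1c"), fix_alpha = 0.9,
                start = f1$model, control = ctl)
  expect_lt(abs(f2$loglik - f1$loglik), 1e-6)
  expect_lt(f1$gradient_norm, 1e-3)
})

test_that("nested selection orders by Wald, anchors rescaled AICc at 0", {
  # truth: only disease duration and HbA1c carry (inflated) effects
  hr <- matrix(1, 6, 5, dimnames = list(retscreen:::.tr_labels(),
                                        dr_covariates()))
  hr[, "disease_duration"] <- c(1.09, 0.95, 1.08, 0.98, 0.90, 1.01)
  hr[, "hba1c"] <- c(1.03, 0.995, 1.02, 1.01, 0.97, 1.05)
  truth <- transition_model(reference_model()$intercepts, log(hr), 0.9,
                            centering = retscreen:::.default_cov_means())
  d <- simulate_cohort(sim_config(700, model = truth, seed = 73))
  tab <- select_covariates(d, c("disease_duration", "hba1c", "systolic_bp"),
                           fix_alpha = 0.9)
  expect_s3_class(tab, "selection_table")
  expect_equal(min(tab$rescaled_aicc, na.rm = TRUE), 0)
  expect_true(tab$rescaled_aicc[tab$selected] == 0)
  sel <- attr(tab, "selected_covariates")
  expect_true(all(c("disease_duration", "hba1c") %in% sel))
  # log-likelihood is non-decreasing along the nested sequence
  lls <- vapply(attr(tab, "fits"), function(f) f$loglik, 0.0)
  expect_true(all(diff(lls) > -1e-6))
  # explained likelihood runs from 0 at the base model
  expect_equal(tab$explained_pct[1], 0)
})

test_that("single-candidate selection yields a two-row table decided by AICc", {
  d <- simulate_cohort(sim_config(250, seed = 74))
  tab <- select_covariates(d, "hba1c", fix_alpha = 0.9)
  expect_equal(nrow(tab), 2L)
  expect_equal(sum(tab$selected), 1L)
  expect_equal(tab$aicc[tab$selected], min(tab$aicc))
})

test_that("Rubin pooling averages estimates and inflates variance", {
  d <- simulate_cohort(sim_config(250, miss_rate = 0.08, seed = 75))
  imp <- multiple_impute(d, m = 3, seed = 5)
  fits <- fit_imputations(imp, covariates = "hba1c", fix_alpha = 0.9)
  pooled <- pool_fits(fits)
  est <- sapply(fits, function(f) f$par)
  expect_equal(unname(pooled$estimates), unname(rowMeans(est)))
  within <- rowMeans(sapply(fits, function(f) diag(f$vcov)))
  expect_true(all(pooled$se^2 >= within - 1e-12))
  expect_s3_class(pooled$model, "transition_model")
})
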