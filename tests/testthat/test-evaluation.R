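test_that("episode accounting applies the 4x/2x/1x multipliers", {
  s <- episode_accounting(c(1281, 1035, 9684))
  expect_equal(unname(s$episodes), c(5124, 2070, 9684))
  expect_equal(s$total, 16878)
  expect_equal(s$reference, 24000)
  expect_equal(s$difference, -7122)
  expect_equal(round(s$percent, 1), -29.7)

  s5 <- episode_accounting(c(664, 531, 10805))
  expect_equal(s5$total, 14523)
  expect_equal(round(s5$percent, 1), -39.5)

  z <- episode_accounting(c(0, 0, 0))
  expect_equal(z$total, 0)
  expect_equal(z$percent, 0)
  expect_true(z$empty)
  expect_error(episode_accounting(c(-1, 0, 0)), "non-negative")
})

test_that("allocation error rates follow the midpoint/interval rules", {
  outc <- data.frame(
    subject_id = c("P1", "P2", "N1", "N2", "N3"),
    positive = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    event_time = c(1.5, 0.4, NA, NA, NA),
    follow_up = c(2, 1, 2.0, 2.5, 1.2))
  alloc <- data.frame(subject_id = c("P1", "P2", "N1", "N2", "N3"),
                      interval_years = c(2, 1, 1, 2, 2))
  r <- allocation_error_rates(outc, alloc)
  # P1: event at 1.5 with a 24-month interval -> overestimated
  # P2: event at 0.4 with a 12-month interval -> overestimated
  expect_equal(r$positive$correct, 0)
  expect_equal(r$positive$overestimated, 1)
  # N1 allocated 12 months -> underestimated; N2 allocated 24 -> correct;
  # N3 has under 24 months of follow-up -> excluded
  expect_equal(r$negative$n, 2L)
  expect_equal(r$negative$correct, 0.5)
  expect_equal(r$negative$excluded_short_followup, 1L)
  # annual reference: P1 event after 12 months is correct, P2 is not;
  # negatives are never correct under a 12-month blanket policy
  expect_equal(r$annual$positive_correct, 0.5)
  expect_equal(r$annual$negative_correct, 0)
})

test_that("concordance handles perfect, permuted and tied orderings", {
  set.seed(61)
  n <- 50
  outc <- data.frame(subject_id = paste0("S", 1:n),
                     positive = rep(c(TRUE, FALSE), c(20, 30)),
                     event_time = c(runif(20, 0.2, 2), rep(NA, 30)),
                     follow_up = c(runif(20, 2, 3), runif(30, 2, 4)))
  # perfectly anti-ordered by event time (earlier event = higher risk),
  # negatives below every positive
  r <- numeric(n); names(r) <- outc$subject_id
  r[1:20] <- 1 - outc$event_time[1:20] / 3
  r[21:n] <- 0
  expect_equal(concordance_index(r, outc), 1)
  # risks independent of outcome hover near 1/2
  cs <- replicate(40, {
    rp <- stats::setNames(sample(r), names(r))
    concordance_index(rp, outc)
  })
  expect_lt(abs(mean(cs) - 0.5), 0.05)
})

test_that("concordance and AUC match brute-force pair oracles on toy sets", {
  set.seed(62)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    npos <- sample(2:(n - 1), 1)
    outc <- data.frame(
      subject_id = paste0("T", seq_len(n)),
      positive = rep(c(TRUE, FALSE), c(npos, n - npos)),
      event_time = c(round(runif(npos, 0.2, 2), 1), rep(NA, n - npos)),
      follow_up = round(runif(n, 0.5, 3), 1))
    # coarse risks force ties with positive probability
    r <- stats::setNames(sample(seq(0.1, 0.5, 0.1), n, replace = TRUE),
                         outc$subject_id)
    ok <- try(concordance_index(r, outc), silent = TRUE)
    if (!inherits(ok, "try-error"))
      expect_identical(ok, oracle_cindex(r, outc))
    case <- outc$positive & outc$event_time <= 1
    ctrl <- (!outc$positive & outc$follow_up >= 1) |
      (outc$positive & outc$event_time > 1)
    if (any(case) && any(ctrl)) {
      h <- horizon_discrimination(r, outc, horizon = 1, threshold = 0.25)
      expect_identical(h$auc, oracle_auc(r[case], r[ctrl]))
    }
  }
})

test_that("separable risks give perfect discrimination; threshold 0 degenerates", {
  outc <- data.frame(subject_id = paste0("S", 1:6),
                     positive = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                     event_time = c(0.3, 0.7, NA, NA, NA, NA),
                     follow_up = c(1, 1, 2, 2, 2, 2))
  r <- stats::setNames(c(0.9, 0.8, 0.1, 0.2, 0.15, 0.05), outc$subject_id)
  h <- horizon_discrimination(r, outc, 1, threshold = 0.5)
  expect_equal(h$auc, 1)
  expect_equal(h$sensitivity, 1)
  expect_equal(h$specificity, 1)
  h0 <- horizon_discrimination(r, outc, 1, threshold = 0)
  expect_equal(h0$sensitivity, 1)
  expect_equal(h0$specificity, 0)
  expect_error(horizon_discrimination(r[1:2], outc[1:2, ], 1), "control")
})

test_that("cross-validation is seed-deterministic and guards sparse folds", {
  d <- simulate_cohort(sim_config(800, seed = 63))
  v1 <- kfold_validate(d, k = 4, seed = 2, covariates = "disease_duration",
                       fix_alpha = 0.9)
  v2 <- kfold_validate(d, k = 4, seed = 2, covariates = "disease_duration",
                       fix_alpha = 0.9)
  expect_identical(v1$folds, v2$folds)
  expect_equal(v1$cindex, v2$cindex)
  expect_true(v1$cindex >= 0 && v1$cindex <= 1)
  # far too many folds for the event count
  expect_error(kfold_validate(d, k = 50, seed = 2, min_events = 5),
               "fewer folds|folds")
})

test_that("bootstrap optimism: constant metrics have none; seeds reproduce", {
  d <- simulate_cohort(sim_config(60, seed = 64))
  fit_fun <- function(dd) fit_mle(dd, fix_alpha = 0.9)
  const_metric <- function(fit, dd) 0.75
  b <- bootstrap_optimism(d, const_metric, fit_fun, B = 50, seed = 3)
  expect_equal(b$optimism, 0)
  expect_equal(b$corrected, b$apparent)
  expect_error(bootstrap_optimism(d, const_metric, fit_fun, B = 10, seed = 3),
               "at least 50")
  ll_metric <- function(fit, dd) panel_log_likelihood(dd, fit$model) /
    n_subjects(dd)
  b1 <- bootstrap_optimism(d, ll_metric, fit_fun, B = 50, seed = 5)
  b2 <- bootstrap_optimism(d, ll_metric, fit_fun, B = 50, seed = 5)
  expect_equal(b1$optimism, b2$optimism)
  # per-subject training log-likelihood is optimistic on average
  expect_gt(b1$optimism, 0)
})
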