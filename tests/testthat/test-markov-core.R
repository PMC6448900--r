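test_that("intensities are log-linear in centred covariates", {
  m <- reference_model()
  tr <- dr_transitions()
  # covariates at the centering constants give the baseline intensities
  Q0 <- build_intensity_matrix(m, as.list(m$centering))
  expect_equal(unname(Q0[tr]), unname(exp(m$intercepts)))
  expect_equal(rowSums(Q0), rep(0, 4), ignore_attr = TRUE)
  expect_identical(Q0[1, 3], 0); expect_identical(Q0[1, 4], 0)
  expect_identical(Q0[3, 1], 0); expect_equal(unname(Q0[4, ]), rep(0, 4))

  # one extra year of disease duration multiplies lambda_12 by its hazard ratio
  x1 <- as.list(m$centering); x1$disease_duration <- x1$disease_duration + 1
  Q1 <- build_intensity_matrix(m, x1)
  expect_equal(Q1[1, 2] / Q0[1, 2], 1.0280, tolerance = 1e-10)
  # ten years: repeated per-unit multiplication
  x10 <- as.list(m$centering); x10$disease_duration <- x10$disease_duration + 10
  Q10 <- build_intensity_matrix(m, x10)
  hr10 <- prod(rep(1.0280, 10))
  expect_equal(Q10[1, 2] / Q0[1, 2], hr10, tolerance = 1e-9)
  expect_equal(hr10, 1.3182, tolerance = 1e-3)
})

test_that("missing covariates are refused with a pointer to imputation", {
  m <- reference_model()
  x <- as.list(m$centering); x$hba1c <- NA
  expect_error(build_intensity_matrix(m, x), "imput")
})

test_that("transition probabilities behave at the boundaries", {
  set.seed(101)
  Q <- random_Q()
  expect_equal(transition_probability(Q, 1.3, 1.3, 0.9), diag(4),
               ignore_attr = TRUE)
  # at t = 1 operational time is 1 for any shape, so P equals expm(Q)
  for (a in c(0.5, 0.9, 1.7))
    expect_equal(transition_probability(Q, 0, 1, a),
                 transition_probability(Q, 0, 1, 1), tolerance = 1e-12)
  expect_error(transition_probability(Q, 2, 1, 0.9), "t2")
})

test_that("the two-state absorbing sub-system matches its closed form", {
  Q <- matrix(0, 4, 4); Q[2, 4] <- 1; Q[2, 2] <- -1
  expect_equal(transition_probability(Q, 0, 1, 1)[2, 4], 1 - exp(-1),
               tolerance = 1e-10)
  for (t in c(0.3, 0.8, 1.9)) for (a in c(0.9, 1))
    expect_equal(transition_probability(Q, 0, t, a)[2, 4], 1 - exp(-t^a),
                 tolerance = 1e-10)
})

test_that("rows are stochastic and the operational-time semigroup holds", {
  set.seed(202)
  for (rep in 1:20) {
    Q <- random_Q()
    a <- runif(1, 0.5, 1.5)
    t1 <- runif(1, 0, 2); t2 <- t1 + runif(1, 0, 2)
    P <- transition_probability(Q, t1, t2, a)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(P[4, ], c(0, 0, 0, 1), ignore_attr = TRUE)
    # P(0,t1) P(t1,t2) = P(0,t2)
    P2 <- transition_probability(Q, 0, t1, a) %*% P
    expect_equal(P2, transition_probability(Q, 0, t2, a),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("transition probabilities agree with the uniformization oracle", {
  set.seed(303)
  for (rep in 1:10) {
    Q <- random_Q()
    u <- runif(1, 0.1, 3)
    expect_equal(transition_probability(Q, 0, u, 1), oracle_tpm(Q, u),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("state occupancy extracts rows and absorption is monotone", {
  set.seed(404)
  Q <- random_Q()
  expect_equal(state_occupancy(Q, 0, 0.9, 2), c(0, 1, 0, 0),
               ignore_attr = TRUE)
  expect_equal(state_occupancy(Q, 3.7, 0.9, 4), c(0, 0, 0, 1),
               ignore_attr = TRUE)
  grid <- seq(0.1, 4, by = 0.1)
  for (s in 1:3) {
    abs4 <- vapply(grid, function(t) state_occupancy(Q, t, 0.9, s)[4], 0.0)
    expect_true(all(diff(abs4) > -1e-12))
  }
})

test_that("single-interval and additive structure of the likelihood", {
  m0 <- transition_model(log(c(0.3, 0.5, 0.2, 0.05, 0.3, 0.1)), alpha = 1)
  d1 <- toy_panel(list(A = list(times = c(0, 1), states = c(1, 1))))
  Q <- build_intensity_matrix(m0)
  expect_equal(panel_log_likelihood(d1, m0),
               log(transition_probability(Q, 0, 1, 1)[1, 1]),
               tolerance = 1e-12)
  dB <- toy_panel(list(B = list(times = c(0, 0.8, 1.7), states = c(2, 3, 4))))
  dAB <- toy_panel(list(A = list(times = c(0, 1), states = c(1, 1)),
                        B = list(times = c(0, 0.8, 1.7), states = c(2, 3, 4))))
  expect_equal(panel_log_likelihood(dAB, m0),
               panel_log_likelihood(d1, m0) + panel_log_likelihood(dB, m0),
               tolerance = 1e-12)
})

test_that("panel likelihood matches the discretized-path oracle on random cases", {
  set.seed(505)
  for (rep in 1:12) {
    alpha <- sample(c(1, 0.9), 1)
    lam <- runif(6, 0.05, 2)
    m <- transition_model(log(lam), alpha = alpha)
    n_sub <- sample(1:5, 1)
    spec <- list()
    for (s in seq_len(n_sub)) {
      k <- sample(1:3, 1)  # intervals
      times <- c(0, sort(runif(k, 0.2, 3)))
      states <- c(sample(1:3, 1))
      for (j in seq_len(k)) {
        prev <- states[length(states)]
        nxt <- if (prev == 4) 4 else sample(1:4, 1, prob = c(.3, .3, .25, .15))
        states <- c(states, nxt)
      }
      spec[[paste0("S", s)]] <- list(times = times, states = states)
    }
    # truncate any post-absorption tail so the panel is valid
    spec <- lapply(spec, function(x) {
      k <- which(x$states == 4)
      if (length(k)) list(times = x$times[1:k[1]], states = x$states[1:k[1]])
      else x
    })
    spec <- Filter(function(x) length(x$times) >= 2, spec)
    if (!length(spec)) next
    d <- toy_panel(spec)
    expect_equal(panel_log_likelihood(d, m), oracle_loglik(d, m),
                 tolerance = 1e-6)
  }
})

test_that("a zero-probability interval yields -Inf with a diagnostic", {
  # an (effectively) impossible observed jump: all intensities at the floor
  m <- transition_model(rep(-40, 6), alpha = 1)
  d <- toy_panel(list(Z = list(times = c(0, 1), states = c(1, 3))))
  ll <- panel_log_likelihood(d, m)
  expect_true(is.infinite(ll) && ll < 0)
  expect_match(attr(ll, "bad_interval"), "Z")
})
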