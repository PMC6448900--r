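# Internal validation (concordance, fixed-horizon discrimination, k-fold
# cross-validation, bootstrap optimism) and screening-policy accounting.

#' Outcome records from a screening panel
#'
#' Builds the per-subject outcome table the validation metrics consume.
#' A subject is screen-positive if state 4 was ever observed; their event
#' time is the midpoint of the interval between the last screen-negative
#' episode and the first screen-positive one (the true transition time is
#' interval-censored). Screen negatives carry their follow-up duration
#' (time of last episode).
#'
#' @param data A [panel_data()].
#' @param truth Optional exact-transition-time data.frame (the `truth`
#'   attribute of [simulate_cohort()]); if supplied, exact state-4 entry
#'   times replace the midpoint convention.
#' @return Data frame: `subject_id`, `positive`, `event_time` (NA for
#'   negatives), `follow_up`.
#' @export
screening_outcomes <- function(data, truth = NULL) {
  df <- as.data.frame(data)
  sp <- split(seq_len(nrow(df)), df$subject_id)
  out <- data.frame(subject_id = names(sp),
                    positive = FALSE, event_time = NA_real_,
                    follow_up = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(sp)) {
    idx <- sp[[i]]
    st <- df$state[idx]; tm <- df$time_years[idx]
    k <- which(st == 4L)
    if (length(k)) {
      out$positive[i] <- TRUE
      out$event_time[i] <- (tm[k[1L] - 1L] + tm[k[1L]]) / 2
      out$follow_up[i] <- tm[k[1L]]
    } else {
      out$follow_up[i] <- tm[length(idx)]
    }
  }
  if (!is.null(truth)) {
    for (i in which(out$positive)) {
      tt <- truth[truth$subject_id == out$subject_id[i] & truth$state == 4L,
                  "time_years"]
      if (length(tt)) out$event_time[i] <- tt[1L]
    }
  }
  out
}

#' Screening-episode accounting over a two-year period
#'
#' People allocated to 6, 12 and 24 month intervals attend 4, 2 and 1
#' screening episodes respectively over two years; the annual-programme
#' reference is 2 episodes per person.
#'
#' @param persons Non-negative integer counts of people allocated to the
#'   6, 12 and 24 month intervals (in that order).
#' @return An `allocation_summary` list: `persons`, `episodes`, `total`,
#'   `reference`, `difference` and `percent` (100 x (total - reference) /
#'   reference; 0 with an `empty` flag for an empty cohort).
#' @export
episode_accounting <- function(persons) {
  if (length(persons) != 3L || any(persons < 0) ||
      any(persons != round(persons)))
    stop("persons must be three non-negative counts (6m, 12m, 24m)")
  mult <- c(4L, 2L, 1L)
  episodes <- mult * persons
  total <- sum(episodes)
  reference <- 2L * sum(persons)
  empty <- reference == 0L
  structure(list(persons = stats::setNames(persons, c("6m", "12m", "24m")),
                 episodes = stats::setNames(episodes, c("6m", "12m", "24m")),
                 total = total,
                 reference = reference,
                 difference = total - reference,
                 percent = if (empty) 0 else 100 * (total - reference) / reference,
                 empty = empty),
            class = "allocation_summary")
}

#' @export
print.allocation_summary <- function(x, ...) {
  cat("Screening episodes over 2 years (6m/12m/24m multipliers 4/2/1)\n")
  cat("  persons: ", paste(x$persons, collapse = " / "),
      "   episodes: ", paste(x$episodes, collapse = " / "), "\n", sep = "")
  cat("  total ", x$total, " vs annual reference ", x$reference,
      " (", sprintf("%+d", x$difference), ", ",
      sprintf("%.1f%%", x$percent), ")\n", sep = "")
  invisible(x)
}

#' Correct/over/under-allocation rates of a screening policy
#'
#' A screen positive is correctly allocated if their event time is at or
#' after the allocated screening date (otherwise the interval was
#' overestimated). A screen negative is correctly allocated only by the
#' maximal interval (anything shorter is an underestimate: screening 'too
#' early'); negatives with follow-up shorter than the maximal interval are
#' excluded. The annual-programme reference applies a fixed 12-month
#' interval the same way, so screen-negative correct allocation is 0% by
#' construction under the annual policy.
#'
#' @param outcomes From [screening_outcomes()].
#' @param allocations Data frame with `subject_id` and `interval_years`
#'   (e.g. a [predict_cohort()] result).
#' @param max_interval Maximal offered interval in years, default 2.
#' @return List with screen-positive and screen-negative correct /
#'   incorrect proportions for the policy and for the annual reference,
#'   plus exclusion counts.
#' @export
allocation_error_rates <- function(outcomes, allocations, max_interval = 2) {
  m <- merge(outcomes, allocations[c("subject_id", "interval_years")],
             by = "subject_id")
  pos <- m[m$positive, , drop = FALSE]
  miss_ev <- sum(is.na(pos$event_time))
  pos <- pos[!is.na(pos$event_time), , drop = FALSE]
  neg <- m[!m$positive, , drop = FALSE]
  excl <- sum(neg$follow_up < max_interval)
  neg <- neg[neg$follow_up >= max_interval, , drop = FALSE]

  rate <- function(x) if (length(x)) mean(x) else NA_real_
  pos_correct <- rate(pos$event_time >= pos$interval_years)
  neg_correct <- rate(neg$interval_years == max_interval)
  list(positive = list(n = nrow(pos),
                       correct = pos_correct,
                       overestimated = 1 - pos_correct,
                       excluded_missing_event = miss_ev),
       negative = list(n = nrow(neg),
                       correct = neg_correct,
                       underestimated = 1 - neg_correct,
                       excluded_short_followup = excl),
       annual = list(positive_correct = rate(pos$event_time >= 1),
                     negative_correct = if (nrow(neg)) 0 else NA_real_))
}

#' Concordance index of predicted risks against observed outcomes
#'
#' The probability, over comparable pairs, that the subject with the
#' earlier event received the higher predicted risk; ties in risk count
#' one half. A pair is comparable when one subject has an event and the
#' other either has a later event or remains screen-negative with
#' follow-up reaching the first subject's event time.
#'
#' @param risks Data frame with `subject_id` and a `risk` column (or a
#'   named numeric vector of risks).
#' @param outcomes From [screening_outcomes()].
#' @return The concordance index in `[0, 1]`.
#' @export
concordance_index <- function(risks, outcomes) {
  r <- .risk_vector(risks)
  m <- outcomes[outcomes$subject_id %in% names(r), , drop = FALSE]
  r <- r[m$subject_id]
  pos <- which(m$positive & !is.na(m$event_time))
  if (!length(pos)) stop("no screen-positive subjects: no comparable pairs")
  conc <- 0; npair <- 0
  for (i in pos) {
    ei <- m$event_time[i]
    cmp <- (m$positive & !is.na(m$event_time) & m$event_time > ei) |
      (!m$positive & m$follow_up >= ei)
    if (!any(cmp)) next
    d <- r[i] - r[cmp]
    conc <- conc + sum(d > 0) + 0.5 * sum(d == 0)
    npair <- npair + sum(cmp)
  }
  if (npair == 0) stop("no comparable pairs")
  conc / npair
}

.risk_vector <- function(risks) {
  if (is.data.frame(risks)) {
    cn <- intersect(c("risk", "risk_24m"), names(risks))
    if (!length(cn)) stop("risks data frame needs a 'risk' column")
    stats::setNames(risks[[cn[1L]]], risks$subject_id)
  } else {
    if (is.null(names(risks))) stop("risk vector must be named by subject")
    risks
  }
}

#' Fixed-horizon discrimination: AUC, sensitivity and specificity
#'
#' Subjects are classified at the horizon: cases had their event by the
#' horizon; controls were event-free through it (screen negatives need
#' follow-up reaching the horizon; later events count as controls). The AUC
#' is the rank (Mann-Whitney) statistic comparing predicted horizon risks
#' between the groups; sensitivity and specificity classify `risk >
#' threshold` as test-positive.
#'
#' @param risks Data frame (`subject_id`, `risk`) or named vector of
#'   predicted risks at this horizon.
#' @param outcomes From [screening_outcomes()].
#' @param horizon Horizon in years.
#' @param threshold Operating risk threshold, default 0.025.
#' @return List: `auc`, `sensitivity`, `specificity`, `n_case`,
#'   `n_control`.
#' @export
horizon_discrimination <- function(risks, outcomes, horizon,
                                   threshold = 0.025) {
  r <- .risk_vector(risks)
  m <- outcomes[outcomes$subject_id %in% names(r), , drop = FALSE]
  r <- r[m$subject_id]
  case <- m$positive & !is.na(m$event_time) & m$event_time <= horizon
  ctrl <- (!m$positive & m$follow_up >= horizon) |
    (m$positive & !is.na(m$event_time) & m$event_time > horizon)
  if (!any(case) || !any(ctrl))
    stop("need at least one case and one control at horizon ", horizon)
  rc <- r[case]; rn <- r[ctrl]
  rk <- rank(c(rc, rn))
  auc <- (sum(rk[seq_along(rc)]) - length(rc) * (length(rc) + 1) / 2) /
    (length(rc) * length(rn))
  list(auc = auc,
       sensitivity = mean(rc > threshold),
       specificity = mean(rn <= threshold),
       n_case = sum(case), n_control = sum(ctrl))
}

#' Subject-level k-fold cross-validation of the fitted risk engine
#'
#' Subjects are partitioned into `k` folds at random, stratified by
#' baseline state. For each fold the model is fitted on the remaining
#' folds, baseline risks are predicted for the held-out subjects, and
#' predictions are pooled across folds before scoring: concordance index
#' (ranking by the longest-horizon risk) and per-horizon AUC, sensitivity
#' and specificity at the operating threshold. Deterministic given `seed`.
#'
#' @param data A complete [panel_data()].
#' @param k Number of folds, default 4.
#' @param seed Integer RNG seed.
#' @param covariates Active covariates for the fits.
#' @param fix_alpha Optional fixed Weibull shape.
#' @param threshold Operating threshold, default 0.025.
#' @param horizons Horizons, default [dr_horizons()].
#' @param min_events Minimum screen positives required per fold, default 5.
#' @param truth Optional exact-event-time table for the outcome records.
#' @return A `validation_report` list: `cindex`, per-horizon metrics,
#'   `folds` (assignment), `predictions`.
#' @export
kfold_validate <- function(data, k = 4L, seed = 1L,
                           covariates = character(0), fix_alpha = NULL,
                           threshold = 0.025, horizons = dr_horizons(),
                           min_events = 5L, truth = NULL) {
  if (k < 2L) stop("k must be at least 2")
  df <- as.data.frame(data)
  base <- baseline_episodes(data)
  set.seed(seed)
  fold <- integer(nrow(base))
  for (s in unique(base$state)) {
    idx <- which(base$state == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  names(fold) <- base$subject_id
  outcomes <- screening_outcomes(data, truth)
  ev_fold <- table(factor(fold[outcomes$subject_id[outcomes$positive]],
                          levels = seq_len(k)))
  if (any(ev_fold < min_events))
    stop("fold(s) with fewer than ", min_events,
         " screen-positive subjects; use fewer folds")

  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train_ids <- names(fold)[fold != f]
    test_ids <- names(fold)[fold == f]
    train <- panel_data(df[df$subject_id %in% train_ids, , drop = FALSE])
    test <- panel_data(df[df$subject_id %in% test_ids, , drop = FALSE])
    fit <- fit_mle(train, covariates, fix_alpha = fix_alpha)
    preds[[f]] <- suppressWarnings(
      predict_cohort(fit$model, test, threshold, horizons, at = "baseline"))
  }
  pred <- do.call(rbind, preds)
  hz_cols <- paste0("risk_", round(horizons * 12), "m")
  long_risk <- stats::setNames(pred[[hz_cols[length(hz_cols)]]],
                               pred$subject_id)
  per_h <- lapply(seq_along(horizons), function(h) {
    rv <- stats::setNames(pred[[hz_cols[h]]], pred$subject_id)
    horizon_discrimination(rv, outcomes, horizons[h], threshold)
  })
  names(per_h) <- hz_cols
  structure(list(cindex = concordance_index(long_risk, outcomes),
                 horizons = per_h,
                 folds = fold,
                 predictions = pred,
                 k = k, seed = seed, threshold = threshold),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(x$k, "-fold cross-validation (threshold ", x$threshold, ")\n", sep = "")
  cat("  C-index:", round(x$cindex, 3), "\n")
  for (h in names(x$horizons)) {
    m <- x$horizons[[h]]
    cat(sprintf("  %s: AUC %.3f, sens %.2f, spec %.2f (%d cases / %d controls)\n",
                sub("risk_", "", h), m$auc, m$sensitivity, m$specificity,
                m$n_case, m$n_control))
  }
  invisible(x)
}

#' Bootstrap optimism of a validation metric
#'
#' For each of `B` subject-level bootstrap resamples: refit on the
#' resample, evaluate the metric on the resample and on the original data;
#' the optimism is the mean of the differences. The corrected metric is the
#' apparent value minus the optimism.
#'
#' @param data A complete [panel_data()].
#' @param metric Function `(fit, data) -> scalar`.
#' @param fit_fun Function `(data) -> fit` (e.g. wrapping [fit_mle()]).
#' @param B Number of bootstrap replicates, default 200 (minimum 50 for a
#'   stable estimate; smaller values are refused).
#' @param seed Integer RNG seed.
#' @return List: `optimism`, `apparent`, `corrected`, `n_failed`.
#' @export
bootstrap_optimism <- function(data, metric, fit_fun, B = 200L, seed = 1L) {
  if (B < 50L) stop("B must be at least 50")
  df <- as.data.frame(data)
  ids <- unique(df$subject_id)
  rows <- split(seq_len(nrow(df)), df$subject_id)
  set.seed(seed)
  fit0 <- fit_fun(data)
  apparent <- metric(fit0, data)
  opt <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    take <- sample(ids, length(ids), replace = TRUE)
    pieces <- lapply(seq_along(take), function(j) {
      d <- df[rows[[take[j]]], , drop = FALSE]
      d$subject_id <- paste0("B", j)
      d
    })
    boot <- panel_data(do.call(rbind, pieces))
    val <- try({
      fb <- fit_fun(boot)
      metric(fb, boot) - metric(fb, data)
    }, silent = TRUE)
    if (!inherits(val, "try-error") && is.finite(val)) opt[b] <- val
  }
  ok <- !is.na(opt)
  if (!any(ok)) stop("every bootstrap replicate failed")
  optimism <- mean(opt[ok])
  list(optimism = optimism,
       apparent = apparent,
       corrected = apparent - optimism,
       n_failed = sum(!ok))
}
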