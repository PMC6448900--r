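# Per-person screen-positive risk at candidate horizons and threshold-based
# screening-interval allocation: the deployed behaviour of the risk engine.

#' Default candidate screening horizons (years)
#' @return `c(0.5, 1, 2)` — 6, 12 and 24 months.
#' @export
dr_horizons <- function() c(0.5, 1, 2)

#' Predict screen-positive risk at each candidate horizon
#'
#' The risk at horizon `h` is the probability of occupying the
#' screen-positive state 4 by `h` years, i.e. entry `(state, 4)` of
#' `expm(Q(covariates) h^alpha)`, with the clock restarted at the prediction
#' episode. Risks are non-decreasing in the horizon because state 4 is
#' absorbing.
#'
#' @param model A [transition_model()].
#' @param state Current observed state, 1-3 (state 4 is already
#'   screen-positive).
#' @param covariates Complete covariate values (apply [worst_case_impute()]
#'   first if any are missing).
#' @param horizons Horizons in years, default [dr_horizons()].
#' @return Named numeric vector of risks, one per horizon.
#' @export
predict_risk <- function(model, state, covariates = NULL,
                         horizons = dr_horizons()) {
  state <- as.integer(state)
  if (!state %in% 1:3)
    stop("state must be 1-3; state 4 is already screen-positive")
  Q <- build_intensity_matrix(model, covariates)
  risks <- vapply(horizons, function(h)
    transition_probability(Q, 0, h, model$alpha)[state, 4L], 0.0)
  stats::setNames(risks, paste0(round(horizons * 12), "m"))
}

#' Allocate a screening interval against a risk threshold
#'
#' Returns the longest candidate horizon whose predicted risk does not
#' exceed the threshold (a risk exactly at the threshold counts as
#' acceptable). If even the shortest horizon exceeds the threshold, the
#' shortest offered interval is returned.
#'
#' @param risks Per-horizon risks, non-decreasing, in the order of
#'   `horizons`.
#' @param threshold Acceptable risk of becoming screen-positive before the
#'   next screen, default 0.025.
#' @param horizons Candidate horizons in years, default [dr_horizons()].
#' @return The allocated interval in years.
#' @export
allocate_interval <- function(risks, threshold = 0.025,
                              horizons = dr_horizons()) {
  if (length(risks) != length(horizons))
    stop("risks and horizons differ in length")
  if (any(diff(risks) < -1e-12))
    stop("risks must be non-decreasing in the horizon")
  ok <- which(risks <= threshold)
  if (length(ok)) horizons[max(ok)] else horizons[1L]
}

#' Risk prediction and interval allocation for a whole cohort
#'
#' One prediction per subject, made from their latest screen-negative
#' episode. Subjects whose latest episode is already screen-positive are
#' skipped with a warning count. Missing covariates at the prediction
#' episode are completed by worst-case imputation using the model's stored
#' percentiles (or `ref`). When a list of models is supplied (one per
#' imputed dataset), the predicted probabilities — not the coefficients —
#' are averaged before allocation.
#'
#' @param model A [transition_model()] or a list of them.
#' @param data A [panel_data()].
#' @param threshold Risk threshold, default 0.025.
#' @param horizons Candidate horizons, default [dr_horizons()].
#' @param ref Optional worst-case reference percentiles; defaults to the
#'   model's stored `percentile75`, falling back to [worst_case_reference()]
#'   on `data`.
#' @param at `"latest"` (deployment) predicts from the last screen-negative
#'   episode; `"baseline"` (validation) predicts from the first episode.
#' @return A `risk_prediction` data.frame: `subject_id`, `state`, one
#'   `risk_*` column per horizon, `interval_years`, `interval_months`,
#'   `threshold`, `imputed` (fields completed by worst-case imputation).
#' @export
predict_cohort <- function(model, data, threshold = 0.025,
                           horizons = dr_horizons(), ref = NULL,
                           at = c("latest", "baseline")) {
  at <- match.arg(at)
  models <- if (inherits(model, "transition_model")) list(model) else model
  active <- colnames(models[[1L]]$coefficients)
  if (is.null(ref)) ref <- models[[1L]]$percentile75
  if (is.null(ref) && length(active)) ref <- worst_case_reference(data, active)

  df <- as.data.frame(data)
  rows <- split(seq_len(nrow(df)), df$subject_id)
  skipped <- 0L
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    idx <- rows[[i]]
    neg <- idx[df$state[idx] != 4L]
    use <- if (at == "baseline") idx[1L] else neg[length(neg)]
    if (at == "latest" && df$state[idx[length(idx)]] == 4L) {
      skipped <- skipped + 1L
      next
    }
    x <- if (length(active)) unlist(df[use, active]) else NULL
    imputed <- character(0)
    if (length(active)) {
      x <- worst_case_impute(stats::setNames(as.numeric(x), active), ref)
      imputed <- attr(x, "imputed")
    }
    risk_mat <- sapply(models, function(mm)
      predict_risk(mm, df$state[use], x, horizons))
    risks <- if (is.matrix(risk_mat)) rowMeans(risk_mat) else mean(risk_mat)
    iv <- allocate_interval(risks, threshold, horizons)
    rec <- data.frame(subject_id = df$subject_id[use],
                      state = df$state[use],
                      stringsAsFactors = FALSE)
    for (h in seq_along(horizons))
      rec[[paste0("risk_", round(horizons[h] * 12), "m")]] <- risks[h]
    rec$interval_years <- iv
    rec$interval_months <- round(iv * 12)
    rec$threshold <- threshold
    rec$imputed <- paste(imputed, collapse = ";")
    out[[i]] <- rec
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  if (skipped > 0L)
    warning(skipped, " subject(s) already screen-positive were skipped")
  attr(res, "skipped") <- skipped
  class(res) <- c("risk_prediction", "data.frame")
  res
}

#' @export
print.risk_prediction <- function(x, ...) {
  cat("Risk predictions for", nrow(x), "subjects at threshold",
      unique(x$threshold), "\n")
  cat("Interval allocation:\n")
  print(table(months = x$interval_months))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
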