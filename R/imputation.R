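# Multiple imputation of missing covariates (for fitting) and the
# 75th-percentile worst-case single imputation (for deployed prediction).

#' Chained-equations multiple imputation of missing covariates
#'
#' Produces `m` completed copies of a panel dataset. Each copy is imputed by
#' chained equations: every covariate with missing values is regressed, in
#' turn, on the other four covariates plus the observed disease state
#' (as a factor) and episode time, and its missing cells are replaced by
#' posterior-predictive draws (coefficients drawn from their sampling
#' distribution, residual variance from its scaled chi-square). Five burn-in
#' cycles are run before a copy is accepted. Observed cells are never
#' altered, and the whole procedure is deterministic given `seed`.
#'
#' Covariates below 80% completeness should be excluded from modelling
#' rather than imputed; the function refuses them.
#'
#' @param data A [panel_data()].
#' @param m Number of completed copies, default 10.
#' @param seed Integer RNG seed.
#' @param cycles Burn-in cycles per copy, default 5.
#' @return An `imputation_set`: list with `datasets` (list of `m` completed
#'   [panel_data()] copies), `m`, `seed`, and `method`.
#' @export
multiple_impute <- function(data, m = 10L, seed = 1L, cycles = 5L) {
  if (m < 2L) stop("m must be at least 2")
  df <- as.data.frame(data)
  covs <- intersect(dr_covariates(), names(df))
  if (!length(covs)) stop("no covariate columns to impute")
  compl <- vapply(covs, function(cv) mean(!is.na(df[[cv]])), 0.0)
  low <- covs[compl < 0.8]
  if (length(low))
    stop("covariate(s) below 80% completeness, exclude from the model ",
         "instead of imputing: ", paste(low, collapse = ", "))

  need <- covs[vapply(covs, function(cv) anyNA(df[[cv]]), FALSE)]
  if (!length(need)) {
    datasets <- replicate(m, data, simplify = FALSE)
    return(structure(list(datasets = datasets, m = m, seed = seed,
                          method = "none (complete data)"),
                     class = "imputation_set"))
  }

  aux <- data.frame(state = factor(df$state, levels = 1:4),
                    time_years = df$time_years)
  datasets <- vector("list", m)
  for (im in seq_len(m)) {
    set.seed((seed + 7919L * im) %% .Machine$integer.max)
    work <- df
    # initialise missing cells with resampled observed values
    for (cv in need) {
      na <- is.na(work[[cv]])
      obs <- work[[cv]][!na]
      work[[cv]][na] <- sample(obs, sum(na), replace = TRUE)
    }
    for (cyc in seq_len(cycles)) {
      for (cv in need) {
        na <- is.na(df[[cv]])
        rhs <- cbind(work[setdiff(covs, cv)], aux)
        mm <- stats::model.matrix(~ ., data = rhs)
        # drop rank-deficient columns (e.g. unused state levels)
        piv <- qr(mm[!na, , drop = FALSE])
        keep <- piv$pivot[seq_len(piv$rank)]
        Xo <- mm[!na, keep, drop = FALSE]
        y <- df[[cv]][!na]
        XtX <- crossprod(Xo)
        beta_hat <- solve(XtX, crossprod(Xo, y))
        res <- y - drop(Xo %*% beta_hat)
        dfres <- nrow(Xo) - length(keep)
        # posterior-predictive draw: sigma^2 then coefficients then noise
        sigma2 <- sum(res^2) / stats::rchisq(1L, dfres)
        beta <- beta_hat +
          drop(t(chol(sigma2 * solve(XtX))) %*% stats::rnorm(length(keep)))
        draw <- drop(mm[na, keep, drop = FALSE] %*% beta) +
          stats::rnorm(sum(na), 0, sqrt(sigma2))
        lo <- if (cv %in% c("age_at_diagnosis", "disease_duration")) 0
              else .Machine$double.eps
        work[[cv]][na] <- pmax(draw, lo)
      }
    }
    datasets[[im]] <- panel_data(work)
  }
  structure(list(datasets = datasets, m = m, seed = seed,
                 method = "chained equations, posterior-predictive draws"),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Imputation set: m =", x$m, "completed datasets (", x$method, ")\n")
  invisible(x)
}

#' Worst-case imputation reference from baseline data
#'
#' The 75th percentile of each covariate's non-missing values at the first
#' screening episode (linear interpolation between order statistics). Used
#' at prediction time to give a pessimistic ('worst case') risk when a new
#' observation arrives with missing covariates.
#'
#' @param data A [panel_data()].
#' @param covariates Covariates to summarise, default all present.
#' @return Named numeric vector of 75th percentiles.
#' @export
worst_case_reference <- function(data, covariates = NULL) {
  base <- baseline_episodes(data)
  covs <- covariates %||% intersect(dr_covariates(), names(base))
  vapply(covs, function(cv)
    stats::quantile(base[[cv]], 0.75, na.rm = TRUE, names = FALSE, type = 7),
    0.0)
}

#' Replace missing covariate values with worst-case reference percentiles
#'
#' @param covariates Named numeric vector (or one-row data.frame) of
#'   covariate values, possibly with `NA` entries.
#' @param ref Named reference percentiles from [worst_case_reference()] or
#'   a model's stored `percentile75`.
#' @return The completed vector, with attribute `"imputed"` naming the
#'   fields that were filled in.
#' @export
worst_case_impute <- function(covariates, ref) {
  x <- unlist(covariates)
  fill <- names(x)[is.na(x)]
  if (length(fill)) {
    missing_ref <- setdiff(fill, names(ref))
    if (length(missing_ref))
      stop("no reference percentile for: ", paste(missing_ref, collapse = ", "))
    x[fill] <- ref[fill]
  }
  attr(x, "imputed") <- fill
  x
}
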