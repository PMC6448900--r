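# Domain constants -----------------------------------------------------------

#' Disease states of the retinopathy progression model
#'
#' The model tracks four per-person retinopathy states: 1 = no retinopathy,
#' 2 = non-referable retinopathy in one eye, 3 = non-referable retinopathy in
#' both eyes, 4 = referable retinopathy (screen-positive). State 4 is
#' absorbing for the purposes of screening-interval allocation.
#'
#' @return Integer vector `1:4`.
#' @export
dr_states <- function() 1:4

#' Permitted instantaneous transitions
#'
#' Only six instantaneous moves are possible: 1-2, 2-1, 2-3, 2-4, 3-2 and
#' 3-4. Observed panel jumps such as 1 to 3 across a screening interval are
#' legal; they occur through intermediate states between visits.
#'
#' @return A two-column integer matrix with columns `from` and `to`, one row
#'   per permitted transition, in the canonical order used throughout the
#'   package.
#' @export
dr_transitions <- function() {
  cbind(from = c(1L, 2L, 2L, 2L, 3L, 3L),
        to   = c(2L, 1L, 3L, 4L, 2L, 4L))
}

#' Names of the clinical covariates
#'
#' The five clinical covariates of the final model, in canonical order:
#' age at diagnosis (years), disease duration (years), HbA1c (mmol/mol),
#' total cholesterol (mmol/l) and systolic blood pressure (mmHg).
#'
#' @return Character vector of column names.
#' @export
dr_covariates <- function() {
  c("age_at_diagnosis", "disease_duration", "hba1c",
    "total_cholesterol", "systolic_bp")
}

.tr_labels <- function() {
  tr <- dr_transitions()
  paste0(tr[, "from"], "-", tr[, "to"])
}

# Panel data ------------------------------------------------------------------

#' Construct and validate a screening panel dataset
#'
#' A panel dataset holds one row per screening episode: subject identifier,
#' time in years since the subject's first screen, observed disease state and
#' (optionally missing) covariate values. Validation enforces the structural
#' invariants the likelihood relies on: times start at 0 and strictly
#' increase within subject, states lie in 1-4, no sequence leaves the
#' absorbing state 4, every subject has at least two episodes, and every
#' subject is screen-negative (state 1-3) at baseline.
#'
#' @param df A data.frame with columns `subject_id`, `time_years`, `state`
#'   and any subset of [dr_covariates()].
#' @return A validated `panel_data` object (a data.frame sorted by subject
#'   and time).
#' @export
panel_data <- function(df) {
  req <- c("subject_id", "time_years", "state")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("panel data lacks required column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  df$subject_id <- as.character(df$subject_id)
  df$time_years <- as.numeric(df$time_years)
  df$state <- as.integer(df$state)
  covs <- intersect(dr_covariates(), names(df))
  for (cv in covs) df[[cv]] <- as.numeric(df[[cv]])
  df <- df[order(df$subject_id, df$time_years), , drop = FALSE]
  rownames(df) <- NULL
  .validate_panel(df)
  structure(df, class = c("panel_data", "data.frame"))
}

.validate_panel <- function(df) {
  if (anyNA(df$state) || any(df$state < 1L | df$state > 4L)) {
    bad <- unique(df$subject_id[is.na(df$state) | df$state < 1L | df$state > 4L])
    stop("state outside 1-4 for subject(s): ", paste(bad, collapse = ", "))
  }
  covs <- intersect(dr_covariates(), names(df))
  for (cv in covs) {
    v <- df[[cv]]
    lo <- if (cv %in% c("age_at_diagnosis", "disease_duration")) 0 else .Machine$double.xmin
    bad <- !is.na(v) & (!is.finite(v) | v < lo)
    if (any(bad))
      stop("invalid ", cv, " (must be finite and ",
           if (lo == 0) ">= 0" else "> 0", ") for subject(s): ",
           paste(unique(df$subject_id[bad]), collapse = ", "))
  }
  sp <- split(seq_len(nrow(df)), df$subject_id)
  for (id in names(sp)) {
    i <- sp[[id]]
    tm <- df$time_years[i]
    st <- df$state[i]
    if (length(i) < 2L)
      stop("subject ", id, " has fewer than two screening episodes")
    if (abs(tm[1L]) > 1e-9)
      stop("first episode of subject ", id, " is not at time 0")
    if (any(diff(tm) <= 0))
      stop("non-increasing times within subject ", id)
    if (st[1L] == 4L)
      stop("subject ", id, " is screen-positive (state 4) at baseline")
    k <- which(st == 4L)
    if (length(k) && any(seq_along(st) > k[1L]))
      stop("subject ", id, " leaves the absorbing state 4")
  }
  invisible(df)
}

#' Read a screening panel from a delimited text file
#'
#' @param path Path to a CSV file with a header row. Required columns (after
#'   applying `schema`): `subject_id`, `time_years`, `state`. Covariate
#'   columns are optional; empty cells are read as missing.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(subject_id = "id", time_years = "t")`.
#' @param sep Field separator, default comma.
#' @return A validated [panel_data()] object.
#' @export
read_panel <- function(path, schema = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df))
        stop("schema column '", schema[[canon]], "' not found in ", path)
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  panel_data(df)
}

#' Write a screening panel to CSV
#'
#' Inverse of [read_panel()]: missing covariates become empty cells, so a
#' write/read round trip reproduces the dataset.
#'
#' @param data A [panel_data()] object.
#' @param path Output file path.
#' @export
write_panel <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Subject count of a panel dataset
#' @param data A [panel_data()] object.
#' @return Number of distinct subjects.
#' @export
n_subjects <- function(data) length(unique(data$subject_id))

#' @export
print.panel_data <- function(x, ...) {
  covs <- intersect(dr_covariates(), names(x))
  nmiss <- sum(is.na(as.matrix(x[covs])))
  cat("Screening panel: ", n_subjects(x), " subjects, ", nrow(x),
      " episodes, ", sum(x$state == 4L), " screen-positive\n", sep = "")
  if (length(covs))
    cat("Covariates: ", paste(covs, collapse = ", "),
        " (", nmiss, " missing values)\n", sep = "")
  invisible(x)
}

#' First-episode (baseline) rows of a panel
#' @param data A [panel_data()] object.
#' @return A data.frame with one row per subject, their baseline episode.
#' @export
baseline_episodes <- function(data) {
  df <- as.data.frame(data)
  df[!duplicated(df$subject_id), , drop = FALSE]
}

# Fix disease duration at its baseline value within each subject.  The
# default analysis treats duration as assigned at the first screening
# episode; updating it per episode is available by skipping this step.
.fix_baseline_duration <- function(df) {
  if (!"disease_duration" %in% names(df)) return(df)
  base <- df$disease_duration[!duplicated(df$subject_id)]
  names(base) <- df$subject_id[!duplicated(df$subject_id)]
  df$disease_duration <- unname(base[df$subject_id])
  df
}

# Transition model ------------------------------------------------------------

#' Construct a transition model
#'
#' A transition model carries, for each of the six permitted transitions, an
#' intercept (log baseline intensity) and log hazard-ratio coefficients for
#' the active covariates, plus the shared Weibull shape `alpha` and the
#' covariate centering constants subtracted before the log-linear predictor
#' is evaluated. `exp` of any coefficient is the per-unit hazard ratio for
#' that transition.
#'
#' @param intercepts Numeric vector of length 6, named by transition labels
#'   (`"1-2"`, `"2-1"`, ...) or in canonical [dr_transitions()] order.
#' @param coefficients Numeric matrix, 6 rows (transitions) by one column
#'   per active covariate; may have zero columns. Column names must be a
#'   subset of [dr_covariates()].
#' @param alpha Weibull shape parameter (> 0); `alpha < 1` concentrates
#'   transitions early in follow-up.
#' @param centering Named numeric vector of centering constants, one per
#'   active covariate (typically cohort means at first screening).
#' @param percentile75 Optional named numeric vector of 75th-percentile
#'   reference values used for worst-case imputation at prediction time.
#' @return A `transition_model` object.
#' @export
transition_model <- function(intercepts, coefficients = NULL, alpha = 0.9,
                             centering = NULL, percentile75 = NULL) {
  labs <- .tr_labels()
  intercepts <- as.numeric(intercepts)
  if (length(intercepts) != 6L)
    stop("need 6 intercepts, one per permitted transition")
  names(intercepts) <- labs
  if (is.null(coefficients)) {
    coefficients <- matrix(numeric(0), nrow = 6L, ncol = 0L,
                           dimnames = list(labs, NULL))
  } else {
    coefficients <- as.matrix(coefficients)
    if (nrow(coefficients) != 6L)
      stop("coefficient matrix must have 6 rows (permitted transitions)")
    bad <- setdiff(colnames(coefficients), dr_covariates())
    if (is.null(colnames(coefficients)) || length(bad))
      stop("coefficient columns must be named by covariates; unknown: ",
           paste(bad, collapse = ", "))
    rownames(coefficients) <- labs
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("alpha must be a single positive number")
  active <- colnames(coefficients)
  if (is.null(centering)) centering <- stats::setNames(rep(0, length(active)), active)
  if (length(active) && !all(active %in% names(centering)))
    stop("centering constants required for all active covariates")
  centering <- centering[active]
  structure(list(intercepts = intercepts,
                 coefficients = coefficients,
                 alpha = alpha,
                 centering = centering,
                 percentile75 = percentile75),
            class = "transition_model")
}

#' Per-unit hazard ratios of a transition model
#' @param model A [transition_model()].
#' @return Matrix of `exp(coefficient)`, 6 transitions by active covariates.
#' @export
hazard_ratios <- function(model) exp(model$coefficients)

#' @export
print.transition_model <- function(x, ...) {
  cat("Four-state retinopathy transition model\n")
  cat("  Weibull shape alpha:", format(x$alpha, digits = 4), "\n")
  cat("  Baseline intensities exp(intercept):\n")
  print(round(exp(x$intercepts), 5))
  if (ncol(x$coefficients)) {
    cat("  Per-unit hazard ratios:\n")
    print(round(hazard_ratios(x), 5))
  }
  invisible(x)
}

#' Serialize a transition model to a flat key/value text file
#'
#' The on-disk format is one `key: value` pair per line, with full-precision
#' numbers, covering the shape parameter, intercepts, coefficients, centering
#' constants and (if present) the worst-case imputation percentiles, so a
#' write/read round trip is lossless and a deployed model file is
#' self-contained.
#'
#' @param model A [transition_model()].
#' @param path Output file path.
#' @export
write_model <- function(model, path) {
  num <- function(v) formatC(v, format = "g", digits = 17)
  lines <- c("format: retscreen-model 1",
             paste0("alpha: ", num(model$alpha)))
  for (k in seq_len(6L))
    lines <- c(lines, paste0("intercept.", .tr_labels()[k], ": ",
                             num(model$intercepts[k])))
  for (cv in colnames(model$coefficients)) {
    lines <- c(lines, paste0("center.", cv, ": ", num(model$centering[[cv]])))
    for (k in seq_len(6L))
      lines <- c(lines, paste0("coef.", .tr_labels()[k], ".", cv, ": ",
                               num(model$coefficients[k, cv])))
  }
  for (cv in names(model$percentile75))
    lines <- c(lines, paste0("percentile75.", cv, ": ",
                             num(model$percentile75[[cv]])))
  writeLines(lines, path)
  invisible(path)
}

#' Read a transition model from its key/value text file
#' @param path Path written by [write_model()].
#' @return A [transition_model()].
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):[[:space:]]*(.*)$", lines))
  if (any(lengths(kv) != 3L)) stop("malformed model file: ", path)
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  if (!identical(vals[keys == "format"], "retscreen-model 1"))
    stop("unrecognised model file format in ", path)
  get1 <- function(k) {
    i <- which(keys == k)
    if (!length(i)) stop("model file missing required key '", k, "'")
    as.numeric(vals[i[1L]])
  }
  alpha <- get1("alpha")
  labs <- .tr_labels()
  intercepts <- vapply(paste0("intercept.", labs), get1, 0.0)
  covs <- unique(sub("^center\\.", "", keys[startsWith(keys, "center.")]))
  coefficients <- NULL
  centering <- NULL
  if (length(covs)) {
    coefficients <- sapply(covs, function(cv)
      vapply(paste0("coef.", labs, ".", cv), get1, 0.0))
    coefficients <- matrix(coefficients, nrow = 6L,
                           dimnames = list(labs, covs))
    centering <- stats::setNames(vapply(paste0("center.", covs), get1, 0.0), covs)
  }
  p75keys <- keys[startsWith(keys, "percentile75.")]
  percentile75 <- NULL
  if (length(p75keys)) {
    pc <- sub("^percentile75\\.", "", p75keys)
    percentile75 <- stats::setNames(vapply(paste0("percentile75.", pc), get1, 0.0), pc)
  }
  transition_model(intercepts, coefficients, alpha, centering, percentile75)
}
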