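#' Describe the regression model shared by every node
#'
#' A design specification names the model family, the outcome (or
#' time/event pair for Cox models), and the ordered covariate list.  The
#' same specification is distributed to every data partner with the
#' analysis package, so the model matrix has identical column order at
#' every site — a requirement for aggregating score vectors and
#' information matrices elementwise.
#'
#' Linear and logistic models always include an intercept; the Cox
#' partial likelihood has none, so `include_intercept` is forced to
#' `FALSE` for that family regardless of the argument.
#'
#' @param family One of `"linear"`, `"logistic"`, `"cox"`.
#' @param covariates Character vector of covariate column names, in the
#'   order they enter the model.  Must be non-empty and duplicate-free.
#' @param outcome Outcome column name (linear/logistic).
#' @param time,event Follow-up time and event-indicator column names
#'   (Cox only).
#' @param include_intercept Ignored for Cox; must be `TRUE` otherwise.
#' @return An object of class `dra_design`.
#' @examples
#' design_spec("logistic", covariates = c("x1", "x2"))
#' @export
design_spec <- function(family = c("linear", "logistic", "cox"),
                        covariates,
                        outcome = "y",
                        time = "time",
                        event = "event",
                        include_intercept = TRUE) {
  family <- match.arg(family)
  if (!is.character(covariates) || length(covariates) == 0L)
    abort_config("'covariates' must be a non-empty character vector")
  if (anyDuplicated(covariates))
    abort_config("'covariates' contains duplicated names")
  include_intercept <- if (family == "cox") FALSE else TRUE
  spec <- list(
    family            = family,
    covariate_columns = covariates,
    outcome_column    = if (family != "cox") outcome else NA_character_,
    time_column       = if (family == "cox") time else NA_character_,
    event_column      = if (family == "cox") event else NA_character_,
    include_intercept = include_intercept
  )
  class(spec) <- "dra_design"
  spec
}

#' Number of model parameters implied by a design
#'
#' @param spec A [design_spec()].
#' @return Integer: covariate count plus one when an intercept is included.
#' @export
design_p <- function(spec) {
  length(spec$covariate_columns) + as.integer(spec$include_intercept)
}

#' Names of the model coefficients, in model-matrix order
#' @param spec A [design_spec()].
#' @return Character vector of length [design_p()].
#' @export
design_terms <- function(spec) {
  c(if (spec$include_intercept) "(Intercept)", spec$covariate_columns)
}

used_columns <- function(spec) {
  if (spec$family == "cox")
    c(spec$time_column, spec$event_column, spec$covariate_columns)
  else
    c(spec$outcome_column, spec$covariate_columns)
}

#' Build the local model matrix and outcome arrays
#'
#' Converts a partner's patient-level analytic dataset into the numeric
#' arrays the local statistics functions consume.  Column order is
#' `[intercept] + covariates` as fixed by the design, and row order is
#' preserved.  Missing values are never dropped silently: any `NA` in a
#' used column is an error, because complete-case handling belongs to
#' the upstream dataset-curation step, not the regression engine.
#'
#' @param dataset A data frame (one row per patient).
#' @param spec A [design_spec()].
#' @return A list with `X` (n-by-p matrix) and either `y` (linear,
#'   logistic) or `time` and `event` (Cox).
#' @export
build_model_matrix <- function(dataset, spec) {
  stopifnot(is.data.frame(dataset), inherits(spec, "dra_design"))
  need <- used_columns(spec)
  missing_cols <- setdiff(need, names(dataset))
  if (length(missing_cols))
    abort_schema(sprintf("dataset is missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  used <- dataset[need]
  bad <- !stats::complete.cases(used)
  if (any(bad))
    abort_data(sprintf("%d row(s) contain missing values in model columns", sum(bad)))

  n <- nrow(dataset)
  Xc <- as.matrix(as.data.frame(lapply(dataset[spec$covariate_columns], as.numeric)))
  if (n == 0L) Xc <- matrix(numeric(0), 0L, length(spec$covariate_columns))
  if (spec$include_intercept) {
    X <- cbind(1, Xc)
  } else {
    X <- Xc
  }
  colnames(X) <- design_terms(spec)
  if (spec$family == "cox") {
    list(X = X,
         time = as.numeric(dataset[[spec$time_column]]),
         event = as.numeric(dataset[[spec$event_column]]))
  } else {
    list(X = X, y = as.numeric(dataset[[spec$outcome_column]]))
  }
}
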