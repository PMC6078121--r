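#' Covariate distribution specifications
#'
#' Building blocks for [cohort_spec()]: each covariate is drawn i.i.d.
#' from a standard normal, a Bernoulli(q), or a uniform(a, b)
#' distribution.
#'
#' @param name Covariate column name.
#' @param q Success probability (Bernoulli).
#' @param a,b Lower and upper bounds (uniform).
#' @return A covariate specification list.
#' @export
cov_normal <- function(name) {
  list(name = name, dist = "standard_normal")
}

#' @rdname cov_normal
#' @export
cov_bernoulli <- function(name, q) {
  if (q <= 0 || q >= 1) abort_config("Bernoulli q must be in (0, 1)")
  list(name = name, dist = "bernoulli", q = q)
}

#' @rdname cov_normal
#' @export
cov_uniform <- function(name, a, b) {
  if (a >= b) abort_config("uniform bounds require a < b")
  list(name = name, dist = "uniform", a = a, b = b)
}

#' Specify a multi-partner synthetic cohort with known truth
#'
#' Describes the de-identified patient-level analytic datasets assembled
#' at each data partner: how many partners, how many patients at each,
#' the covariate distributions, the model family, and the true parameter
#' vector that generated the outcomes — so every downstream stage can be
#' validated against known truth.
#'
#' Outcome models, given the linear predictor `eta = X beta + site shift`:
#' linear `y = eta + N(0, 1)`; logistic `y ~ Bernoulli(expit(eta))`;
#' Cox: event times exponential with rate `exp(eta)` (baseline rate 1,
#' no intercept in beta), censoring times exponential with rate
#' `censoring_rate` (0 = no censoring), observed time the minimum.
#' An optional random site effect (`site_effect_sd > 0`) shifts each
#' partner's intercept (or log-hazard), emulating between-site
#' heterogeneity; it is exactly absorbed by site stratification in the
#' Cox fit.
#'
#' @param family Model family.
#' @param n_partners Number of partners.
#' @param n_per_partner Integer vector (recycled) of per-partner sizes.
#' @param covariates List of covariate specs ([cov_normal()] etc.).
#' @param true_beta True parameters: intercept first for linear and
#'   logistic; covariate effects only for Cox.
#' @param censoring_rate Exponential censoring rate (Cox only).
#' @param site_effect_sd Standard deviation of the random site shift.
#' @param seed Base seed; each partner draws from a substream derived
#'   deterministically from `(seed, partner_id)`.
#' @return A `dra_cohort_spec` object.
#' @export
cohort_spec <- function(family = c("linear", "logistic", "cox"),
                        n_partners, n_per_partner, covariates, true_beta,
                        censoring_rate = 0.5, site_effect_sd = 0, seed = 1L) {
  family <- match.arg(family)
  n_partners <- as.integer(n_partners)
  if (n_partners < 1L) abort_config("n_partners must be >= 1")
  n_per_partner <- rep_len(as.integer(n_per_partner), n_partners)
  if (any(n_per_partner <= 0L)) abort_config("n_per_partner must all be > 0")
  if (!length(covariates)) abort_config("at least one covariate is required")
  p_expected <- length(covariates) + as.integer(family != "cox")
  if (length(true_beta) != p_expected)
    abort_config(sprintf(
      "true_beta has length %d but family '%s' with %d covariate(s) needs %d",
      length(true_beta), family, length(covariates), p_expected))
  if (site_effect_sd < 0) abort_config("site_effect_sd must be >= 0")
  if (family == "cox" && censoring_rate < 0)
    abort_config("censoring_rate must be >= 0")
  structure(list(family = family, n_partners = n_partners,
                 n_per_partner = n_per_partner, covariates = covariates,
                 true_beta = as.numeric(true_beta),
                 censoring_rate = censoring_rate,
                 site_effect_sd = site_effect_sd,
                 seed = as.integer(seed)),
            class = "dra_cohort_spec")
}

#' The package's standard study cohorts
#'
#' The reference conditions used throughout the documentation, test
#' suite, and demonstration runs: three partners of 2000 patients each,
#' three covariates (standard normal, Bernoulli(0.4), uniform(-1, 1)),
#' and moderate true effects.  The Cox cohort adds a random site effect
#' (sd 0.3) — the scenario that motivates site-stratified risk sets —
#' and exponential censoring at rate 0.5 (roughly one third censored).
#'
#' @param family Model family.
#' @param seed Base seed.
#' @return A [cohort_spec()].
#' @export
standard_cohort_spec <- function(family = c("linear", "logistic", "cox"),
                                 seed = 20180525L) {
  family <- match.arg(family)
  covs <- list(cov_normal("x1"), cov_bernoulli("x2", 0.4),
               cov_uniform("x3", -1, 1))
  switch(family,
    linear = cohort_spec("linear", 3L, 2000L, covs,
                         true_beta = c(1.0, 0.5, -0.5, 0.25), seed = seed),
    logistic = cohort_spec("logistic", 3L, 2000L, covs,
                           true_beta = c(-0.5, 0.4, -0.3, 0.6), seed = seed),
    cox = cohort_spec("cox", 3L, 2000L, covs,
                      true_beta = c(0.5, -0.3, 0.25),
                      censoring_rate = 0.5, site_effect_sd = 0.3,
                      seed = seed))
}

# deterministic per-partner substream seed; keeps partner datasets
# individually reproducible and below the 32-bit integer bound
partner_substream_seed <- function(seed, partner_id) {
  as.integer((as.double(seed) * 7919 + as.double(partner_id) * 104729) %%
               2147483647)
}

draw_covariate <- function(cv, n) {
  switch(cv$dist,
    standard_normal = stats::rnorm(n),
    bernoulli = stats::rbinom(n, 1L, cv$q),
    uniform = stats::runif(n, cv$a, cv$b),
    abort_config(sprintf("unknown covariate distribution '%s'", cv$dist)))
}

with_local_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one partner's analytic dataset
#'
#' Draws the partner's patients from the cohort specification using a
#' deterministic per-partner random substream, so the same
#' `(spec, partner_id)` pair always yields the identical dataset and
#' partners are mutually independent.  Patient identifiers are opaque
#' and site-local.
#'
#' @param spec A [cohort_spec()].
#' @param partner_id Partner index in `1:n_partners`.
#' @return A data frame: `patient_id`, covariates, and the outcome
#'   columns (`y`, or `time` + `event`).
#' @export
generate_partner_dataset <- function(spec, partner_id) {
  stopifnot(inherits(spec, "dra_cohort_spec"))
  partner_id <- as.integer(partner_id)
  if (is.na(partner_id) || partner_id < 1L || partner_id > spec$n_partners)
    abort_config(sprintf("partner_id must be in 1..%d", spec$n_partners))
  n <- spec$n_per_partner[partner_id]
  with_local_rng(partner_substream_seed(spec$seed, partner_id), {
    site_shift <- if (spec$site_effect_sd > 0)
      spec$site_effect_sd * stats::rnorm(1L) else 0
    X <- vapply(spec$covariates, draw_covariate, numeric(n), n = n)
    if (n == 1L) X <- matrix(X, 1L)
    colnames(X) <- vapply(spec$covariates, `[[`, "", "name")
    ds <- data.frame(patient_id = sprintf("S%d-%06d", partner_id, seq_len(n)),
                     X, check.names = FALSE, stringsAsFactors = FALSE)
    if (spec$family == "cox") {
      eta <- drop(X %*% spec$true_beta) + site_shift
      t_event <- stats::rexp(n, rate = exp(eta))
      if (spec$censoring_rate > 0) {
        t_cens <- stats::rexp(n, rate = spec$censoring_rate)
        ds$time <- pmin(t_event, t_cens)
        ds$event <- as.integer(t_event <= t_cens)
      } else {
        ds$time <- t_event
        ds$event <- 1L
      }
    } else {
      eta <- drop(cbind(1, X) %*% spec$true_beta) + site_shift
      ds$y <- if (spec$family == "linear") eta + stats::rnorm(n)
              else stats::rbinom(n, 1L, stats::plogis(eta))
    }
    ds
  })
}

#' Write / read an analytic dataset as delimited text
#'
#' Comma-delimited UTF-8 with a header row; numeric columns are written
#' with 17 significant digits so the round trip is lossless for IEEE
#' doubles.  Columns are mapped by name on read, so reordered columns
#' are accepted; any missing value is a parse error naming the first
#' offending line, because analytic datasets are required to be complete
#' before the regression engine ever sees them.
#'
#' @param dataset Data frame to write.
#' @param path File path.
#' @return `write_dataset`: `path`, invisibly.  `read_dataset`: the
#'   data frame.
#' @export
write_dataset <- function(dataset, path) {
  out <- dataset
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], fmt17)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("dataset file '%s' not found", path))
  ds <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) abort_parse(sprintf("cannot parse '%s': %s", path,
                                            conditionMessage(e))))
  bad <- which(!stats::complete.cases(ds))
  if (length(bad))
    abort_parse(sprintf("missing value in '%s' at data line %d",
                        basename(path), bad[1L] + 1L))  # +1 for header row
  ds
}
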