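test_that("model matrix construction honors the design contract", {
  ds <- data.frame(patient_id = c("a", "b", "c"), x1 = c(0.5, -1, 2),
                   y = c(0, 1, 1))
  mm <- build_model_matrix(ds, design_spec("logistic", "x1"))
  expect_equal(dim(mm$X), c(3L, 2L))
  expect_equal(mm$X[, 1L], rep(1, 3))
  expect_equal(colnames(mm$X), c("(Intercept)", "x1"))
  expect_equal(mm$y, c(0, 1, 1))

  # Cox never gets an intercept, even if requested
  dsc <- data.frame(x1 = rnorm(3), time = c(1, 2, 3), event = c(1, 0, 1))
  spc <- design_spec("cox", "x1", include_intercept = TRUE)
  expect_false(spc$include_intercept)
  mmc <- build_model_matrix(dsc, spc)
  expect_equal(ncol(mmc$X), 1L)

  expect_error(build_model_matrix(data.frame(x1 = 1, time = 1),
                                  design_spec("cox", "x1")),
               class = "dra_schema_error")
  ds$x1[2] <- NA
  expect_error(build_model_matrix(ds, design_spec("logistic", "x1")),
               "1 row", class = "dra_data_error")
  expect_error(design_spec("logistic", c("a", "a")),
               class = "dra_config_error")
})

test_that("linear summaries match hand arithmetic and are additive", {
  s <- linear_local_summaries(matrix(1, 3, 1), c(1, 2, 3))
  expect_equal(s$xtx, matrix(3, 1, 1))
  expect_equal(s$xty, 6)
  expect_equal(s$yty, 14)
  expect_equal(s$n, 3L)

  empty <- linear_local_summaries(matrix(numeric(0), 0, 2), numeric(0))
  expect_equal(empty$n, 0L)
  expect_equal(empty$xtx, matrix(0, 2, 2))

  expect_error(linear_local_summaries(matrix(c(1, NA), 2, 1), c(1, 2)),
               class = "dra_data_error")

  # additivity over random partitions (concatenation oracle)
  set.seed(11)
  for (rep in 1:5) {
    X <- cbind(1, matrix(rnorm(60), 20))
    y <- rnorm(20)
    cut <- sample(2:18, 1)
    a <- linear_local_summaries(X[1:cut, , drop = FALSE], y[1:cut],
                                partner_id = 1)
    b <- linear_local_summaries(X[(cut + 1):20, , drop = FALSE],
                                y[(cut + 1):20], partner_id = 2)
    tot <- aggregate_statistics(list(a, b))
    whole <- linear_local_summaries(X, y)
    expect_equal(tot$xtx, whole$xtx)
    expect_equal(tot$xty, whole$xty)
    expect_equal(tot$yty, whole$yty)
    expect_equal(tot$n, whole$n)
  }
})

test_that("distributed linear solve equals pooled least squares", {
  # intercept-only pooled mean across two partners
  a <- linear_local_summaries(matrix(1, 3, 1), c(1, 2, 3), partner_id = 1)
  b <- linear_local_summaries(matrix(1, 2, 1), c(1.5, 2.5), partner_id = 2)
  fit <- linear_solve(aggregate_statistics(list(a, b)))
  expect_equal(unname(fit$beta_hat), 2.0)
  expect_equal(fit$n_iterations, 1L)
  expect_true(fit$converged)

  # noise-free y = 2x recovered exactly
  set.seed(1)
  x <- rnorm(10)
  a <- linear_local_summaries(cbind(1, x[1:6]), 2 * x[1:6], partner_id = 1)
  b <- linear_local_summaries(cbind(1, x[7:10]), 2 * x[7:10], partner_id = 2)
  fit <- linear_solve(aggregate_statistics(list(a, b)))
  expect_equal(unname(fit$beta_hat), c(0, 2), tolerance = 1e-10)
  expect_lt(fit$sigma2, 1e-12)   # exact fit up to SSCP cancellation error

  # random two-partner data vs pooled lm oracle
  set.seed(2)
  X <- cbind(1, matrix(rnorm(80), 40))
  y <- drop(X %*% c(1, -0.5, 0.25)) + rnorm(40)
  parts <- list(1:25, 26:40)
  ss <- lapply(seq_along(parts), function(k)
    linear_local_summaries(X[parts[[k]], ], y[parts[[k]]], partner_id = k))
  fit <- linear_solve(aggregate_statistics(ss))
  ref <- lm(y ~ X - 1)
  expect_equal(unname(fit$beta_hat), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-8)

  # guards: rank deficiency and n <= p
  dup <- linear_local_summaries(cbind(1, x, x), rnorm(10))
  expect_error(linear_solve(dup), "rank deficient",
               class = "dra_estimation_error")
  tiny <- linear_local_summaries(matrix(1, 1, 2), 1)
  expect_error(linear_solve(tiny), class = "dra_estimation_error")
})

test_that("logistic local statistics match closed forms and brute force", {
  X <- matrix(1, 50, 1)
  y <- rep(c(1, 0), c(30, 20))
  si <- logistic_local_score_info(X, y, 0)
  expect_equal(si$gradient, 5.0)
  expect_equal(si$information, matrix(12.5, 1, 1))
  expect_equal(si$loglik, 50 * log(0.5))
  expect_equal(si$n_events, 30L)

  # guarded logs keep the loglik finite under extreme beta
  si2 <- logistic_local_score_info(matrix(1, 20, 1), rep(0, 20), 500)
  expect_true(is.finite(si2$loglik))
  expect_lt(si2$loglik, -1e3)
  expect_lte(si2$loglik, 0)

  expect_error(logistic_local_score_info(X, y + 0.5, 0),
               class = "dra_data_error")

  # two-partner aggregation vs per-patient brute force at arbitrary beta
  set.seed(3)
  Xr <- cbind(1, matrix(rnorm(60), 30))
  yr <- rbinom(30, 1, 0.5)
  beta <- c(0.3, -0.7, 0.2)
  a <- logistic_local_score_info(Xr[1:12, ], yr[1:12], beta, partner_id = 1)
  b <- logistic_local_score_info(Xr[13:30, ], yr[13:30], beta, partner_id = 2)
  tot <- aggregate_statistics(list(a, b))
  ref <- logistic_oracle(Xr, yr, beta)
  expect_equal(tot$gradient, ref$gradient, tolerance = 1e-12)
  expect_equal(tot$information, ref$information, tolerance = 1e-12)
  expect_equal(tot$loglik, ref$loglik, tolerance = 1e-12)
})

test_that("cox local statistics match risk-set enumeration and stratified pooling", {
  # no events: zero contribution
  z <- cox_local_score_info(matrix(rnorm(5), 5, 1), 1:5, rep(0, 5), 0.5)
  expect_equal(z$gradient, 0)
  expect_equal(z$information, matrix(0, 1, 1))
  expect_equal(z$loglik, 0)

  # at beta = 0 the score is sum over events of (x_i - risk-set mean of x)
  set.seed(4)
  x <- rbinom(12, 1, 0.5)
  tt <- sample(seq(0.1, 1.2, by = 0.1))   # distinct times
  ev <- rbinom(12, 1, 0.7)
  si <- cox_local_score_info(matrix(x), tt, ev, 0)
  manual <- sum(vapply(which(ev == 1), function(i)
    x[i] - mean(x[tt >= tt[i]]), 0))
  expect_equal(si$gradient, manual, tolerance = 1e-12)

  # arbitrary beta, with ties, vs direct enumeration oracle
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  tt <- sample(c(0.5, 1, 1.5, 2, 3), 20, replace = TRUE)  # heavy ties
  ev <- rbinom(20, 1, 0.6)
  beta <- c(0.4, -0.6)
  si <- cox_local_score_info(X, tt, ev, beta)
  ref <- cox_oracle(X, tt, ev, beta)
  expect_equal(si$gradient, ref$gradient, tolerance = 1e-12)
  expect_equal(si$information, ref$information, tolerance = 1e-10)
  expect_equal(si$loglik, ref$loglik, tolerance = 1e-12)

  # summed partner payloads = pooled stratified statistics
  a <- cox_local_score_info(X[1:8, ], tt[1:8], ev[1:8], beta, partner_id = 1)
  b <- cox_local_score_info(X[9:20, ], tt[9:20], ev[9:20], beta,
                            partner_id = 2)
  tot <- aggregate_statistics(list(a, b))
  refA <- cox_oracle(X[1:8, ], tt[1:8], ev[1:8], beta)
  refB <- cox_oracle(X[9:20, ], tt[9:20], ev[9:20], beta)
  expect_equal(tot$gradient, refA$gradient + refB$gradient,
               tolerance = 1e-12)
  expect_equal(tot$loglik, refA$loglik + refB$loglik, tolerance = 1e-12)

  expect_error(cox_local_score_info(X, tt - 1, ev, beta),
               class = "dra_data_error")
})

test_that("aggregation validates protocol consistency", {
  X <- cbind(1, rnorm(10))
  y <- rbinom(10, 1, 0.5)
  one <- logistic_local_score_info(X, y, c(0, 0), iteration = 3,
                                   partner_id = 1)
  solo <- aggregate_statistics(list(one))
  expect_equal(solo$gradient, one$gradient)
  expect_equal(solo$information, one$information)

  stale <- logistic_local_score_info(X, y, c(0, 0), iteration = 4,
                                     partner_id = 2)
  expect_error(aggregate_statistics(list(one, stale)), "partner",
               class = "dra_protocol_error")
  shrunk <- logistic_local_score_info(X[, 1, drop = FALSE], y, 0,
                                      iteration = 3, partner_id = 2)
  expect_error(aggregate_statistics(list(one, shrunk)),
               class = "dra_protocol_error")

  # manual elementwise addition of three payloads
  set.seed(6)
  pls <- lapply(1:3, function(k) {
    Xk <- cbind(1, rnorm(15))
    logistic_local_score_info(Xk, rbinom(15, 1, 0.4), c(0.1, -0.2),
                              iteration = 1, partner_id = k)
  })
  tot <- aggregate_statistics(pls)
  expect_equal(tot$gradient, pls[[1]]$gradient + pls[[2]]$gradient +
                 pls[[3]]$gradient)
  expect_equal(tot$information, pls[[1]]$information + pls[[2]]$information +
                 pls[[3]]$information)
  expect_equal(tot$n, 45L)
})

test_that("newton updates, convergence assessment, and Wald inference", {
  X <- matrix(1, 50, 1)
  y <- rep(c(1, 0), c(30, 20))
  si <- logistic_local_score_info(X, y, 0)
  expect_equal(newton_step(0, si)$beta_new, 0.4)

  # zero gradient leaves beta unchanged
  at_mle <- logistic_local_score_info(X, y, log(30 / 20))
  expect_equal(newton_step(log(30 / 20), at_mle)$beta_new, log(30 / 20),
               tolerance = 1e-12)

  # iterating converges to logit of the sample proportion
  beta <- 0
  for (i in 1:8)
    beta <- newton_step(beta, logistic_local_score_info(X, y, beta))$beta_new
  expect_equal(beta, log(30 / 20), tolerance = 1e-12)

  st <- assess_convergence(c(1, 2), c(1, 2), -10, -10, 1e-6, 25, 5)
  expect_equal(st$state, "converged")
  st <- assess_convergence(0, 1e-3, -10, -9, 1e-6, 25, 25)
  expect_equal(st$state, "max_iterations_reached")
  st <- assess_convergence(0, NaN, -10, -9, 1e-6, 25, 2)
  expect_equal(st$state, "failed")
  expect_match(st$message, "non-finite")

  # closed-form standard errors
  w <- wald_inference("logistic", c(0.5, -1), diag(c(4, 25)))
  expect_equal(w$se, c(0.5, 0.2))
  expect_equal(w$ci95[1, ], c(lower = 0.5 - 1.959964 * 0.5,
                              upper = 0.5 + 1.959964 * 0.5))
  expect_equal(w$wald_z, c(1, -5))
  expect_error(wald_inference("logistic", c(0, 0), matrix(1, 2, 2)),
               class = "dra_estimation_error")

  # intercept-only logistic at the MLE with n = 100, half cases: se = 0.2
  X100 <- matrix(1, 100, 1)
  y100 <- rep(0:1, 50)
  siM <- logistic_local_score_info(X100, y100, 0)
  expect_equal(wald_inference("logistic", 0, siM$information)$se, 0.2)
})

test_that("singular information reports a separation/collinearity diagnosis", {
  X <- cbind(1, rep(1, 10))   # collinear with the intercept
  si <- logistic_local_score_info(X, rbinom(10, 1, 0.5), c(0, 0))
  expect_error(newton_step(c(0, 0), si), "collinear",
               class = "dra_estimation_error")
})

test_that("covariate rescaling inversely rescales its estimate", {
  cohort <- small_logistic_cohort()
  parts <- lapply(1:3, function(k) generate_partner_dataset(cohort, k))
  spec <- design_spec("logistic", c("x1", "x2", "x3"))
  base <- dra_fit(parts, spec)
  scaled <- lapply(parts, function(d) { d$x1 <- d$x1 * 10; d })
  fit10 <- dra_fit(scaled, spec)
  expect_equal(fit10$beta_hat[["x1"]], base$beta_hat[["x1"]] / 10,
               tolerance = 1e-8)

  lin <- cohort_spec("linear", 2L, 100L, list(cov_normal("x1")),
                     true_beta = c(1, 2), seed = 7L)
  lparts <- lapply(1:2, function(k) generate_partner_dataset(lin, k))
  lspec <- design_spec("linear", "x1")
  b1 <- dra_fit(lparts, lspec)
  lscaled <- lapply(lparts, function(d) { d$x1 <- d$x1 / 4; d })
  b2 <- dra_fit(lscaled, lspec)
  expect_equal(b2$beta_hat[["x1"]], b1$beta_hat[["x1"]] * 4,
               tolerance = 1e-10)
})

test_that("partner order does not change aggregated statistics or estimates", {
  cohort <- small_logistic_cohort()
  parts <- lapply(1:3, function(k) generate_partner_dataset(cohort, k))
  spec <- design_spec("logistic", c("x1", "x2", "x3"))
  mm <- lapply(parts, build_model_matrix, spec = spec)
  beta <- c(0.1, -0.2, 0.3, 0)
  pls <- lapply(1:3, function(k)
    logistic_local_score_info(mm[[k]]$X, mm[[k]]$y, beta, partner_id = k))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    tot <- aggregate_statistics(pls[perm])
    ref <- aggregate_statistics(pls)
    expect_identical(tot$gradient, ref$gradient)
    expect_identical(tot$information, ref$information)
    expect_identical(tot$loglik, ref$loglik)
  }
  fit_a <- dra_fit(parts, spec)
  fit_b <- dra_fit(parts[c(3, 1, 2)], spec)
  # datasets keep their partner identity only through ordering here, so
  # permuting the list relabels partners; estimates must be unchanged
  expect_equal(fit_b$beta_hat, fit_a$beta_hat, tolerance = 1e-12)
})

test_that("step-halving keeps the aggregated log-likelihood non-decreasing", {
  # a separated-ish dataset provokes big Newton steps early on
  set.seed(8)
  n <- 60
  x <- rnorm(n)
  y <- as.numeric(x + rnorm(n, sd = 0.3) > 0)
  ds <- data.frame(patient_id = as.character(1:n), x1 = x, y = y)
  fit <- dra_fit(list(ds[1:30, ], ds[31:60, ]), design_spec("logistic", "x1"),
                 max_iterations = 25)
  ll <- fit$history$loglik
  expect_true(all(diff(ll) >= -1e-10))
})
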