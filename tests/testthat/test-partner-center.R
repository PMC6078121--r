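setup_tree <- function(cohort) {
  root <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                    "run")
  layout <- dra_simulate(cohort, root)
  list(root = root, layout = layout)
}

test_that("a partner answers parameter broadcasts with local statistics", {
  tr <- setup_tree(small_logistic_cohort())
  spec <- design_spec("logistic", c("x1", "x2", "x3"))
  node <- partner_node(1, tr$layout, spec)

  # mirror of the closed-form local statistics on a known dataset
  known <- data.frame(x = 1, y = rep(c(1, 0), c(30, 20)))
  kn <- partner_node(2, tr$layout, design_spec("logistic", "x"),
                     dataset = known)
  pl <- execute_iteration(kn, beta_state(c(0, 0), 1L, "logistic"))
  expect_equal(pl$gradient, c(5, 5))
  expect_equal(pl$information[1, 1], 12.5)
  expect_identical(pl$partner_id, 2L)

  # p mismatch is a protocol error surfaced as such
  expect_error(execute_iteration(node, beta_state(c(0, 0), 1L, "logistic")),
               class = "dra_protocol_error")

  # full serve cycle over the folder tree
  bsf <- file.path(tr$root, "bs.txt")
  write_payload(beta_state(rep(0, 4), 1L, "logistic"), bsf)
  deposit(bsf, tr$layout$partners[[1]]$inputfiles, "files_done")
  r <- partner_serve_once(node, interval = 0.01, timeout = 1)
  expect_true(r$served)
  expect_false(r$terminal)
  out <- consume(tr$layout$partners[[1]]$msoc, "files_done",
                 file.path(tr$root, "ws"))
  back <- read_payload(out[[1]])
  expect_identical(back$kind, "score_info")
  expect_identical(back$iteration, 1L)

  # stale iteration: error payload, node keeps running
  write_payload(beta_state(rep(0, 4), 1L, "logistic"), bsf)
  deposit(bsf, tr$layout$partners[[1]]$inputfiles, "files_done")
  r2 <- partner_serve_once(node, interval = 0.01, timeout = 1)
  expect_true(r2$served)
  expect_false(node$terminated)
  err <- read_payload(consume(tr$layout$partners[[1]]$msoc, "files_done",
                              file.path(tr$root, "ws"))[[1]])
  expect_identical(err$kind, "error")
  expect_match(err$message, "stale")

  # malformed parameter file: structured error payload
  writeLines("not a payload", bsf)
  deposit(bsf, tr$layout$partners[[1]]$inputfiles, "files_done")
  r3 <- partner_serve_once(node, interval = 0.01, timeout = 1)
  expect_true(r3$served)
  err2 <- read_payload(consume(tr$layout$partners[[1]]$msoc, "files_done",
                               file.path(tr$root, "ws"))[[1]])
  expect_match(err2$message, "malformed")
})

test_that("job_done terminates the partner after diagnostics", {
  tr <- setup_tree(small_logistic_cohort())
  spec <- design_spec("logistic", c("x1", "x2", "x3"))
  node <- partner_node(1, tr$layout, spec)
  bsf <- file.path(tr$root, "bs.txt")
  write_payload(beta_state(rep(0, 4), 1L, "logistic", job_done = TRUE), bsf)
  deposit(bsf, tr$layout$partners[[1]]$inputfiles, "job_done")
  summary <- run_partner_loop(node, interval = 0.01, timeout = 0.2)
  expect_identical(summary$served, 1L)
  expect_true(summary$terminated)
  out <- read_payload(consume(tr$layout$partners[[1]]$msoc, "files_done",
                              file.path(tr$root, "ws"))[[1]])
  expect_identical(out$kind, "diagnostics")
  # terminated node refuses further work
  expect_false(partner_serve_once(node, timeout = 0.05)$served)
})

test_that("the center collects from every inbox and names laggards", {
  tr <- setup_tree(small_logistic_cohort())
  spec <- design_spec("logistic", c("x1", "x2", "x3"))
  center <- center_node(tr$layout, spec, poll_interval = 0.01, timeout = 0.2)
  partners <- lapply(1:3, function(k) partner_node(k, tr$layout, spec))

  distribute_parameters(center, beta_state(rep(0, 4), 1L, "logistic"))
  for (k in 1:2) partner_serve_once(partners[[k]], timeout = 1)  # 3 silent
  expect_error(collect_intermediates(center, 1L), "3",
               class = "dra_transfer_error")
  partner_serve_once(partners[[3]], timeout = 1)
  payloads <- collect_intermediates(center, 1L)
  expect_length(payloads, 3L)
  expect_identical(vapply(payloads, `[[`, 0L, "partner_id"), 1:3)
  # every msoc and inbox trigger consumed
  expect_length(stale_triggers(file.path(tr$root, "center")), 0L)

  # empty partner list rejected at construction
  expect_error(folder_layout(tr$root, 0), class = "dra_config_error")
})

test_that("an error payload from a partner fails the run with its message", {
  tr <- setup_tree(small_logistic_cohort())
  spec <- design_spec("logistic", c("x1", "x2", "x3"))
  # partner 2 configured against the wrong schema
  bad_spec <- design_spec("logistic", c("x1", "x2", "nope"))
  partners <- list(partner_node(1, tr$layout, spec),
                   partner_node(2, tr$layout, bad_spec),
                   partner_node(3, tr$layout, spec))
  center <- center_node(tr$layout, spec, poll_interval = 0.01, timeout = 1)
  expect_error(
    run_center(center, pump = function() for (nd in partners)
      if (!nd$terminated) partner_serve_once(nd, timeout = 1)),
    "partner 2", class = "dra_protocol_error")
})

test_that("patient-level rows never leave dplocal during a full run", {
  tr <- setup_tree(small_logistic_cohort())
  before <- list.files(tr$root, recursive = TRUE)
  res <- fast_run(tr$root)
  expect_true(res$fit$converged)
  outside <- setdiff(list.files(tr$root, recursive = TRUE, full.names = TRUE),
                     file.path(tr$root, before))
  outside <- outside[!grepl("dplocal", outside)]
  # everything created outside dplocal is either a payload passing the
  # aggregate-only audit or a report/log artifact of the center
  payloadish <- outside[grepl("\\.txt$", outside) &
                          !grepl("run_report|run_log", outside)]
  aud <- audit_payload(payloadish)
  expect_true(all(aud$pass))
  n_rows <- nrow(generate_partner_dataset(small_logistic_cohort(), 1))
  for (f in outside)
    expect_lt(length(readLines(f, warn = FALSE)), n_rows)
})

test_that("identical trees and configs give bitwise-identical runs", {
  tr1 <- setup_tree(small_logistic_cohort())
  tr2 <- setup_tree(small_logistic_cohort())
  r1 <- fast_run(tr1$root)
  r2 <- fast_run(tr2$root)
  expect_identical(r1$fit$beta_hat, r2$fit$beta_hat)
  expect_identical(r1$fit$se, r2$fit$se)
  expect_identical(r1$fit$history$loglik, r2$fit$history$loglik)
  expect_identical(r1$diagnostics$hl_statistic, r2$diagnostics$hl_statistic)
})

test_that("the file protocol reproduces the in-memory distributed fit exactly", {
  cohort <- small_cox_cohort()
  tr <- setup_tree(cohort)
  res <- fast_run(tr$root)
  parts <- lapply(1:3, function(k) generate_partner_dataset(cohort, k))
  mem <- dra_fit(parts, design_spec("cox", c("x1", "x2")))
  expect_identical(res$fit$beta_hat, mem$beta_hat)
  expect_identical(res$fit$loglik_final, mem$loglik_final)
  expect_identical(res$fit$n_iterations, mem$n_iterations)
})

test_that("simulate refuses to clobber a tree unless forced", {
  cohort <- small_logistic_cohort()
  tr <- setup_tree(cohort)
  expect_error(dra_simulate(cohort, tr$root), class = "dra_config_error")
  layout <- dra_simulate(cohort, tr$root, force = TRUE)
  ds <- read_dataset(file.path(layout$partners[[1]]$dplocal,
                               "analytic_dataset.csv"))
  expect_equal(ds, generate_partner_dataset(cohort, 1))
})
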