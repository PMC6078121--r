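---
title: "Distributed regression without sharing patient-level data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed regression without sharing patient-level data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-site epidemiological studies routinely need regression models fit
over patients held at several data-holding organizations ("data
partners"), each of which is unwilling or legally unable to release
patient-level records. In a distributed data network the partners keep
their data behind their own firewalls and answer queries with aggregate
output only. **dra** implements distributed regression analysis (DRA) in
this setting: an analysis center broadcasts parameter "guesses", each
partner evaluates aggregate statistics of its own patients at those
parameters, and the center combines them and iterates. Because every
statistic involved is additive across sites, the result is numerically
equivalent to fitting the pooled data — without any patient row crossing
a site boundary.

The package simulates the whole network in software: a synthetic cohort
generator stands in for the upstream cohort-extraction step, partner and
center nodes exchange files through a folder-based protocol driven by
trigger files, and a verification pass audits everything that was
transferred.

## Statistical model

Let site $k$ hold $n_k$ patients with model matrix $X_k$ and outcomes
$y_k$, and let $\beta \in \mathbb{R}^p$ be the shared parameter vector.

**Linear.** Each partner sends the cross-product blocks
$X_k^\top X_k$, $X_k^\top y_k$, $y_k^\top y_k$ and $n_k$. Summation
over sites gives the pooled normal equations, solved in closed form;
the residual variance follows from
$\mathrm{RSS} = y^\top y - 2\beta^\top X^\top y + \beta^\top X^\top X \beta$
with $\hat\sigma^2 = \mathrm{RSS}/(n-p)$. One round trip suffices; no
iteration is needed because the statistics do not depend on $\beta$.

**Logistic.** With $\pi_i = \mathrm{expit}(x_i^\top\beta)$, partner $k$
returns the score $U_k(\beta) = X_k^\top (y_k - \pi_k)$, the information
$I_k(\beta) = X_k^\top W_k X_k$ with $W_k = \mathrm{diag}(\pi_i(1-\pi_i))$,
and the Bernoulli log-likelihood. The center's Newton–Raphson update
$\beta' = \beta + \left(\sum_k I_k\right)^{-1} \sum_k U_k$ is, term by
term, the pooled update: at every iteration the distributed and pooled
paths produce the same $\beta$ sequence.

**Cox.** Each partner is treated as its own stratum: risk sets are
formed within a site and never across sites. Partners return the score,
observed information, and partial log-likelihood of their own stratum
under the Breslow tie convention, whose contributions are additive. The
distributed fit is therefore exactly a pooled Cox model *stratified by
site* with Breslow ties. Cross-site risk sets would require exchanging
per-event-time aggregates — a different, chattier protocol — and
stratification is also the statistically safer default when baseline
hazards differ across sites (the site-effect scenario the generator can
produce). The partial likelihood has no intercept; linear and logistic
designs always include one.

**Inference.** The covariance is the inverse aggregated information
(or $\hat\sigma^2 (X^\top X)^{-1}$ for linear), with Wald $z$ statistics
and 95% intervals using the fixed normal multiplier 1.959964 for every
family.

## The iteration and its controls

* **Initialization:** $\beta_0 = 0$ — reproducible and conventional.
* **Convergence:** $\max_i |\beta'_i - \beta_i| \le$ `tolerance`
  (default `1e-6`); the run otherwise stops at `max_iterations`
  (default 25). Both are run-configuration overridable.
* **Step-halving:** the objective at a Newton candidate is only known
  after the next collection round, so halving is driven by the center:
  if the aggregated log-likelihood decreased, the step is halved (up to
  10 times, each costing one extra broadcast/collect round trip) before
  the run is declared failed. Accepted iterations therefore have
  non-decreasing log-likelihood.
* **Degenerate inputs:** rank-deficient $X^\top X$ or singular
  aggregated information (collinearity, complete separation) is a hard
  error with a diagnosis — never a silent pseudo-inverse. `chol()` alone
  does not reliably reject exactly singular matrices, so every solve
  goes through a Cholesky with an explicit pivot-ratio guard
  (smallest pivot $\ge 10^{-7}\times$ largest). Missing values in model
  columns are an error: complete-case filtering belongs to upstream
  dataset curation, not the engine. A non-finite update yields a
  `failed` status rather than an exception so the center can shut the
  protocol down cleanly.
* **Determinism:** payloads are summed in ascending partner id, so a
  run is bit-reproducible regardless of arrival order; payload files
  carry 17 significant digits, which round-trips IEEE doubles exactly,
  so a file-based run is bit-identical to the in-memory driver
  (`dra_fit()`).

## The transfer protocol

Every site uses the four-folder convention — `sasprogram`,
`inputfiles`, `dplocal` (patient data, never read by the transport
layer), `msoc` (outbound aggregates) — and the center has one inbox per
partner, `msoc1` … `msocK`. Two zero-length markers drive the state
machine: `files_done.ok` (payload complete, ready for pickup) and
`job_done.ok` (analysis finished: compute diagnostics and terminate).
Completeness is signalled *only* by the trigger; payloads are written
under a temporary name and renamed within the same volume, so a poller
keyed on the trigger can never observe a half-written file. Consuming a
payload moves it (preventing double processing) and deletes the
trigger, so the next trigger's appearance starts a fresh cycle.

Three automation levels gate transfers: `manual` requires an approval
callback before every deposit and every consume; `semi_automated` gates
only files leaving a partner's `msoc` folder (what a site reviews
before upload); `fully_automated` gates nothing. Gating affects timing
only — the numbers are identical across levels, and a denial aborts
with no partial payload visible. Every deposit is archived and recorded
in an append-only audit log; `dra_verify()` replays the log, re-audits
every archived file, and checks that no stale trigger survived.

The privacy contract is auditable because the payload format is
transparent: `key,value` text whose numeric content size is a
closed-form function of $p$ (plus the diagnostics bin count) — never of
$n$. `audit_payload()` re-parses each transferred file and rejects
anything whose size deviates, including planted patient-level tables.

Defaults: poll interval 0.5 s, per-collection timeout 300 s (the
orchestrated demonstrations poll faster since all nodes share one
process). A payload answering an earlier iteration than the partner
already served is rejected as stale via a structured error payload; the
center requires a response from every partner before updating and names
laggards on timeout.

## Diagnostics from binned aggregates

After the terminal broadcast each partner evaluates the final model
locally and returns per-bin aggregates over fixed global
predicted-probability bins (default 20 equal-width bins on $[0,1]$):
patient count, sum of outcomes, sum of predictions, plus its final
log-likelihood. These are the minimal additive sufficient statistics
for: a Hosmer–Lemeshow-type calibration statistic
$\sum_g (O_g - E_g)^2 / (E_g(1 - E_g/n_g))$ over nonempty pooled bins
(df = nonempty bins − 2), and a binned AUC — the probability a random
case's bin exceeds a random control's, ties counting one half. The
binned statistic equals the identical binned computation on pooled data
(up to float summation order), and the binned AUC converges to the
exact rank-based AUC as bins refine; at 20 bins it is within 0.02 on
the standard cohort. Fixed global edges (not pooled risk deciles) avoid
a second protocol round; exact AUC would require patient-level scores,
which the privacy contract excludes. Cox diagnostics are the final
stratified partial log-likelihood and event counts; linear diagnostics
return the pooled residual sum of squares.

## The synthetic cohort generator

`cohort_spec()` describes the study: partner count and sizes, covariate
distributions (standard normal, Bernoulli($q$), uniform($a,b$)), the
family, and the true parameters. Outcomes follow the family's canonical
model on the linear predictor; Cox event times are exponential with
rate $e^{x^\top\beta}$ (baseline rate 1, closed-form truth) under
independent exponential censoring. An optional site effect shifts each
partner's intercept (or log-baseline-hazard), emulating between-site
heterogeneity. Each partner draws from a substream seeded
deterministically from `(seed, partner_id)`, so datasets are
individually reproducible and mutually independent, and generation
restores the caller's RNG state.

The standard study conditions (`standard_cohort_spec()`) are three
partners of 2000 patients; covariates N(0,1), Bernoulli(0.4),
U(−1,1); logistic truth $(-0.5, 0.4, -0.3, 0.6)$ (≈37% prevalence),
linear truth $(1, 0.5, -0.5, 0.25)$ with unit noise, Cox truth
$(0.5, -0.3, 0.25)$ with censoring rate 0.5 (≈40% censored) and site
effect sd 0.3 — the scenario that motivates stratification. Under these
conditions the logistic fit converges in about 6 iterations at the
default tolerance, Wald 95% intervals attain nominal coverage over 200
replicates, and Cox log-hazard-ratio bias is well below 0.05 at a
combined n of 6000.

What the generator does *not* emulate: confounding structures,
propensity-score steps, common-data-model quirks, misclassification,
missingness (datasets are complete by construction — the engine treats
missingness as an error), informative censoring, or non-exponential
baseline hazards. Passing tests therefore demonstrate protocol and
numerical correctness, not robustness to real-data pathologies.

## Design choices where the design was open

* **Single-process event loop.** `dra_run()` interleaves the center and
  partner nodes in one process: after each broadcast every partner
  serves its pending message, then the center collects. Since every
  hand-off goes through the same files and triggers, results are
  identical to genuinely concurrent nodes (`run_partner_loop()` can
  serve a partner standalone), while runs stay deterministic and fast.
* **All-partner completeness.** The center waits for every partner each
  iteration and fails naming laggards, rather than proceeding with a
  subset — site-level complete case, matching the equivalence claim.
* **Stale-iteration rejection.** Partners refuse parameter states with
  an iteration index at or below the last one they answered; the
  aggregator refuses mixed iteration echoes, identifying the offender.
* **Linear one-shot.** The linear family completes in one round trip
  inside the same iterative machinery (one broadcast, one collection,
  then the terminal broadcast), so all families share one workflow.
* **Problem sizes.** The test suite and the acceptance script use the
  standard three-partner × 2000-patient cohorts for end-to-end runs and
  200 simulation replicates for coverage/bias — sizes at which the
  Monte Carlo error of the checked quantities is small relative to
  their acceptance margins, while a full suite completes in about a
  minute.

## Known limitations

* Cox fits are site-stratified; a shared-baseline-hazard Cox model
  (cross-site risk sets) is a different protocol and is not provided.
* No robust/sandwich variances, Firth correction, regularization,
  Efron ties, or time-varying covariates.
* No interruption recovery: a run that dies mid-protocol is re-run, not
  resumed.
* One analysis per folder tree at a time; no multi-request queueing.
* The transport emulates folder-and-trigger semantics on a local
  filesystem; real network transport, authentication, and encryption
  are out of scope.

## Worked example

```{r, eval = FALSE}
library(dra)

cohort <- standard_cohort_spec("logistic")
root <- file.path(tempdir(), "demo")
dra_simulate(cohort, root)

res <- dra_run(root)
res$fit                      # estimates, se, z, 95% CI
res$diagnostics$hl_statistic # pooled binned calibration
res$diagnostics$auc_binned   # pooled binned discrimination
dra_verify(root)             # privacy + protocol audit
```
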