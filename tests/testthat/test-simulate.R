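test_that("covariates have the requested marginal and joint structure", {
  sp <- scenario_spec(1)
  set.seed(42)
  n <- 100000L
  w <- generate_covariates(sp, n, latent = TRUE)
  z <- attr(w, "latent")
  expect_identical(dim(w), c(n, 10L))
  ## dichotomized columns are 0/1 with threshold at the latent mean
  expect_true(all(w[, sp$dichotomize] %in% c(0, 1)))
  expect_true(all(abs(colMeans(w[, sp$dichotomize]) - 0.5) < 3 / sqrt(n) * 2))
  ## non-dichotomized columns are marginally standard normal
  cont <- setdiff(1:10, sp$dichotomize)
  expect_true(all(abs(colMeans(w[, cont])) < 3 / sqrt(n)))
  expect_true(all(abs(apply(w[, cont], 2, stats::sd) - 1) < 0.02))
  ## requested latent correlations are realized (before dichotomization)
  cp <- sp$correlation_pairs
  for (k in seq_len(nrow(cp))) {
    expect_lt(abs(stats::cor(z[, cp$i[k]], z[, cp$j[k]]) - cp$rho[k]), 0.01)
  }
  ## unlisted pairs are uncorrelated
  expect_lt(abs(stats::cor(z[, 1], z[, 2])), 0.02)
  expect_lt(abs(stats::cor(z[, 7], z[, 10])), 0.02)
})

test_that("a correlation-free spec yields independent columns", {
  sp <- toy_spec(p = 3)
  set.seed(7)
  w <- generate_covariates(sp, 1e5)
  cors <- stats::cor(w)
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.02))
})

test_that("true_propensity evaluates the configured inverse-logit", {
  ## all coefficients zero, intercept zero: exactly 0.5 everywhere
  sp0 <- toy_spec(p = 2)
  expect_equal(true_propensity(sp0, matrix(rnorm(20), 10, 2)),
               rep(0.5, 10))
  ## hand evaluation: coefs (1, -1), x = (1, 1), intercept 0.3
  sp <- toy_spec(p = 2, exposure_main_coefs = c(1, -1),
                 exposure_intercept = 0.3)
  expect_equal(true_propensity(sp, matrix(c(1, 1), 1)),
               stats::plogis(0.3))
  ## interactions and quadratics enter as configured
  sp2 <- toy_spec(p = 2, exposure_main_coefs = c(0, 0))
  sp2$exposure_interaction_terms <- data.frame(i = 1, j = 2, coef = 2)
  sp2$exposure_quadratic_terms <- data.frame(i = 2, coef = -1)
  expect_equal(true_propensity(sp2, matrix(c(3, 2), 1)),
               stats::plogis(2 * 3 * 2 - 1 * 4))
  expect_error(true_propensity(sp, matrix(0, 1, 3)), "2 columns")
})

test_that("simulate_dataset is deterministic and respects its contract", {
  sp <- scenario_spec(2)
  d1 <- simulate_dataset(sp, n = 500, seed = 11)
  d2 <- simulate_dataset(sp, n = 500, seed = 11)
  expect_identical(d1, d2)
  expect_identical(dim(d1$covariates), c(500L, 10L))
  expect_true(all(d1$exposure %in% 0:1))
  expect_true(all(d1$true_propensity > 0 & d1$true_propensity < 1))
  expect_identical(length(d1$outcome), 500L)
  d3 <- simulate_dataset(sp, n = 500, seed = 12)
  expect_false(identical(d1$outcome, d3$outcome))
})

test_that("noiseless null outcome reduces to intercept plus effect", {
  sp <- toy_spec(p = 2, exposure_main_coefs = c(1, -1))
  d <- simulate_dataset(sp, n = 100, seed = 3)
  expect_equal(d$outcome,
               sp$outcome_intercept + sp$treatment_effect * d$exposure)
})

test_that("degenerate exposure draws are retried and eventually error", {
  ## intercept -40: exposure probability ~ 0, every draw degenerate
  sp <- toy_spec(p = 2, exposure_intercept = -40)
  expect_error(
    suppressMessages(simulate_dataset(sp, n = 20, seed = 1,
                                      max_retries = 3)),
    "degenerate after 3 retries")
  ## retries are announced
  expect_message(
    try(simulate_dataset(sp, n = 20, seed = 1, max_retries = 1),
        silent = TRUE),
    "retrying with seed")
})

test_that("simulate_study seeds replicates as base_seed + k", {
  sp <- scenario_spec(1)
  st <- simulate_study(sp, n = 100, n_reps = 3, base_seed = 50)
  expect_length(st, 3)
  expect_identical(vapply(st, `[[`, integer(1), "seed"), 51:53)
  ## overlapping base seeds reproduce identical replicates
  st2 <- simulate_study(sp, n = 100, n_reps = 2, base_seed = 51)
  expect_identical(st[[2]], st2[[1]])
  expect_error(simulate_study(sp, n_reps = 0), "at least 1")
})

test_that("exposure prevalence is calibrated near one half", {
  sp <- scenario_spec(1)
  prev <- vapply(1:200, function(k) {
    mean(simulate_dataset(sp, n = 500, seed = 3000 + k)$exposure)
  }, numeric(1))
  expect_lt(abs(mean(prev) - 0.5), 0.03)
})

test_that("correct-specification OLS recovers the -0.4 effect; crude contrast does not", {
  for (s in c(1, 3)) {
    sp <- scenario_spec(s)
    d <- simulate_dataset(sp, n = 2e4, seed = 77 + s)
    fit <- stats::lm(d$outcome ~ d$exposure + d$covariates)
    est <- coef(fit)[2]
    se <- sqrt(diag(stats::vcov(fit)))[2]
    if (isTRUE(sp$outcome_on_latent)) {
      ## analysis covariates are coarsened versions of the outcome drivers,
      ## so OLS on them retains a little residual confounding; the check is
      ## against gross miscalibration
      expect_lt(abs(est - sp$treatment_effect), 0.05)
    } else {
      expect_lt(abs(est - sp$treatment_effect), 3 * se)
    }
    ## confounding is real: the unadjusted contrast is systematically off
    crude <- mean(d$outcome[d$exposure == 1]) -
      mean(d$outcome[d$exposure == 0])
    expect_gt(abs(crude - sp$treatment_effect), 0.1)
  }
})

test_that("dataset CSV export has the documented layout", {
  d <- simulate_dataset(scenario_spec(1), n = 50, seed = 5)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_simdata_csv(d, tmp)
  back <- utils::read.csv(tmp)
  expect_identical(names(back),
                   c("id", paste0("w", 1:10), "exposure", "outcome"))
  expect_equal(back$outcome, d$outcome)
})
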