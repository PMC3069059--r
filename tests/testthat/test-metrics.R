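test_that("absolute percent bias is the bias of the mean estimate", {
  expect_equal(absolute_percent_bias(rep(-0.4, 5), -0.4), 0)
  expect_equal(absolute_percent_bias(c(-0.2, -0.4), -0.4), 25)
  expect_equal(absolute_percent_bias(c(-0.4, -0.6), -0.4), 25)
  expect_equal(absolute_percent_bias(c(-0.2, -0.4), -0.4, signed = TRUE), 25)
  expect_equal(absolute_percent_bias(c(-0.4, -0.6), -0.4, signed = TRUE),
               -25)
  ## permutation invariant
  set.seed(101)
  v <- rnorm(50, -0.4, 0.1)
  expect_identical(absolute_percent_bias(v, -0.4),
                   absolute_percent_bias(sample(v), -0.4))
  expect_error(absolute_percent_bias(v, 0), "undefined")
  expect_error(absolute_percent_bias(numeric(), -0.4), "no estimates")
  ## the mean-absolute-error variant is bounded below by the |mean| variant
  expect_gte(mean_absolute_percent_error(v, -0.4),
             absolute_percent_bias(v, -0.4))
})

test_that("coverage and mean SE aggregate records as stated", {
  recs <- data.frame(ci_low = c(-0.5, -0.45, -0.3), ci_high = c(-0.3, -0.45,
                                                                -0.1))
  expect_equal(coverage_percent(recs, -0.4), 100 / 3 * 1)
  expect_equal(coverage_percent(recs, -0.45), 200 / 3)
  expect_equal(coverage_percent(recs, 0), 0)
  big <- data.frame(ci_low = rep(c(-1, -0.2), c(875, 125)),
                    ci_high = rep(c(0, -0.1), c(875, 125)))
  expect_equal(coverage_percent(big, -0.4), 87.5)
  expect_equal(mean_standard_error(data.frame(standard_error = c(0.1, 0.3))),
               0.2)
  expect_equal(mean_standard_error(data.frame(se = c(0.2, 0.2, 0.5))), 0.3)
})

test_that("weight diagnostics match enumeration on a known vector", {
  ws <- make_ws(1:100, rep(0, 100))
  d <- weight_diagnostics(list(ws))
  expect_equal(d$max, 100)
  expect_equal(d$prop_ge_10, 0.91)
  expect_equal(d$prop_ge_20, 0.81)
  expect_equal(d$median, unname(stats::quantile(1:100, 0.5, type = 7)))
  ## top-5% sum: weights strictly above the 95th percentile (95.05)
  expect_equal(d$mean_top5_sum, sum(96:100))
  expect_true(d$q1 <= d$median && d$median <= d$q3 && d$q3 <= d$max)
  ## all small weights: both proportions zero
  small <- weight_diagnostics(list(make_ws(runif(50, 0, 5), rep(0, 50))))
  expect_equal(small$prop_ge_10, 0)
  expect_equal(small$prop_ge_20, 0)
  ## trimmed input is rejected: diagnostics are pre-trim quantities
  expect_error(weight_diagnostics(list(make_ws(1:10, rep(0, 10),
                                               trim = 90L))),
               "untrimmed")
})

test_that("Spearman weight correlations behave as rank statistics", {
  set.seed(102)
  w1 <- replicate(5, rexp(40), simplify = FALSE)
  mono <- lapply(w1, function(v) v^3 + 1)   # strictly monotone transform
  out <- spearman_weight_correlations(list(a = w1, b = mono))
  expect_equal(unname(diag(out)), c(1, 1))
  expect_equal(out["a", "b"], 1)
  ## independent weights: mean correlation near zero
  null1 <- replicate(100, rexp(250), simplify = FALSE)
  null2 <- replicate(100, rexp(250), simplify = FALSE)
  out0 <- spearman_weight_correlations(list(a = null1, b = null2))
  expect_lt(abs(out0["a", "b"]), 0.1)
  ## mismatched replicate structure is an error
  expect_error(spearman_weight_correlations(list(a = w1, b = mono[1:3])),
               "differing numbers")
  bad <- mono
  bad[[2]] <- bad[[2]][-1]
  expect_error(spearman_weight_correlations(list(a = w1, b = bad)),
               "mismatched subjects")
})

test_that("optimal trim level minimizes the criterion with least-trim ties", {
  grid <- 50:100
  tab <- data.frame(scenario = 2, method = "logistic",
                    trim_percentile = grid,
                    abs_percent_bias = abs(grid - 95) + 7.8,
                    coverage_percent = 90)
  expect_equal(optimal_trim_level(tab, 2, "logistic", "bias"), 95)
  ## flat table: least trimming wins
  flat <- transform(tab, abs_percent_bias = 10)
  expect_equal(optimal_trim_level(flat, 2, "logistic", "bias"), 100)
  ## transcribed headline values: 17.7 untrimmed, 7.8 at the 95th, worse
  ## everywhere else
  tab2 <- transform(tab, abs_percent_bias = ifelse(
    grid == 100, 17.7, ifelse(grid == 95, 7.8, 25)))
  expect_equal(optimal_trim_level(tab2, 2, "logistic", "bias"), 95)
  ## coverage criterion: distance from nominal 95
  tab3 <- transform(tab, coverage_percent = ifelse(grid == 92, 94.8, 80))
  expect_equal(optimal_trim_level(tab3, 2, "logistic", "coverage"), 92)
  expect_error(optimal_trim_level(tab[tab$trim_percentile > 60, ], 2,
                                  "logistic"),
               "missing trim percentiles")
})

test_that("performance tables have exact coverage granularity and MC errors", {
  set.seed(103)
  n_reps <- 40
  est <- rnorm(n_reps, -0.42, 0.05)
  recs <- data.frame(scenario = 1, method = "logistic",
                     trim_percentile = rep(c(100, 90), each = n_reps),
                     estimate = rep(est, 2), se = 0.05,
                     ci_low = rep(est, 2) - 0.1,
                     ci_high = rep(est, 2) + 0.1)
  tab <- performance_table(recs, truth = -0.4)
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$coverage_percent * n_reps / 100 ==
                  round(tab$coverage_percent * n_reps / 100)))
  expect_equal(tab$abs_percent_bias[1],
               absolute_percent_bias(est, -0.4))
  expect_equal(tab$mc_sd[1], stats::sd(est))
  ## MC standard error of the bias shrinks like 1/sqrt(n) on nested subsets
  half <- performance_table(recs[recs$trim_percentile == 100, ][1:20, ],
                            truth = -0.4)
  expect_equal(half$mc_se_of_bias / tab$mc_se_of_bias[1],
               stats::sd(est[1:20]) / stats::sd(est) * sqrt(2),
               tolerance = 1e-10)
})
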