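test_that("main-effects logistic regression tracks the true propensity", {
  d <- simulate_dataset(scenario_spec(1), n = 500, seed = 21)
  f <- fit_propensity(d, "logistic")
  expect_s3_class(f, "propensity_fit")
  expect_true(all(f$propensity > 0 & f$propensity < 1))
  expect_identical(f$n_clipped, 0L)
  ## correctly specified scenario: strong rank agreement with the truth
  expect_gt(stats::cor(f$propensity, d$true_propensity,
                       method = "spearman"), 0.9)
  ## deterministic fit
  expect_identical(fit_propensity(d, "logistic")$propensity, f$propensity)
})

test_that("under a null exposure model all logistic coefficients are near zero", {
  sp <- toy_spec(p = 4)   # all exposure coefficients zero
  d <- simulate_dataset(sp, n = 800, seed = 31)
  f <- fit_propensity(d, "logistic")
  oracle <- stats::glm(d$exposure ~ d$covariates, family = stats::binomial())
  se <- sqrt(diag(stats::vcov(oracle)))
  expect_equal(unname(f$metadata$coefficients), unname(coef(oracle)),
               tolerance = 1e-6)
  expect_true(all(abs(coef(oracle)[-1]) < 3 * se[-1]))
})

test_that("logistic fits are permutation equivariant", {
  d <- simulate_dataset(scenario_spec(1), n = 200, seed = 41)
  perm <- sample(200)
  dp <- list(covariates = d$covariates[perm, ], exposure = d$exposure[perm])
  f <- fit_propensity(d, "logistic")
  fp <- fit_propensity(dp, "logistic")
  expect_equal(fp$propensity, f$propensity[perm], tolerance = 1e-8)
})

test_that("CART propensities are terminal-node treated fractions", {
  ## 12 points, one binary covariate: hand-computed node proportions
  x <- matrix(rep(c(0, 1), each = 6), ncol = 1,
              dimnames = list(NULL, "w1"))
  a <- c(1, 1, 0, 0, 0, 0,  1, 1, 1, 1, 1, 0)   # 2/6 and 5/6 treated
  f <- fit_propensity(list(covariates = x, exposure = a), "cart",
                      control = propensity_control(minsplit = 2,
                                                   minbucket = 1, cp = 0))
  expect_equal(unname(f$propensity[x[, 1] == 0]), rep(2 / 6, 6))
  expect_equal(unname(f$propensity[x[, 1] == 1]), rep(5 / 6, 6))
})

test_that("a perfectly separable covariate yields clipped pure nodes", {
  x <- matrix(seq(-1, 1, length.out = 100), ncol = 1,
              dimnames = list(NULL, "w1"))
  a <- as.integer(x[, 1] >= 0)
  f <- fit_propensity(list(covariates = x, exposure = a), "cart")
  eps <- f$clip_epsilon
  expect_equal(unname(f$propensity), ifelse(a == 1, 1 - eps, eps))
  expect_equal(f$n_clipped, 100L)
})

test_that("constant covariates give a root-only tree at the prevalence", {
  x <- matrix(1, 50, 2, dimnames = list(NULL, c("w1", "w2")))
  a <- rep(c(0, 1), 25)
  expect_warning(
    f <- fit_propensity(list(covariates = x, exposure = a), "cart"),
    "no usable split")
  expect_equal(unname(f$propensity), rep(0.5, 50))
  expect_true(f$metadata$no_split)
})

test_that("random forests are seed-deterministic and clipped at the boundary", {
  d <- simulate_dataset(scenario_spec(1), n = 150, seed = 51)
  f1 <- fit_propensity(d, "random_forest", seed = 9,
                       control = propensity_control(ntree = 50))
  f2 <- fit_propensity(d, "random_forest", seed = 9,
                       control = propensity_control(ntree = 50))
  expect_identical(f1$propensity, f2$propensity)
  expect_true(all(f1$propensity >= f1$clip_epsilon &
                  f1$propensity <= 1 - f1$clip_epsilon))
})

test_that("a one-tree unpruned forest matches a fully grown CART", {
  set.seed(61)
  x <- matrix(rnorm(60 * 3), 60, 3,
              dimnames = list(NULL, paste0("w", 1:3)))
  a <- rbinom(60, 1, stats::plogis(x[, 1]))
  dd <- list(covariates = x, exposure = a)
  rf1 <- fit_propensity(dd, "random_forest", seed = 1,
                        control = propensity_control(
                          ntree = 1, mtry = 3, replace = FALSE,
                          forest_votes = "insample"))
  ct <- fit_propensity(dd, "cart",
                       control = propensity_control(minsplit = 2,
                                                    minbucket = 1, cp = 0))
  ## both grow pure leaves on distinct continuous covariates, so the clipped
  ## propensities coincide (and reproduce the units' own classes)
  expect_identical(rf1$propensity, ct$propensity)
  eps <- rf1$clip_epsilon
  expect_equal(unname(rf1$propensity), ifelse(a == 1, 1 - eps, eps))
})

test_that("clip_propensity clips only boundary values and counts them", {
  expect_equal(clip_propensity(0.5, 0.01)$propensity, 0.5)
  expect_equal(clip_propensity(1, 0.001)$propensity, 0.999)
  expect_equal(clip_propensity(0, 0.001)$propensity, 0.001)
  v <- c(0.2, 0.5, 0.8)
  out <- clip_propensity(v, 0.001)
  expect_identical(out$propensity, v)
  expect_identical(out$n_clipped, 0L)
  expect_identical(clip_propensity(c(0, 1, 0.5), 0.01)$n_clipped, 2L)
  expect_error(clip_propensity(0.5, 0.7), "\\(0, 0.5\\)")
  expect_error(clip_propensity(0.5, 0), "\\(0, 0.5\\)")
})

test_that("single-group exposure vectors are rejected", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("w1", "w2")))
  expect_error(
    fit_propensity(list(covariates = x, exposure = rep(1, 10)), "logistic"),
    "non-empty")
})
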