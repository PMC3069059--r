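## Small scenario with p covariates, all confounders unless stated; used for
## hand-checkable toys where the 10-covariate design is overkill.
toy_spec <- function(p = 2,
                     exposure_main_coefs = rep(0, p),
                     exposure_intercept = 0,
                     outcome_coefs = rep(0, p),
                     outcome_noise_sd = 0,
                     dichotomize = integer(),
                     ...) {
  scenario_spec(1,
    n_covariates = as.integer(p),
    covariate_roles = rep("confounder", p),
    correlation_pairs = data.frame(i = integer(), j = integer(),
                                   rho = numeric()),
    dichotomize = dichotomize,
    exposure_main_coefs = exposure_main_coefs,
    exposure_intercept = exposure_intercept,
    outcome_coefs = outcome_coefs,
    outcome_noise_sd = outcome_noise_sd,
    outcome_on_latent = FALSE,
    ...)
}

## Independent brute-force weighted KS: loop over every observed value as a
## candidate sup point and accumulate weighted ECDFs by explicit sums.
brute_ks <- function(x, group, weights = rep(1, length(x))) {
  wt <- sum(weights[group == 1])
  wc <- sum(weights[group == 0])
  d <- 0
  for (v in x) {
    ft <- sum(weights[group == 1 & x <= v]) / wt
    fc <- sum(weights[group == 0 & x <= v]) / wc
    d <- max(d, abs(ft - fc))
  }
  d
}

## Independent weighted-regression oracle via explicit normal equations.
wls_oracle <- function(y, a, w) {
  X <- cbind(1, a)
  XtWX <- t(X) %*% (w * X)
  beta <- solve(XtWX, t(X) %*% (w * y))
  r <- y - X %*% beta
  s2 <- sum(w * r^2) / (length(y) - 2)
  vc_model <- s2 * solve(XtWX)
  meat <- t(X) %*% ((w * drop(r))^2 * X)
  vc_sand <- solve(XtWX) %*% meat %*% solve(XtWX)
  list(estimate = beta[2], se_model = sqrt(vc_model[2, 2]),
       se_sandwich = sqrt(vc_sand[2, 2]))
}

## Bare weight_set constructor for metric tests.
make_ws <- function(weights, exposure, trim = 100L) {
  structure(list(weights = weights, untrimmed_weights = weights,
                 exposure = as.integer(exposure),
                 trim_percentile = as.integer(trim),
                 cutpoint_value = NA_real_, source_method = "test"),
            class = "weight_set")
}
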