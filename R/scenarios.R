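#' Scenario specification for the simulation study
#'
#' A `scenario_spec` holds the complete generative model for one simulation
#' scenario: the latent covariate correlation structure, which covariates are
#' thresholded to binary, the exposure (true propensity score) model, and the
#' outcome model.  Ten covariates are generated; four act as confounders
#' (associated with exposure and outcome), three affect only the exposure and
#' three only the outcome.  The three packaged scenarios share all
#' coefficients and differ only in the non-additive/non-linear terms of the
#' true propensity model:
#'
#' * scenario 1: additivity and linearity (main effects only);
#' * scenario 2: mild non-additivity and non-linearity (two-way interaction
#'   terms and one quadratic term);
#' * scenario 3: moderate non-additivity and non-linearity (ten two-way
#'   interaction terms and three quadratic terms).
#'
#' The exposure intercept is calibrated so that the exposure probability at
#' the average of the covariates is approximately 0.5, and the true effect of
#' exposure on the continuous outcome is -0.4.
#'
#' @param scenario Integer 1, 2 or 3 selecting a packaged scenario.
#' @param ... Named fields overriding the packaged defaults; see Details.
#'
#' @details Overridable fields and their defaults:
#' \describe{
#'   \item{`n_covariates`}{Number of covariates (10).}
#'   \item{`covariate_roles`}{Character vector of length `n_covariates` with
#'     values `"confounder"`, `"exposure_only"`, `"outcome_only"`.}
#'   \item{`correlation_pairs`}{Data frame `i, j, rho` of latent-normal
#'     correlations.}
#'   \item{`dichotomize`}{Indices of covariates thresholded to binary at
#'     `dichotomize_cut` (default cut 0, i.e. the latent mean).}
#'   \item{`exposure_intercept`, `exposure_main_coefs`}{Linear part of the
#'     true propensity model (on the analysis-scale covariates).}
#'   \item{`exposure_interaction_terms`}{Data frame `i, j, coef`.}
#'   \item{`exposure_quadratic_terms`}{Data frame `i, coef`.}
#'   \item{`outcome_intercept`, `outcome_coefs`, `treatment_effect`,
#'     `outcome_noise_sd`}{Outcome model \eqn{y = a_0 + \gamma A + a'w +
#'     \epsilon}.  Coefficients for exposure-only covariates are zero.}
#'   \item{`outcome_on_latent`}{Logical; if `TRUE` (packaged default) the
#'     outcome linear predictor uses the continuous latent covariate values,
#'     i.e. dichotomization is a feature of the measured data, not of the
#'     response surface.  See the methods vignette.}
#' }
#'
#' @return An object of class `scenario_spec`.
#' @examples
#' sp <- scenario_spec(2)
#' sp
#' nrow(sp$exposure_interaction_terms)
#' @export
scenario_spec <- function(scenario = 1, ...) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:3) {
    stop("'scenario' must be 1, 2 or 3", call. = FALSE)
  }
  spec <- default_scenario_fields(scenario)
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(spec))
    if (length(unknown)) {
      stop("unknown scenario_spec field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    spec[names(dots)] <- dots
  }
  validate_scenario_spec(new_scenario_spec(spec))
}

new_scenario_spec <- function(fields) {
  structure(fields, class = "scenario_spec")
}

## Generating coefficients shared by the three scenarios.  Exposure-model
## coefficients act on covariates 1-7 (confounders 1-4, exposure-only 5-7);
## outcome coefficients act on covariates 1-4 and 8-10.
scenario_coefs <- function() {
  list(
    b = c(0.8, -0.25, 0.6, -0.4, -0.8, -0.5, 0.7, 0, 0, 0),
    a = c(0.3, -0.36, -0.73, -0.2, 0, 0, 0, 0.71, -0.19, 0.26),
    a0 = -3.85,
    gamma = -0.4
  )
}

default_scenario_fields <- function(scenario) {
  cf <- scenario_coefs()
  b <- cf$b
  inter <- switch(scenario,
    data.frame(i = integer(), j = integer(), coef = numeric()),
    data.frame(i    = c(1, 2, 4, 5),
               j    = c(3, 4, 5, 6),
               coef = c(0.5 * b[1], 0.7 * b[2], 0.5 * b[4], 0.5 * b[5])),
    data.frame(i    = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5),
               j    = c(3, 4, 5, 6, 7, 6, 3, 4, 5, 6),
               coef = c(0.5 * b[1], 0.7 * b[2], 0.5 * b[3], 0.7 * b[4],
                        0.5 * b[5], 0.5 * b[1], 0.7 * b[2], 0.5 * b[3],
                        0.5 * b[4], 0.5 * b[5]))
  )
  quad <- switch(scenario,
    data.frame(i = integer(), coef = numeric()),
    data.frame(i = 2, coef = b[2]),
    data.frame(i = c(2, 4, 7), coef = c(b[2], b[4], b[7]))
  )
  list(
    scenario_id = scenario,
    n_covariates = 10L,
    covariate_roles = c(rep("confounder", 4), rep("exposure_only", 3),
                        rep("outcome_only", 3)),
    correlation_pairs = data.frame(i = c(1, 2, 3, 4), j = c(5, 6, 8, 9),
                                   rho = c(0.2, 0.9, 0.2, 0.9)),
    dichotomize = c(1L, 3L, 5L, 6L, 8L, 9L),
    dichotomize_cut = 0,
    exposure_intercept = 0,
    exposure_main_coefs = b,
    exposure_interaction_terms = inter,
    exposure_quadratic_terms = quad,
    outcome_intercept = cf$a0,
    outcome_coefs = cf$a,
    treatment_effect = cf$gamma,
    outcome_noise_sd = 0,
    outcome_on_latent = TRUE
  )
}

validate_scenario_spec <- function(spec) {
  p <- spec$n_covariates
  stopifnot(is.numeric(p), length(p) == 1, p >= 1)
  if (length(spec$covariate_roles) != p ||
      !all(spec$covariate_roles %in%
           c("confounder", "exposure_only", "outcome_only"))) {
    stop("covariate_roles must be length ", p, " with values ",
         "'confounder', 'exposure_only', 'outcome_only'", call. = FALSE)
  }
  counts <- table(factor(spec$covariate_roles,
                         levels = c("confounder", "exposure_only",
                                    "outcome_only")))
  if (p == 10 && !all(counts == c(4, 3, 3))) {
    stop("with 10 covariates the design requires 4 confounders, ",
         "3 exposure-only and 3 outcome-only covariates", call. = FALSE)
  }
  if (length(spec$exposure_main_coefs) != p ||
      length(spec$outcome_coefs) != p) {
    stop("exposure_main_coefs and outcome_coefs must have length ", p,
         call. = FALSE)
  }
  if (any(spec$outcome_coefs[spec$covariate_roles == "exposure_only"] != 0)) {
    stop("outcome_coefs must be zero for exposure-only covariates",
         call. = FALSE)
  }
  cp <- spec$correlation_pairs
  if (nrow(cp)) {
    if (any(cp$i < 1 | cp$i > p | cp$j < 1 | cp$j > p | cp$i == cp$j)) {
      stop("correlation_pairs indices out of range", call. = FALSE)
    }
    if (any(abs(cp$rho) >= 1)) {
      stop("correlations must lie strictly in (-1, 1)", call. = FALSE)
    }
  }
  sig <- correlation_matrix(spec)
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= sqrt(.Machine$double.eps)) {
    bad <- paste(sprintf("(%d,%d,%.3g)", cp$i, cp$j, cp$rho), collapse = " ")
    stop("correlation_pairs do not define a positive definite matrix: ", bad,
         call. = FALSE)
  }
  for (tm in list(spec$exposure_interaction_terms)) {
    if (nrow(tm) && any(tm$i < 1 | tm$i > p | tm$j < 1 | tm$j > p)) {
      stop("exposure_interaction_terms index out of range", call. = FALSE)
    }
  }
  qt <- spec$exposure_quadratic_terms
  if (nrow(qt) && any(qt$i < 1 | qt$i > p)) {
    stop("exposure_quadratic_terms index out of range", call. = FALSE)
  }
  if (any(spec$dichotomize < 1 | spec$dichotomize > p)) {
    stop("dichotomize index out of range", call. = FALSE)
  }
  if (spec$outcome_noise_sd < 0) {
    stop("outcome_noise_sd must be non-negative", call. = FALSE)
  }
  spec
}

## Latent-normal correlation matrix implied by the pair list.
correlation_matrix <- function(spec) {
  p <- spec$n_covariates
  sig <- diag(p)
  cp <- spec$correlation_pairs
  if (nrow(cp)) {
    for (k in seq_len(nrow(cp))) {
      sig[cp$i[k], cp$j[k]] <- sig[cp$j[k], cp$i[k]] <- cp$rho[k]
    }
  }
  sig
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Simulation scenario %d (%d covariates)\n",
              x$scenario_id, x$n_covariates))
  cat(sprintf("  roles: %d confounder, %d exposure-only, %d outcome-only\n",
              sum(x$covariate_roles == "confounder"),
              sum(x$covariate_roles == "exposure_only"),
              sum(x$covariate_roles == "outcome_only")))
  cat(sprintf("  correlated latent pairs: %d; dichotomized: %s\n",
              nrow(x$correlation_pairs),
              if (length(x$dichotomize)) paste(x$dichotomize, collapse = ",")
              else "none"))
  cat(sprintf("  propensity model: %d interaction, %d quadratic term(s)\n",
              nrow(x$exposure_interaction_terms),
              nrow(x$exposure_quadratic_terms)))
  cat(sprintf("  treatment effect: %g; outcome noise sd: %g\n",
              x$treatment_effect, x$outcome_noise_sd))
  invisible(x)
}

#' Read or write a scenario specification as a YAML file
#'
#' Scenario specifications serialize to a flat YAML document so generating
#' coefficients can be inspected and overridden outside R.  The three
#' packaged scenarios are shipped under `system.file("scenarios",
#' package = "pstrim")`.
#'
#' @param path File path.
#' @param spec A `scenario_spec`.
#' @return `read_scenario_spec()` returns a validated `scenario_spec`;
#'   `write_scenario_spec()` returns `path` invisibly.
#' @examples
#' f <- system.file("scenarios", "scenario3.yaml", package = "pstrim")
#' sp <- read_scenario_spec(f)
#' nrow(sp$exposure_interaction_terms)
#' @export
read_scenario_spec <- function(path) {
  if (!file.exists(path)) {
    stop("scenario file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  for (f in c("correlation_pairs", "exposure_interaction_terms",
              "exposure_quadratic_terms")) {
    y[[f]] <- as.data.frame(lapply(y[[f]], unlist))
    if (!nrow(y[[f]])) {
      y[[f]] <- if (f == "exposure_quadratic_terms") {
        data.frame(i = integer(), coef = numeric())
      } else {
        data.frame(i = integer(), j = integer(), coef = numeric())
      }
    }
  }
  y$dichotomize <- as.integer(unlist(y$dichotomize))
  y$covariate_roles <- as.character(unlist(y$covariate_roles))
  y$exposure_main_coefs <- as.numeric(unlist(y$exposure_main_coefs))
  y$outcome_coefs <- as.numeric(unlist(y$outcome_coefs))
  validate_scenario_spec(new_scenario_spec(y))
}

#' @rdname read_scenario_spec
#' @export
write_scenario_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  y <- unclass(spec)
  for (f in c("correlation_pairs", "exposure_interaction_terms",
              "exposure_quadratic_terms")) {
    y[[f]] <- lapply(as.data.frame(y[[f]]), as.vector)
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Load a packaged scenario
#'
#' Convenience wrapper reading one of the shipped scenario YAML files.
#'
#' @param scenario Integer 1, 2 or 3.
#' @return A `scenario_spec`.
#' @export
packaged_scenario <- function(scenario) {
  f <- system.file("scenarios", sprintf("scenario%d.yaml", scenario),
                   package = "pstrim")
  if (!nzchar(f)) {
    stop("no packaged scenario ", scenario, call. = FALSE)
  }
  read_scenario_spec(f)
}
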