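#' Generate the covariate matrix for one dataset
#'
#' Draws `n` rows of correlated standard-normal covariates and thresholds the
#' columns listed in `spec$dichotomize` to binary.  Correlations are imposed
#' on the latent normals (a Gaussian copula once thresholding is applied), so
#' the requested `correlation_pairs` hold for the latent values, before any
#' dichotomization.
#'
#' @param spec A [scenario_spec()].
#' @param n Number of rows (at least 2).
#' @param latent Logical; return the latent (pre-threshold) matrix as the
#'   `"latent"` attribute.
#' @return An `n` by `spec$n_covariates` matrix with columns `w1..wp`.
#'   Columns in `spec$dichotomize` contain 0/1.
#' @examples
#' x <- generate_covariates(scenario_spec(1), 100)
#' colMeans(x)
#' @export
generate_covariates <- function(spec, n, latent = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  sig <- correlation_matrix(spec)
  z <- MASS::mvrnorm(n, mu = rep(0, spec$n_covariates), Sigma = sig)
  colnames(z) <- paste0("w", seq_len(spec$n_covariates))
  w <- z
  if (length(spec$dichotomize)) {
    w[, spec$dichotomize] <- (z[, spec$dichotomize] > spec$dichotomize_cut) + 0
  }
  if (latent) attr(w, "latent") <- z
  w
}

#' True propensity score under a scenario
#'
#' Evaluates the inverse logit of the scenario's true exposure model —
#' intercept, main effects, and any configured interaction and quadratic
#' terms — at the supplied covariate values.
#'
#' @param spec A [scenario_spec()].
#' @param covariates Matrix with `spec$n_covariates` columns (analysis-scale,
#'   i.e. after any dichotomization).
#' @return Vector of probabilities strictly inside (0, 1).
#' @examples
#' sp <- scenario_spec(1)
#' w <- generate_covariates(sp, 5)
#' true_propensity(sp, w)
#' @export
true_propensity <- function(spec, covariates) {
  stopifnot(inherits(spec, "scenario_spec"))
  covariates <- as.matrix(covariates)
  if (ncol(covariates) != spec$n_covariates) {
    stop("covariates must have ", spec$n_covariates, " columns",
         call. = FALSE)
  }
  lp <- spec$exposure_intercept +
    drop(covariates %*% spec$exposure_main_coefs)
  it <- spec$exposure_interaction_terms
  if (nrow(it)) {
    for (k in seq_len(nrow(it))) {
      lp <- lp + it$coef[k] * covariates[, it$i[k]] * covariates[, it$j[k]]
    }
  }
  qt <- spec$exposure_quadratic_terms
  if (nrow(qt)) {
    for (k in seq_len(nrow(qt))) {
      lp <- lp + qt$coef[k] * covariates[, qt$i[k]]^2
    }
  }
  stats::plogis(lp)
}

#' Simulate one replicate dataset
#'
#' Generates covariates, draws the binary exposure from the scenario's true
#' propensity model, and builds the continuous outcome
#' \eqn{y = a_0 + \gamma A + a'w + \epsilon}.  With `outcome_on_latent =
#' TRUE` (the packaged default) the outcome linear predictor uses the
#' continuous latent covariate values rather than the thresholded columns the
#' analyst observes.  The draw is fully determined by `(spec, n, seed)`.
#'
#' If by chance every subject lands in the same exposure group the draw is
#' retried with a deterministically derived seed (up to `max_retries` times,
#' each retry signalled by a message) before failing.
#'
#' @param spec A [scenario_spec()].
#' @param n Sample size (default 500).
#' @param seed Integer seed for this replicate.
#' @param max_retries Retries allowed for a degenerate exposure draw.
#' @return An object of class `ps_simdata`: list with elements `covariates`
#'   (n x p matrix), `exposure` (0/1), `outcome`, `true_propensity`, `seed`,
#'   `scenario_id`.
#' @examples
#' d <- simulate_dataset(scenario_spec(1), n = 200, seed = 7)
#' table(d$exposure)
#' @export
simulate_dataset <- function(spec, n = 500, seed, max_retries = 10) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  seed <- as.integer(seed)
  use_seed <- seed
  for (attempt in 0:max_retries) {
    set.seed(use_seed)
    w <- generate_covariates(spec, n, latent = TRUE)
    z <- attr(w, "latent")
    attr(w, "latent") <- NULL
    ps <- true_propensity(spec, w)
    a <- stats::rbinom(n, 1L, ps)
    if (length(unique(a)) == 2L) {
      wy <- if (isTRUE(spec$outcome_on_latent)) z else w
      y <- spec$outcome_intercept + spec$treatment_effect * a +
        drop(wy %*% spec$outcome_coefs)
      if (spec$outcome_noise_sd > 0) {
        y <- y + stats::rnorm(n, 0, spec$outcome_noise_sd)
      }
      return(structure(
        list(covariates = w, exposure = a, outcome = y,
             true_propensity = ps, seed = seed, scenario_id = spec$scenario_id,
             retries = attempt),
        class = "ps_simdata"))
    }
    use_seed <- seed + 7919L * (attempt + 1L)
    message(sprintf(
      "degenerate exposure draw (seed %d); retrying with seed %d",
      seed, use_seed))
  }
  stop("exposure degenerate after ", max_retries, " retries (seed ", seed,
       ")", call. = FALSE)
}

#' Simulate a Monte-Carlo study
#'
#' Generates `n_reps` mutually independent replicate datasets; replicate `k`
#' uses seed `base_seed + k`, so any replicate can be regenerated in
#' isolation and overlapping seed ranges reproduce identical replicates.
#'
#' @param spec A [scenario_spec()].
#' @param n Sample size per replicate.
#' @param n_reps Number of replicates (at least 1).
#' @param base_seed Integer; replicate `k` is seeded with `base_seed + k`.
#' @return List of `ps_simdata` objects.
#' @export
simulate_study <- function(spec, n = 500, n_reps = 1000, base_seed = 0) {
  if (n_reps < 1) stop("n_reps must be at least 1", call. = FALSE)
  lapply(seq_len(n_reps), function(k) {
    simulate_dataset(spec, n = n, seed = as.integer(base_seed) + k)
  })
}

#' @export
print.ps_simdata <- function(x, ...) {
  cat(sprintf("Simulated dataset: n = %d, scenario %d, seed %d\n",
              length(x$exposure), x$scenario_id, x$seed))
  cat(sprintf("  exposed %d / unexposed %d; outcome mean %.3f\n",
              sum(x$exposure), sum(1 - x$exposure), mean(x$outcome)))
  invisible(x)
}

#' @export
as.data.frame.ps_simdata <- function(x, ...) {
  out <- data.frame(id = seq_along(x$exposure), x$covariates,
                    exposure = x$exposure, outcome = x$outcome)
  out
}

#' Export a simulated dataset as CSV
#'
#' Writes the analysis view of a dataset (`id, w1..wp, exposure, outcome`).
#'
#' @param x A `ps_simdata`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_simdata_csv <- function(x, path) {
  stopifnot(inherits(x, "ps_simdata"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
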