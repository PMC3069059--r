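#' Weighted estimate of the treatment effect
#'
#' Fits the weighted least-squares regression of the outcome on an intercept
#' and the exposure indicator only (no covariates), with the propensity
#' score weights as regression weights.  For a binary regressor the WLS
#' slope is identically the weighted mean outcome among the exposed minus
#' the weighted mean outcome among the unexposed; the closed form is used.
#'
#' Two variance estimators are available:
#' \describe{
#'   \item{`"model"`}{the precision-weight (model-based) WLS standard error,
#'     i.e. what `lm(y ~ a, weights = w)` reports:
#'     \eqn{\hat\sigma^2 (1/W_1 + 1/W_0)} with
#'     \eqn{\hat\sigma^2 = \sum_i w_i r_i^2 / (n - 2)};}
#'   \item{`"sandwich"`}{the HC0 robust (design-based) standard error
#'     \eqn{\sqrt{\sum_{A=1} (w_i r_i)^2 / W_1^2 +
#'     \sum_{A=0} (w_i r_i)^2 / W_0^2}}, appropriate when the weights are
#'     not precision weights.}
#' }
#' The confidence interval is `estimate ± t(n-2) * SE`.  Both estimators are
#' invariant to rescaling all weights by a positive constant.
#'
#' @param dataset A `ps_simdata`, or list with `outcome` and `exposure`.
#' @param ws A `weight_set` (or numeric weight vector).
#' @param ci_level Confidence level in (0, 1), default 0.95.
#' @param variance `"model"` (default) or `"sandwich"`.
#' @return Object of class `att_estimate`: `estimate`, `standard_error`,
#'   `ci_low`, `ci_high`, `ci_level`, `trim_percentile`, `method`,
#'   `variance`, `replicate_seed`, `n`.
#' @examples
#' d <- simulate_dataset(scenario_spec(1), n = 300, seed = 2)
#' ws <- odds_weights(fit_propensity(d, "logistic"), d$exposure)
#' estimate_effect(d, ws)
#' @export
estimate_effect <- function(dataset, ws, ci_level = 0.95,
                            variance = c("model", "sandwich")) {
  variance <- match.arg(variance)
  if (ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must lie in (0, 1)", call. = FALSE)
  }
  y <- dataset$outcome
  a <- as.integer(dataset$exposure)
  if (inherits(ws, "weight_set")) {
    w <- ws$weights
    trim <- ws$trim_percentile
    method <- ws$source_method
  } else {
    w <- as.numeric(ws)
    trim <- NA_integer_
    method <- "supplied"
  }
  n <- length(y)
  if (length(a) != n || length(w) != n) {
    stop("outcome, exposure and weights lengths differ", call. = FALSE)
  }
  w1 <- sum(w[a == 1L])
  w0 <- sum(w[a == 0L])
  if (w1 <= 0 || w0 <= 0) {
    stop("zero total weight in the ", if (w1 <= 0) "exposed" else "unexposed",
         " group", call. = FALSE)
  }
  m1 <- sum((w * y)[a == 1L]) / w1
  m0 <- sum((w * y)[a == 0L]) / w0
  est <- m1 - m0
  r <- y - ifelse(a == 1L, m1, m0)
  se <- if (variance == "model") {
    sqrt(sum(w * r^2) / (n - 2) * (1 / w1 + 1 / w0))
  } else {
    sqrt(sum(((w * r)[a == 1L])^2) / w1^2 +
         sum(((w * r)[a == 0L])^2) / w0^2)
  }
  crit <- stats::qt(1 - (1 - ci_level) / 2, df = n - 2)
  structure(
    list(estimate = est, standard_error = se,
         ci_low = est - crit * se, ci_high = est + crit * se,
         ci_level = ci_level, trim_percentile = trim, method = method,
         variance = variance,
         replicate_seed = if (!is.null(dataset$seed)) dataset$seed else
           NA_integer_,
         n = n),
    class = "att_estimate")
}

#' Does a confidence interval cover the truth?
#'
#' Closed-interval convention: the truth lying exactly on an endpoint counts
#' as covered.
#'
#' @param est An `att_estimate`.
#' @param truth The true effect.
#' @return Logical.
#' @export
covers_truth <- function(est, truth) {
  stopifnot(inherits(est, "att_estimate"))
  est$ci_low <= truth && truth <= est$ci_high
}

#' @export
print.att_estimate <- function(x, ...) {
  cat(sprintf(
    "ATT estimate: %.4f (SE %.4f, %g%% CI %.4f to %.4f) [%s variance]\n",
    x$estimate, x$standard_error, 100 * x$ci_level, x$ci_low, x$ci_high,
    x$variance))
  if (!is.na(x$trim_percentile)) {
    cat(sprintf("  weights: %s, trim percentile %d\n", x$method,
                x$trim_percentile))
  }
  invisible(x)
}

#' @export
coef.att_estimate <- function(object, ...) {
  c(exposure = object$estimate)
}

#' @export
confint.att_estimate <- function(object, parm, level, ...) {
  m <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
              dimnames = list("exposure",
                              sprintf("%.1f %%",
                                      100 * c((1 - object$ci_level) / 2,
                                              1 - (1 - object$ci_level) / 2))))
  m
}
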