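#' Clip probabilities away from 0 and 1
#'
#' Tree-based learners can emit fitted probabilities of exactly 0 or 1,
#' which map to degenerate or infinite odds weights.  Values below `epsilon`
#' are raised to `epsilon` and values above `1 - epsilon` lowered to
#' `1 - epsilon`; interior values pass through unchanged.  The default
#' `epsilon = 1e-3` caps an odds weight at 999, far above the largest weight
#' a realistic fit produces, so clipping only guards the boundary.
#'
#' @param raw Numeric vector in \[0, 1\].
#' @param epsilon Clip bound, in (0, 0.5).
#' @return List with `propensity` (clipped values) and `n_clipped`.
#' @examples
#' clip_propensity(c(0, 0.5, 1), 0.001)
#' @export
clip_propensity <- function(raw, epsilon = 1e-3) {
  if (epsilon <= 0 || epsilon >= 0.5) {
    stop("epsilon must lie in (0, 0.5)", call. = FALSE)
  }
  clipped <- pmin(pmax(raw, epsilon), 1 - epsilon)
  list(propensity = clipped, n_clipped = sum(clipped != raw))
}

#' Estimate propensity scores
#'
#' Fits one of four propensity score models to a simulated dataset:
#'
#' * `"logistic"`: maximum-likelihood logistic regression on the main
#'   effects of all covariates (no interactions or non-linear terms);
#' * `"cart"`: a single classification tree ([rpart::rpart()]); the
#'   propensity is the treated fraction of the terminal node;
#' * `"random_forest"`: a classification forest
#'   ([randomForest::randomForest()]); the propensity is the fraction of
#'   out-of-bag trees voting "treated" (in-sample votes are available via
#'   `forest_votes = "insample"` but memorize each subject's own exposure);
#' * `"boosted"`: gradient-boosted shallow trees with the iteration chosen
#'   to minimize mean weighted KS covariate imbalance (see
#'   [fit_boosted_cart()]).
#'
#' Tree-based fitted probabilities are clipped via [clip_propensity()];
#' logistic probabilities are interior by construction and are not clipped
#' unless the fit is flagged (non-convergence or quasi-separation).
#'
#' @param data A `ps_simdata`, or any list with elements `covariates`
#'   (matrix) and `exposure` (0/1 vector).
#' @param method One of `"logistic"`, `"cart"`, `"random_forest"`,
#'   `"boosted"`.
#' @param control Named list of method settings; see [propensity_control()].
#' @param seed Integer seed for the stochastic learners (forest, boosting).
#'   Ignored by the deterministic methods.
#' @return An object of class `propensity_fit`: list with `method`,
#'   `propensity` (strictly inside (0,1)), `raw_propensity`, `clip_epsilon`,
#'   `n_clipped`, `metadata` and `n`.
#' @examples
#' d <- simulate_dataset(scenario_spec(1), n = 300, seed = 1)
#' f <- fit_propensity(d, "logistic")
#' f
#' @export
fit_propensity <- function(data,
                           method = c("logistic", "cart", "random_forest",
                                      "boosted"),
                           control = propensity_control(), seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(data$covariates)
  a <- as.integer(data$exposure)
  if (length(a) != nrow(x)) {
    stop("exposure length must match covariate rows", call. = FALSE)
  }
  if (length(unique(a)) < 2L) {
    stop("both exposure groups must be non-empty", call. = FALSE)
  }
  switch(method,
    logistic = fit_logistic_main_effects(x, a, control),
    cart = fit_cart_tree(x, a, control),
    random_forest = fit_forest(x, a, control, seed),
    boosted = fit_boosted_cart(data, control, seed)
  )
}

#' Method settings for propensity estimation
#'
#' Returns the default settings used by [fit_propensity()], overridable by
#' name.  Tree settings mirror the reference implementations' documented
#' defaults: CART stops at `minsplit = 20`, `minbucket = 7`, complexity
#' threshold `cp = 0.01`; the forest grows `ntree = 500` trees with
#' `mtry = floor(sqrt(p))` predictors per split and bootstrap resampling;
#' boosting uses depth-3 trees, shrinkage 0.005, 50\% subsampling, up to
#' `max_trees = 10000` iterations evaluated for balance every
#' `eval_every = 100`.
#'
#' @param ... Named overrides.
#' @return Named list of settings.
#' @export
propensity_control <- function(...) {
  ctl <- list(
    clip_epsilon = 1e-3,
    ## CART
    minsplit = 20L, minbucket = 7L, cp = 0.01, maxdepth = 30L,
    ## forest
    ntree = 500L, mtry = NULL, replace = TRUE, nodesize = 1L,
    sampsize = NULL, forest_votes = "oob",
    ## boosting
    max_trees = 10000L, shrinkage = 0.005, depth = 3L, subsample = 0.5,
    eval_every = 100L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(ctl))
  if (length(unknown)) {
    stop("unknown control setting(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ctl[names(dots)] <- dots
  ctl
}

new_propensity_fit <- function(method, raw, epsilon, metadata, clip = TRUE) {
  if (clip) {
    cl <- clip_propensity(raw, epsilon)
    p <- cl$propensity
    nc <- cl$n_clipped
  } else {
    p <- raw
    nc <- 0L
    epsilon <- 0
  }
  structure(
    list(method = method, propensity = p, raw_propensity = raw,
         clip_epsilon = epsilon, n_clipped = nc, metadata = metadata,
         n = length(raw)),
    class = "propensity_fit")
}

fit_logistic_main_effects <- function(x, a, control) {
  fit <- stats::glm.fit(cbind(`(Intercept)` = 1, x), a,
                        family = stats::binomial())
  p <- fit$fitted.values
  eps <- sqrt(.Machine$double.eps)
  separated <- any(p < eps | p > 1 - eps)
  flagged <- !fit$converged || separated
  if (flagged) {
    warning("logistic propensity fit flagged: ",
            if (!fit$converged) "did not converge " else "",
            if (separated) "fitted probabilities at the boundary" else "",
            call. = FALSE)
  }
  meta <- list(coefficients = fit$coefficients, converged = fit$converged,
               separation = separated, flagged = flagged)
  ## MLE probabilities are interior unless the fit is flagged
  new_propensity_fit("logistic", p, control$clip_epsilon, meta,
                     clip = flagged)
}

fit_cart_tree <- function(x, a, control) {
  df <- data.frame(.a = factor(a, levels = c(0, 1)), x)
  fit <- rpart::rpart(.a ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        minsplit = control$minsplit,
                        minbucket = control$minbucket,
                        cp = control$cp, maxdepth = control$maxdepth,
                        xval = 0))
  raw <- unname(stats::predict(fit, type = "prob")[, "1"])
  no_split <- nrow(fit$frame) == 1L
  if (no_split) {
    warning("CART found no usable split; propensity is the sample prevalence",
            call. = FALSE)
  }
  meta <- list(n_terminal = sum(fit$frame$var == "<leaf>"),
               no_split = no_split, tree = fit)
  new_propensity_fit("cart", raw, control$clip_epsilon, meta)
}

fit_forest <- function(x, a, control, seed) {
  mtry <- if (is.null(control$mtry)) max(1L, floor(sqrt(ncol(x)))) else
    control$mtry
  sampsize <- if (is.null(control$sampsize)) nrow(x) else control$sampsize
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(
    x, factor(a, levels = c(0, 1)), ntree = control$ntree, mtry = mtry,
    replace = control$replace, nodesize = control$nodesize,
    sampsize = sampsize)
  raw <- if (control$forest_votes == "oob") {
    ## out-of-bag vote fractions: a subject's propensity comes only from
    ## trees that did not train on it.  In-sample votes of fully grown
    ## trees memorize each subject's own exposure, which caps control
    ## weights near 0.6 and defeats the weighting.
    v <- unname(fit$votes[, "1"])
    if (anyNA(v) || any(!is.finite(v))) {
      stop("some subjects have no out-of-bag trees (ntree too small or ",
           "no resampling); use forest_votes = \"insample\"", call. = FALSE)
    }
    v
  } else {
    unname(stats::predict(fit, newdata = x, type = "prob")[, "1"])
  }
  meta <- list(ntree = control$ntree, mtry = mtry, seed = as.integer(seed),
               votes = control$forest_votes)
  new_propensity_fit("random_forest", raw, control$clip_epsilon, meta)
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("Propensity fit (%s), n = %d\n", x$method, x$n))
  q <- stats::quantile(x$propensity, c(0.25, 0.5, 0.75))
  cat(sprintf("  propensity quartiles: %.3f / %.3f / %.3f; clipped: %d\n",
              q[1], q[2], q[3], x$n_clipped))
  if (x$method == "boosted") {
    cat(sprintf("  chosen boosting iteration: %d (mean KS %.4f)\n",
                x$metadata$balance_path$chosen_iteration,
                min(x$metadata$balance_path$mean_ks)))
  }
  invisible(x)
}

#' @export
predict.propensity_fit <- function(object, ...) {
  object$propensity
}
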