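#' Boosted-tree propensity scores with a KS-balance stopping rule
#'
#' Fits a gradient-boosted classification ensemble of shallow trees
#' (via [xgboost::xgb.train()]) and selects the boosting iteration that
#' minimizes covariate imbalance rather than classification loss: at each
#' candidate iteration on the evaluation grid, candidate propensities are
#' turned into inverse-odds weights for the average effect among the treated
#' (treated weight 1, controls weighted \eqn{p/(1-p)}) and the mean weighted
#' Kolmogorov-Smirnov statistic over all covariates is computed
#' ([weighted_ks()]).  The returned propensities are those of the first
#' iteration attaining the minimum mean KS; the whole balance path is kept in
#' the fit metadata.
#'
#' @param data A `ps_simdata` or list with `covariates` and `exposure`.
#' @param control Settings from [propensity_control()]: `max_trees`,
#'   `shrinkage`, `depth`, `subsample`, `eval_every`, `clip_epsilon`.
#' @param seed Integer seed passed to the booster (single-threaded, so the
#'   fit is reproducible).
#' @return A `propensity_fit` whose `metadata$balance_path` is a data frame
#'   `iteration, mean_ks` plus the `chosen_iteration`.
#' @examples
#' d <- simulate_dataset(scenario_spec(1), n = 200, seed = 3)
#' ctl <- propensity_control(max_trees = 200, eval_every = 50)
#' f <- fit_boosted_cart(d, ctl, seed = 1)
#' f$metadata$balance_path$chosen_iteration
#' @export
fit_boosted_cart <- function(data, control = propensity_control(),
                             seed = 1L) {
  x <- as.matrix(data$covariates)
  a <- as.integer(data$exposure)
  if (length(unique(a)) < 2L) {
    stop("both exposure groups must be non-empty", call. = FALSE)
  }
  if (control$max_trees < control$eval_every) {
    stop("empty evaluation grid: max_trees (", control$max_trees,
         ") is smaller than eval_every (", control$eval_every, ")",
         call. = FALSE)
  }
  grid <- seq(control$eval_every, control$max_trees, by = control$eval_every)
  dtrain <- xgboost::xgb.DMatrix(x, label = a, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = control$depth, eta = control$shrinkage,
                  subsample = control$subsample, nthread = 1,
                  seed = as.integer(seed)),
    data = dtrain, nrounds = control$max_trees, verbose = 0)
  mean_ks <- vapply(grid, function(g) {
    p <- stats::predict(booster, dtrain, iterationrange = c(1, g))
    p <- clip_propensity(p, control$clip_epsilon)$propensity
    wts <- ifelse(a == 1L, 1, p / (1 - p))
    mean(vapply(seq_len(ncol(x)),
                function(j) weighted_ks(x[, j], a, wts), numeric(1)))
  }, numeric(1))
  chosen <- grid[which.min(mean_ks)]   # first minimizer on ties
  raw <- stats::predict(booster, dtrain, iterationrange = c(1, chosen))
  meta <- list(
    balance_path = list(iteration = grid, mean_ks = mean_ks,
                        chosen_iteration = chosen),
    seed = as.integer(seed),
    params = control[c("max_trees", "shrinkage", "depth", "subsample",
                       "eval_every")])
  new_propensity_fit("boosted", raw, control$clip_epsilon, meta)
}

#' Export a boosting balance path as CSV
#'
#' @param fit A boosted `propensity_fit`.
#' @param path Output file; columns `iteration, mean_ks`.
#' @return `path`, invisibly.
#' @export
write_balance_path_csv <- function(fit, path) {
  bp <- fit$metadata$balance_path
  if (is.null(bp)) stop("fit has no balance path", call. = FALSE)
  utils::write.csv(data.frame(iteration = bp$iteration,
                              mean_ks = bp$mean_ks),
                   path, row.names = FALSE)
  invisible(path)
}
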