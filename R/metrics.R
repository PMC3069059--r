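#' Absolute percent bias of a set of estimates
#'
#' The absolute percentage difference between the Monte-Carlo mean estimate
#' and the true effect: \eqn{100 |\bar\theta - \theta| / |\theta|}.  This is
#' the bias of the averaged estimator, not the average absolute error;
#' `signed = TRUE` returns the signed version (positive when the mean
#' estimate exceeds the truth).
#'
#' @param estimates Numeric vector of per-replicate estimates.
#' @param truth True effect (non-zero).
#' @param signed Return the signed percent bias instead of its absolute
#'   value.
#' @return Percent bias.
#' @examples
#' absolute_percent_bias(c(-0.3, -0.3), truth = -0.4)  # 25
#' @export
absolute_percent_bias <- function(estimates, truth, signed = FALSE) {
  if (!length(estimates)) stop("no estimates supplied", call. = FALSE)
  if (truth == 0) {
    stop("relative bias is undefined for truth = 0", call. = FALSE)
  }
  b <- 100 * (mean(estimates) - truth) / abs(truth)
  if (signed) b else abs(b)
}

#' Mean per-replicate absolute percent error
#'
#' The companion measure to [absolute_percent_bias()]: the Monte-Carlo mean
#' of the per-replicate absolute percent errors
#' \eqn{100 |\theta_k - \theta| / |\theta|}.  Includes sampling variability,
#' so it is bounded away from zero even for an unbiased estimator.
#'
#' @inheritParams absolute_percent_bias
#' @return Mean absolute percent error.
#' @export
mean_absolute_percent_error <- function(estimates, truth) {
  if (!length(estimates)) stop("no estimates supplied", call. = FALSE)
  if (truth == 0) {
    stop("relative error is undefined for truth = 0", call. = FALSE)
  }
  mean(100 * abs(estimates - truth) / abs(truth))
}

estimate_field <- function(records, field) {
  if (is.data.frame(records)) return(records[[field]])
  vapply(records, function(r) r[[field]], numeric(1))
}

#' Confidence-interval coverage percentage
#'
#' @param records List of `att_estimate` objects, or a data frame with
#'   columns `ci_low` and `ci_high`.
#' @param truth True effect.
#' @return Percent of intervals covering the truth (a multiple of
#'   `100 / n`).
#' @export
coverage_percent <- function(records, truth) {
  lo <- estimate_field(records, "ci_low")
  hi <- estimate_field(records, "ci_high")
  if (!length(lo)) stop("no records supplied", call. = FALSE)
  100 * mean(lo <= truth & truth <= hi)
}

#' Mean reported standard error
#'
#' Arithmetic mean of the per-replicate standard errors.
#'
#' @param records List of `att_estimate` objects or a data frame with a
#'   `standard_error` (or `se`) column.
#' @return Mean standard error.
#' @export
mean_standard_error <- function(records) {
  se <- if (is.data.frame(records)) {
    if (!is.null(records$standard_error)) records$standard_error else
      records$se
  } else {
    estimate_field(records, "standard_error")
  }
  if (!length(se)) stop("no records supplied", call. = FALSE)
  mean(se)
}

#' Weight distribution diagnostics for the unexposed group
#'
#' Characterizes the untrimmed ATT odds weights of the unexposed group
#' across replicates: quartiles, median and maximum of the pooled weights,
#' the proportions of pooled weights at least 10 and at least 20, and the
#' average (across replicates) of the sum of weights above the replicate's
#' own 95th percentile — the total weight carried by the top 5\% of
#' unexposed subjects.
#'
#' @param weight_sets List of untrimmed `weight_set` objects (one per
#'   replicate).
#' @return List with `q1`, `median`, `q3`, `max`, `prop_ge_10`,
#'   `prop_ge_20`, `mean_top5_sum`, `n_reps`, `n_pooled`.
#' @export
weight_diagnostics <- function(weight_sets) {
  if (!length(weight_sets)) stop("no weight sets supplied", call. = FALSE)
  trimmed <- vapply(weight_sets, function(w) w$trim_percentile < 100L,
                    logical(1))
  if (any(trimmed)) {
    stop("weight diagnostics are defined for untrimmed weights only",
         call. = FALSE)
  }
  unexp <- lapply(weight_sets, function(w) w$weights[w$exposure == 0L])
  pooled <- unlist(unexp, use.names = FALSE)
  top5 <- vapply(unexp, function(v) {
    sum(v[v > stats::quantile(v, 0.95, type = 7)])
  }, numeric(1))
  q <- unname(stats::quantile(pooled, c(0.25, 0.5, 0.75), type = 7))
  list(q1 = q[1], median = q[2], q3 = q[3], max = max(pooled),
       prop_ge_10 = mean(pooled >= 10), prop_ge_20 = mean(pooled >= 20),
       mean_top5_sum = mean(top5), n_reps = length(unexp),
       n_pooled = length(pooled))
}

#' Agreement of weights across estimation methods
#'
#' For each pair of propensity estimation methods, computes the Spearman
#' rank correlation of the unexposed subjects' weights within each replicate
#' and averages across replicates (weights of a replicate are compared on
#' the same subjects).
#'
#' @param weights_by_method Named list; each element is a list (one entry
#'   per replicate) of numeric vectors of unexposed weights, all methods
#'   sharing the same replicates.
#' @param pooled If `TRUE`, compute a single correlation on the pooled
#'   weights instead of averaging per-replicate correlations.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_weight_correlations <- function(weights_by_method, pooled = FALSE) {
  m <- length(weights_by_method)
  if (m < 1) stop("no methods supplied", call. = FALSE)
  nrep <- unique(vapply(weights_by_method, length, integer(1)))
  if (length(nrep) != 1) {
    stop("methods have differing numbers of replicates", call. = FALSE)
  }
  for (k in seq_len(nrep)) {
    sizes <- unique(vapply(weights_by_method,
                           function(w) length(w[[k]]), integer(1)))
    if (length(sizes) != 1) {
      stop("replicate ", k, " has mismatched subjects across methods",
           call. = FALSE)
    }
  }
  nm <- names(weights_by_method)
  out <- diag(m)
  dimnames(out) <- list(nm, nm)
  if (m == 1) return(out)
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      r <- if (pooled) {
        stats::cor(unlist(weights_by_method[[i]]),
                   unlist(weights_by_method[[j]]), method = "spearman")
      } else {
        mean(vapply(seq_len(nrep), function(k) {
          stats::cor(weights_by_method[[i]][[k]],
                     weights_by_method[[j]][[k]], method = "spearman")
        }, numeric(1)))
      }
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}

#' Aggregate replicate estimates into a performance table
#'
#' One row per (scenario, method, trim percentile) with the Monte-Carlo
#' operating characteristics: absolute percent bias of the mean estimate
#' (and its signed version), mean per-replicate absolute percent error, the
#' mean reported standard error, the Monte-Carlo standard deviation of the
#' estimates (the empirical standard error of the estimator), confidence
#' interval coverage, and the Monte-Carlo standard error of the bias.
#'
#' @param records Data frame with columns `scenario`, `method`,
#'   `trim_percentile`, `estimate`, `se`, `ci_low`, `ci_high`.
#' @param truth True effect (default -0.4).
#' @return Data frame of class `performance_table`.
#' @export
performance_table <- function(records, truth = -0.4) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  key <- interaction(records$scenario, records$method,
                     records$trim_percentile, drop = TRUE)
  rows <- lapply(split(records, key), function(r) {
    data.frame(
      scenario = r$scenario[1], method = r$method[1],
      trim_percentile = r$trim_percentile[1],
      n_reps = nrow(r),
      abs_percent_bias = absolute_percent_bias(r$estimate, truth),
      signed_percent_bias = absolute_percent_bias(r$estimate, truth,
                                                  signed = TRUE),
      mean_abs_percent_error = mean_absolute_percent_error(r$estimate,
                                                           truth),
      mean_se = mean(r$se),
      mc_sd = stats::sd(r$estimate),
      coverage_percent = coverage_percent(r, truth),
      mc_se_of_bias = 100 * stats::sd(r$estimate) / sqrt(nrow(r)) /
        abs(truth))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$scenario, out$method, -out$trim_percentile), ]
  rownames(out) <- NULL
  class(out) <- c("performance_table", "data.frame")
  out
}

#' Trim level optimizing a performance criterion
#'
#' Scans the trim grid of one (scenario, method) cell of a performance table
#' and returns the percentile minimizing absolute percent bias
#' (`criterion = "bias"`) or the distance of coverage from the nominal 95\%
#' (`criterion = "coverage"`).  Ties go to the least-trimmed (largest)
#' percentile.
#'
#' @param table A `performance_table`.
#' @param scenario,method Cell selectors.
#' @param criterion `"bias"` or `"coverage"`.
#' @param grid Trim grid the table is required to contain for this cell
#'   (default `50:100`).
#' @return The optimal trim percentile (integer).
#' @export
optimal_trim_level <- function(table, scenario, method,
                               criterion = c("bias", "coverage"),
                               grid = 50:100) {
  criterion <- match.arg(criterion)
  rows <- table[table$scenario == scenario & table$method == method, ]
  missing_q <- setdiff(grid, rows$trim_percentile)
  if (length(missing_q)) {
    stop("performance table is missing trim percentiles ",
         paste(missing_q, collapse = ", "), " for scenario ", scenario,
         " method ", method, call. = FALSE)
  }
  rows <- rows[rows$trim_percentile %in% grid, ]
  score <- if (criterion == "bias") {
    rows$abs_percent_bias
  } else {
    abs(rows$coverage_percent - 95)
  }
  best <- rows$trim_percentile[score == min(score)]
  max(best)   # least trimming wins ties
}
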