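#' Inverse-odds weights for the effect among the treated
#'
#' Weighting by the odds: exposed subjects receive weight 1; unexposed
#' subjects receive \eqn{p/(1-p)}, where \eqn{p} is the estimated propensity
#' score.  This reweights the unexposed group to resemble the exposed group,
#' so the weighted contrast targets the average treatment effect among the
#' treated (ATT).
#'
#' @param fit A `propensity_fit`, or a numeric vector of propensities
#'   strictly inside (0, 1).
#' @param exposure 0/1 exposure vector of the same length.
#' @return An object of class `weight_set`: list with `weights`, `exposure`,
#'   `trim_percentile` (100 = untrimmed), `cutpoint_value` (`NA` when
#'   untrimmed) and `source_method`.
#' @examples
#' odds_weights(c(0.5, 0.9, 0.2), c(1, 0, 0))$weights  # 1, 9, 0.25
#' @export
odds_weights <- function(fit, exposure) {
  if (inherits(fit, "propensity_fit")) {
    p <- fit$propensity
    method <- fit$method
  } else {
    p <- as.numeric(fit)
    method <- "supplied"
  }
  a <- as.integer(exposure)
  if (length(p) != length(a)) {
    stop("propensity and exposure lengths differ", call. = FALSE)
  }
  if (any(p <= 0 | p >= 1)) {
    stop("propensities must lie strictly in (0, 1)", call. = FALSE)
  }
  w <- ifelse(a == 1L, 1, p / (1 - p))
  structure(
    list(weights = w, untrimmed_weights = w, exposure = a,
         trim_percentile = 100L, cutpoint_value = NA_real_,
         source_method = method),
    class = "weight_set")
}

#' Trim large weights at a percentile cutpoint
#'
#' Weight trimming (truncation): every weight above the cutpoint value
#' \eqn{w_0} is set equal to \eqn{w_0}, where \eqn{w_0} is the requested
#' percentile of the weight distribution.  Exposed subjects' weights are 1 by
#' construction and are never altered.  Percentile 100 means no trimming.
#' The studied range is the 50th to the 99th percentile.
#'
#' Trimming always operates on the untrimmed weights retained inside the
#' `weight_set`, so trimming at the same percentile twice changes nothing and
#' successive trims at different percentiles do not compound.
#'
#' @param ws A `weight_set`.
#' @param percentile Integer in \[50, 100\].
#' @param reference Population over which the percentile is computed:
#'   `"unexposed"` (default; the group whose weights vary) or `"all"`.
#'   Quantiles use the type-7 (linear interpolation) convention.
#' @return A `weight_set` with updated `weights`, `trim_percentile` and
#'   `cutpoint_value`.
#' @examples
#' ws <- odds_weights(c(0.5, 0.9, 0.8, 0.2), c(1, 0, 0, 0))
#' trim_weights(ws, 50)$weights
#' @export
trim_weights <- function(ws, percentile,
                         reference = c("unexposed", "all")) {
  stopifnot(inherits(ws, "weight_set"))
  reference <- match.arg(reference)
  percentile <- as.integer(percentile)
  if (is.na(percentile) || percentile < 50L || percentile > 100L) {
    stop("trim percentile must lie in [50, 100]", call. = FALSE)
  }
  base <- if (is.null(ws$untrimmed_weights)) ws$weights else
    ws$untrimmed_weights
  out <- ws
  out$weights <- base
  out$untrimmed_weights <- base
  out$trim_percentile <- percentile
  if (percentile == 100L) {
    out$cutpoint_value <- NA_real_
    return(out)
  }
  ref <- if (reference == "unexposed") base[ws$exposure == 0L] else base
  cut <- unname(stats::quantile(ref, percentile / 100, type = 7))
  unexp <- ws$exposure == 0L
  out$weights[unexp] <- pmin(base[unexp], cut)
  out$cutpoint_value <- cut
  out
}

#' Trim a weight set over a grid of percentiles
#'
#' Applies [trim_weights()] independently to the untrimmed weights for each
#' requested percentile.  The default grid is the studied range — the 50th to
#' 99th percentiles at 1\% steps plus 100 (untrimmed).
#'
#' @param ws An untrimmed `weight_set`.
#' @param percentiles Integer vector within \[50, 100\].
#' @param reference As in [trim_weights()].
#' @return Named list of `weight_set` objects, one per percentile.
#' @export
trim_grid <- function(ws, percentiles = 50:100,
                      reference = c("unexposed", "all")) {
  reference <- match.arg(reference)
  out <- lapply(percentiles, function(q) trim_weights(ws, q, reference))
  names(out) <- as.character(percentiles)
  out
}

#' @export
print.weight_set <- function(x, ...) {
  unexp <- x$weights[x$exposure == 0L]
  cat(sprintf("ATT odds weights (%s): %d exposed (weight 1), %d unexposed\n",
              x$source_method, sum(x$exposure), length(unexp)))
  cat(sprintf("  trim percentile: %s%s\n",
              if (x$trim_percentile == 100L) "none" else x$trim_percentile,
              if (!is.na(x$cutpoint_value))
                sprintf(" (cutpoint %.3f)", x$cutpoint_value) else ""))
  q <- stats::quantile(unexp, c(0.25, 0.5, 0.75))
  cat(sprintf("  unexposed weights: q1 %.3f, median %.3f, q3 %.3f, max %.3f\n",
              q[1], q[2], q[3], max(unexp)))
  invisible(x)
}

#' Export a weight set as CSV
#'
#' @param ws A `weight_set`.
#' @param path Output file; columns `id, exposure, weight, trim_percentile`.
#' @return `path`, invisibly.
#' @export
write_weights_csv <- function(ws, path) {
  stopifnot(inherits(ws, "weight_set"))
  utils::write.csv(
    data.frame(id = seq_along(ws$weights), exposure = ws$exposure,
               weight = ws$weights, trim_percentile = ws$trim_percentile),
    path, row.names = FALSE)
  invisible(path)
}
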