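#' Weighted two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum over the pooled observed values of the absolute difference
#' between the weighted empirical CDFs of the two groups, each normalized by
#' its group's total weight.  With unit weights this is the classical
#' two-sample KS statistic.  Used as the covariate-balance metric inside the
#' boosting stopping rule: 0 means the weighted control distribution matches
#' the treated distribution exactly, 1 means disjoint support.
#'
#' @param x Numeric vector of covariate values.
#' @param group 0/1 vector; 1 = treated.
#' @param weights Non-negative weights (default all 1).
#' @return The statistic, in \[0, 1\].
#' @examples
#' weighted_ks(c(1, 2, 3, 4), c(1, 1, 0, 0))          # disjoint: 1
#' weighted_ks(c(1, 2, 3, 4), c(1, 0, 1, 0))          # interleaved: 0.5
#' @export
weighted_ks <- function(x, group, weights = rep(1, length(x))) {
  n <- length(x)
  if (length(group) != n || length(weights) != n) {
    stop("x, group and weights must have equal length", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  g <- as.integer(group)
  if (!all(g %in% c(0L, 1L))) stop("group must be 0/1", call. = FALSE)
  wt <- sum(weights[g == 1L])
  wc <- sum(weights[g == 0L])
  if (wt <= 0 || wc <= 0) {
    stop("zero total weight in the ",
         if (wt <= 0) "treated" else "control", " group", call. = FALSE)
  }
  o <- order(x)
  xs <- x[o]
  inc_t <- ifelse(g[o] == 1L, weights[o], 0) / wt
  inc_c <- ifelse(g[o] == 0L, weights[o], 0) / wc
  d <- cumsum(inc_t) - cumsum(inc_c)
  ## evaluate only at the last index of each tied value block
  last <- c(xs[-1] != xs[-length(xs)], TRUE)
  max(abs(d[last]))
}
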