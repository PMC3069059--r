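#' Configuration for a trimming experiment
#'
#' Bundles the full factorial design — scenarios, propensity methods, trim
#' grid, replicate count — with the estimation options.  Methods are fitted
#' once per replicate and the fitted weights are trimmed at every grid
#' percentile, so the grid adds almost no cost.
#'
#' @param scenarios List of [scenario_spec()] objects, or integers selecting
#'   packaged scenarios.
#' @param methods Subset of `c("logistic", "cart", "random_forest",
#'   "boosted")`.
#' @param trim_grid Integer percentiles within \[50, 100\].
#' @param n Sample size per replicate (default 500).
#' @param n_reps Replicates per scenario (default 1000).
#' @param base_seed Integer; replicate `k` of every scenario uses dataset
#'   seed `base_seed + k` (method-specific seeds are derived from it).
#' @param ci_level Confidence level.
#' @param variance `"model"` or `"sandwich"` (see [estimate_effect()]).
#' @param trim_reference `"unexposed"` or `"all"` (see [trim_weights()]).
#' @param control Method settings from [propensity_control()].
#' @param keep_weights Keep per-replicate unexposed weight vectors for
#'   diagnostics (default `TRUE`).
#' @return A `run_config` object.
#' @export
run_config <- function(scenarios = 1:3,
                       methods = c("logistic", "cart", "random_forest",
                                   "boosted"),
                       trim_grid = 50:100, n = 500, n_reps = 1000,
                       base_seed = 0, ci_level = 0.95,
                       variance = c("model", "sandwich"),
                       trim_reference = c("unexposed", "all"),
                       control = propensity_control(),
                       keep_weights = TRUE) {
  variance <- match.arg(variance)
  trim_reference <- match.arg(trim_reference)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.numeric(scenarios)) {
    scenarios <- lapply(scenarios, scenario_spec)
  }
  if (!length(scenarios) ||
      !all(vapply(scenarios, inherits, logical(1), "scenario_spec"))) {
    stop("'scenarios' must be scenario numbers or scenario_spec objects",
         call. = FALSE)
  }
  trim_grid <- sort(unique(as.integer(trim_grid)), decreasing = TRUE)
  if (any(trim_grid < 50L | trim_grid > 100L)) {
    stop("trim_grid must lie within [50, 100]", call. = FALSE)
  }
  if (n_reps < 1) stop("n_reps must be at least 1", call. = FALSE)
  structure(
    list(scenarios = scenarios, methods = methods, trim_grid = trim_grid,
         n = as.integer(n), n_reps = as.integer(n_reps),
         base_seed = as.integer(base_seed), ci_level = ci_level,
         variance = variance, trim_reference = trim_reference,
         control = control, keep_weights = keep_weights),
    class = "run_config")
}

#' Packaged configuration reproducing the full study
#'
#' The full design: three scenarios, four propensity methods, the 50-100
#' trim grid, 1000 replicates of 500 subjects.  `reduced = TRUE` drops to
#' 250 replicates for a faster pass with the same factorial structure.
#'
#' @param reduced Use 250 replicates instead of 1000.
#' @param base_seed Base seed.
#' @param ... Further overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
replicate_paper_config <- function(reduced = FALSE, base_seed = 0, ...) {
  run_config(scenarios = 1:3,
             methods = c("logistic", "cart", "random_forest", "boosted"),
             trim_grid = 50:100, n = 500,
             n_reps = if (reduced) 250 else 1000,
             base_seed = base_seed, ...)
}

method_seed_offsets <- c(logistic = 0L, cart = 0L,
                         random_forest = 1000003L, boosted = 2000003L)

#' Run a weight-trimming experiment
#'
#' Executes the full factorial design of a [run_config()]: for every
#' (scenario, replicate) one dataset is generated and each method fitted
#' once; the untrimmed ATT odds weights are then trimmed at every grid
#' percentile and the weighted effect estimated, giving one record per
#' (scenario, method, trim percentile, replicate).  The run is deterministic
#' given the configuration.
#'
#' @param config A `run_config`.
#' @param outdir Optional directory; if given, the record stream
#'   (`records.csv`, appended after every replicate so interrupted runs keep
#'   partial results), summary tables and a JSON-like manifest are written
#'   there.
#' @param verbose Print progress.
#' @return Object of class `trim_experiment`: list with `records` (data
#'   frame), `weights` (per scenario/method lists of unexposed weight
#'   vectors, when kept), `config`, `manifest`.
#' @examples
#' cfg <- run_config(scenarios = 1, methods = "logistic",
#'                   trim_grid = c(100, 90), n = 200, n_reps = 3)
#' ex <- run_experiment(cfg)
#' nrow(ex$records)
#' @export
run_experiment <- function(config, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t_start <- proc.time()[["elapsed"]]
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  records_path <- if (!is.null(outdir)) file.path(outdir, "records.csv")
  rec_list <- vector("list", length(config$scenarios) * config$n_reps)
  ri <- 0L
  weights <- list()
  timings <- c(simulate = 0, fit = 0, estimate = 0)
  for (spec in config$scenarios) {
    sc <- spec$scenario_id
    sc_key <- paste0("scenario", sc)
    weights[[sc_key]] <- lapply(config$methods, function(m) list())
    names(weights[[sc_key]]) <- config$methods
    for (k in seq_len(config$n_reps)) {
      seed <- config$base_seed + k
      t0 <- proc.time()[["elapsed"]]
      d <- simulate_dataset(spec, n = config$n, seed = seed)
      t1 <- proc.time()[["elapsed"]]
      timings["simulate"] <- timings["simulate"] + (t1 - t0)
      rep_rows <- vector("list", length(config$methods))
      for (mi in seq_along(config$methods)) {
        m <- config$methods[mi]
        fit <- fit_propensity(d, m, control = config$control,
                              seed = seed + method_seed_offsets[[m]])
        t2 <- proc.time()[["elapsed"]]
        timings["fit"] <- timings["fit"] + (t2 - t1)
        ws <- odds_weights(fit, d$exposure)
        if (config$keep_weights) {
          weights[[sc_key]][[m]][[k]] <- ws$weights[ws$exposure == 0L]
        }
        nq <- length(config$trim_grid)
        vals <- matrix(NA_real_, nq, 4)
        for (qi in seq_len(nq)) {
          e <- estimate_effect(
            d, trim_weights(ws, config$trim_grid[qi],
                            config$trim_reference),
            ci_level = config$ci_level, variance = config$variance)
          vals[qi, ] <- c(e$estimate, e$standard_error, e$ci_low, e$ci_high)
        }
        rep_rows[[mi]] <- data.frame(
          scenario = sc, method = m, trim_percentile = config$trim_grid,
          seed = seed, estimate = vals[, 1], se = vals[, 2],
          ci_low = vals[, 3], ci_high = vals[, 4],
          covered = vals[, 3] <= spec$treatment_effect &
            spec$treatment_effect <= vals[, 4])
        t1 <- proc.time()[["elapsed"]]
        timings["estimate"] <- timings["estimate"] + (t1 - t2)
      }
      ri <- ri + 1L
      rec_list[[ri]] <- do.call(rbind, rep_rows)
      if (!is.null(records_path)) {
        utils::write.table(rec_list[[ri]], records_path, sep = ",",
                           row.names = FALSE,
                           col.names = !file.exists(records_path),
                           append = file.exists(records_path))
      }
      if (verbose && k %% 50 == 0) {
        message(sprintf("scenario %d: replicate %d/%d", sc, k,
                        config$n_reps))
      }
    }
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("pstrim")),
    n_records = nrow(records),
    scenarios = vapply(config$scenarios, `[[`, integer(1), "scenario_id"),
    methods = config$methods, trim_grid = config$trim_grid,
    n = config$n, n_reps = config$n_reps, base_seed = config$base_seed,
    variance = config$variance, trim_reference = config$trim_reference,
    seed_scheme = "dataset seed = base_seed + replicate index",
    timings_sec = c(round(timings, 3),
                    total = round(proc.time()[["elapsed"]] - t_start, 3)))
  ex <- structure(
    list(records = records,
         weights = if (config$keep_weights) weights else NULL,
         config = config, manifest = manifest),
    class = "trim_experiment")
  if (!is.null(outdir)) {
    write_experiment(ex, outdir)
  }
  ex
}

#' @export
print.trim_experiment <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "Weight-trimming experiment: %d records (%d scenario(s) x %s x %d trim level(s) x %d reps)\n",
    m$n_records, length(m$scenarios), paste(m$methods, collapse = "/"),
    length(m$trim_grid), m$n_reps))
  invisible(x)
}

#' Summarize an experiment
#'
#' Builds the performance table, untrimmed weight diagnostics per
#' (scenario, method), and the between-method Spearman correlation matrices
#' of unexposed weights.
#'
#' @param x A `trim_experiment`.
#' @param truth True effect; taken from the first scenario when omitted.
#' @return List of class `trim_summary` with elements `performance`,
#'   `diagnostics`, `spearman`.
#' @export
summarize_experiment <- function(x, truth = NULL) {
  stopifnot(inherits(x, "trim_experiment"))
  if (is.null(truth)) truth <- x$config$scenarios[[1]]$treatment_effect
  perf <- performance_table(x$records, truth = truth)
  diags <- NULL
  spear <- NULL
  if (!is.null(x$weights)) {
    diags <- lapply(x$weights, function(sc) {
      lapply(sc, function(wlist) {
        ws <- lapply(wlist, function(v) {
          structure(list(weights = v, exposure = rep(0L, length(v)),
                         trim_percentile = 100L, cutpoint_value = NA_real_,
                         source_method = "pooled"),
                    class = "weight_set")
        })
        weight_diagnostics(ws)
      })
    })
    if (length(x$config$methods) > 1) {
      spear <- lapply(x$weights, spearman_weight_correlations)
    }
  }
  structure(list(performance = perf, diagnostics = diags, spearman = spear,
                 truth = truth),
            class = "trim_summary")
}

#' @export
print.trim_summary <- function(x, ...) {
  p <- x$performance
  cat("Performance at selected trim levels (untrimmed and grid extremes):\n")
  show <- p[p$trim_percentile %in% c(100, 95, 90, 87, 80, 50), ]
  print(format(show[, c("scenario", "method", "trim_percentile",
                        "abs_percent_bias", "mean_se", "mc_sd",
                        "coverage_percent")],
               digits = 3), row.names = FALSE)
  invisible(x)
}

#' Write experiment outputs as CSV
#'
#' Writes the long-format record stream, the performance table, a weight
#' diagnostics table and the Spearman correlation matrices under `dir`.
#'
#' @param x A `trim_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  stopifnot(inherits(x, "trim_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!file.exists(file.path(dir, "records.csv"))) {
    utils::write.csv(x$records, file.path(dir, "records.csv"),
                     row.names = FALSE)
  }
  s <- summarize_experiment(x)
  utils::write.csv(s$performance, file.path(dir, "performance.csv"),
                   row.names = FALSE)
  if (!is.null(s$diagnostics)) {
    rows <- list()
    for (sc in names(s$diagnostics)) {
      for (m in names(s$diagnostics[[sc]])) {
        d <- s$diagnostics[[sc]][[m]]
        rows[[paste(sc, m)]] <- data.frame(
          scenario = sc, method = m, q1 = d$q1, median = d$median,
          q3 = d$q3, max = d$max, prop_ge_10 = d$prop_ge_10,
          prop_ge_20 = d$prop_ge_20, mean_top5_sum = d$mean_top5_sum)
      }
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(dir, "weight_diagnostics.csv"),
                     row.names = FALSE)
  }
  if (!is.null(s$spearman)) {
    for (sc in names(s$spearman)) {
      utils::write.csv(s$spearman[[sc]],
                       file.path(dir, paste0("spearman_", sc, ".csv")))
    }
  }
  manifest <- x$manifest
  writeLines(
    paste(names(unlist(manifest)), unlist(manifest), sep = ": "),
    file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Plot bias, SE or coverage against the trim percentile
#'
#' Reproduces the study's summary figures: one panel per scenario, one line
#' per propensity method, the chosen metric on the vertical axis and the
#' trim percentile (100 = untrimmed, decreasing to the right meaning more
#' trimming) on the horizontal axis.
#'
#' @param x A `trim_experiment` or `performance_table`.
#' @param metric One of `"bias"` (absolute percent bias), `"se"` (mean
#'   reported SE), `"mc_sd"` (empirical SE of the estimates), `"coverage"`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the performance table used.
#' @export
plot_trim_curves <- function(x, metric = c("bias", "se", "mc_sd",
                                           "coverage"), ...) {
  metric <- match.arg(metric)
  perf <- if (inherits(x, "trim_experiment")) {
    summarize_experiment(x)$performance
  } else {
    x
  }
  col <- switch(metric, bias = "abs_percent_bias", se = "mean_se",
                mc_sd = "mc_sd", coverage = "coverage_percent")
  ylab <- switch(metric, bias = "absolute percent bias (%)",
                 se = "mean standard error", mc_sd = "MC SD of estimates",
                 coverage = "95% CI coverage (%)")
  scenarios <- sort(unique(perf$scenario))
  methods <- unique(perf$method)
  op <- graphics::par(mfrow = c(1, length(scenarios)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (sc in scenarios) {
    p <- perf[perf$scenario == sc, ]
    qs <- sort(unique(p$trim_percentile), decreasing = TRUE)
    y <- sapply(methods, function(m) {
      pm <- p[p$method == m, ]
      pm[[col]][match(qs, pm$trim_percentile)]
    })
    graphics::matplot(rev(seq_along(qs)), y, type = "l", lty = 1, lwd = 2,
                      col = seq_along(methods), xaxt = "n",
                      xlab = "trim percentile", ylab = ylab,
                      main = paste("scenario", sc), ...)
    at <- pretty(seq_along(qs))
    at <- at[at >= 1 & at <= length(qs)]
    graphics::axis(1, at = at, labels = rev(qs)[at])
    if (metric == "coverage") graphics::abline(h = 95, lty = 3)
    graphics::legend("topleft", legend = methods, col = seq_along(methods),
                     lty = 1, lwd = 2, bty = "n", cex = 0.8)
  }
  invisible(perf)
}

#' @export
plot.trim_experiment <- function(x, metric = "bias", ...) {
  plot_trim_curves(x, metric = metric, ...)
}
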