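#' Round half away from zero
#'
#' Fixture tables print values rounded half-up to a fixed number of
#' decimals; base R's `round()` rounds half to even, so the convention is
#' implemented explicitly.
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon so decimal halves stored just below .5 in binary round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Normalize contour-modification times by from-scratch contouring time
#'
#' Divides each observer's per-case modification time by that same
#' observer's time to contour the organ from scratch, removing
#' between-observer speed differences so times can be pooled. Normalized
#' values are rounded half-up to 3 decimals to match printed-table
#' precision.
#'
#' @param times data.frame with columns `observer`, `case`, `seconds`.
#' @param scratch data.frame with columns `observer`, `scratch_seconds`
#'   (one row per observer, all > 0).
#' @return `times` with columns `scratch_seconds`, `normalized` (the exact
#'   ratio) and `normalized_printed` (half-up to 3 decimals, the precision
#'   at which such tables are printed) added.
#' @export
normalize_times <- function(times, scratch) {
  need <- c("observer", "case", "seconds")
  if (!all(need %in% names(times))) {
    stop("normalize_times(): 'times' needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(c("observer", "scratch_seconds") %in% names(scratch))) {
    stop("normalize_times(): 'scratch' needs columns observer, scratch_seconds",
         call. = FALSE)
  }
  if (any(scratch$scratch_seconds <= 0)) {
    stop("normalize_times(): scratch times must be > 0", call. = FALSE)
  }
  miss <- setdiff(unique(times$observer), scratch$observer)
  if (length(miss)) {
    stop("normalize_times(): missing from-scratch time for observer(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- match(times$observer, scratch$observer)
  times$scratch_seconds <- scratch$scratch_seconds[idx]
  times$normalized <- times$seconds / times$scratch_seconds
  times$normalized_printed <- round_half_up(times$normalized, 3)
  times
}

#' Ordinary least-squares line fit with R^2
#'
#' @param x,y numeric vectors of equal length (>= 3); `x` must vary.
#' @return an object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("fit_linear(): lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("fit_linear(): need at least 3 points", call. = FALSE)
  if (stats::sd(x) < 1e-12) {
    stop("fit_linear(): 'x' is constant; fit is degenerate", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  out <- list(slope = unname(stats::coef(fit)[2L]),
              intercept = unname(stats::coef(fit)[1L]),
              r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
              n = length(x))
  class(out) <- "regression_result"
  out
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): y = %.3f + %.3f x, R^2 = %.3f\n",
              x$n, x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Max-to-min ratio of a set of positive values
#'
#' Summary of inter-observer spread (for example of absolute versus
#' normalized contouring times); reported to 2 decimals (half-up).
#' @param values positive numeric vector.
#' @return max/min, rounded to 2 decimals.
#' @export
max_min_ratio <- function(values) {
  if (!length(values)) stop("max_min_ratio(): empty input", call. = FALSE)
  if (any(values <= 0)) stop("max_min_ratio(): values must be > 0", call. = FALSE)
  round_half_up(max(values) / min(values), 2)
}

#' Per-case means over observers
#'
#' Arithmetic mean of a value column per case across all observers,
#' rounded half-up to 3 decimals (printed-table precision). The table must
#' be complete: every case must have a value for every observer.
#'
#' @param df data.frame with columns `observer`, `case` and `value_col`.
#' @param value_col name of the value column to average.
#' @return data.frame with columns `case` and `mean` (one row per case,
#'   in first-appearance order).
#' @export
aggregate_observers <- function(df, value_col) {
  need <- c("observer", "case", value_col)
  if (!all(need %in% names(df))) {
    stop("aggregate_observers(): need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(df[[value_col]]))) {
    stop("aggregate_observers(): missing cells in '", value_col, "'",
         call. = FALSE)
  }
  tab <- table(df$case, df$observer)
  if (any(tab != 1L)) {
    stop("aggregate_observers(): table is not complete ",
         "(one value per case x observer required)", call. = FALSE)
  }
  cases <- unique(df$case)
  means <- vapply(cases, function(cs) {
    mean(df[[value_col]][df$case == cs])
  }, numeric(1L))
  data.frame(case = cases, mean = round_half_up(means, 3),
             stringsAsFactors = FALSE)
}

#' Load the packaged observer-study fixture tables
#'
#' The packaged CSVs transcribe a four-observer timing study on the two
#' simulated bladder contour sets: per-observer HSC and DSC of each case
#' against that observer's final contour, absolute contour-modification
#' seconds, from-scratch contouring seconds, and the printed normalized
#' times and per-case means used for cross-checking.
#'
#' @return list of data.frames: `metrics` (observer, case, hsc, dsc),
#'   `times` (observer, case, seconds), `scratch` (observer,
#'   scratch_seconds), `printed_normalized` (observer/AVE, case,
#'   normalized), `printed_metric_ave` (case, hsc, dsc).
#' @export
load_study_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "hsctools",
                                  mustWork = TRUE)
  list(
    metrics = utils::read.csv(path("observer_metrics.csv"),
                              stringsAsFactors = FALSE),
    times = utils::read.csv(path("observer_times.csv"),
                            stringsAsFactors = FALSE),
    scratch = utils::read.csv(path("observer_scratch.csv"),
                              stringsAsFactors = FALSE),
    printed_normalized = utils::read.csv(path("printed_normalized.csv"),
                                         stringsAsFactors = FALSE),
    printed_metric_ave = utils::read.csv(path("printed_metric_ave.csv"),
                                         stringsAsFactors = FALSE)
  )
}

#' Relate normalized modification time to a contour metric
#'
#' Normalizes the timing table, joins it with the per-observer metric
#' table on (observer, case), fits one OLS line per observer and one
#' pooled fit of per-case mean normalized time on per-case mean metric
#' value. Purely descriptive: no hypothesis test is performed. A
#' predictor that barely varies (as the DSC does within a fixed-DSC
#' contour set) yields a flagged, weak or degenerate fit rather than an
#' error in the pooled report.
#'
#' @param metrics_table data.frame with columns `observer`, `case` and
#'   the predictor column (`hsc` or `dsc`).
#' @param timing_table data.frame with columns `observer`, `case`,
#'   `seconds`.
#' @param scratch_table data.frame with columns `observer`,
#'   `scratch_seconds`.
#' @param predictor `"hsc"` or `"dsc"`.
#' @return an object of class `study_report`: list with `predictor`,
#'   `per_observer` (data.frame: observer, slope, intercept, r_squared,
#'   n), `pooled` ([fit_linear] result), `data` (joined long table) and
#'   `pooled_data` (per-case means).
#' @export
run_study <- function(metrics_table, timing_table, scratch_table,
                      predictor = c("hsc", "dsc")) {
  predictor <- match.arg(predictor)
  if (!predictor %in% names(metrics_table)) {
    stop("run_study(): metrics table has no '", predictor, "' column",
         call. = FALSE)
  }
  timed <- normalize_times(timing_table, scratch_table)
  key_m <- paste(metrics_table$observer, metrics_table$case)
  key_t <- paste(timed$observer, timed$case)
  unmatched <- setdiff(union(key_m, key_t), intersect(key_m, key_t))
  if (length(unmatched)) {
    stop("run_study(): unmatched observer/case keys: ",
         paste(unmatched, collapse = "; "), call. = FALSE)
  }
  joined <- merge(metrics_table, timed, by = c("observer", "case"),
                  sort = FALSE)

  obs <- unique(joined$observer)
  per_observer <- do.call(rbind, lapply(obs, function(o) {
    sub <- joined[joined$observer == o, ]
    fit <- fit_linear(sub[[predictor]], sub$normalized_printed)
    data.frame(observer = o, slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, n = fit$n,
               stringsAsFactors = FALSE)
  }))

  mx <- aggregate_observers(joined, predictor)
  mt <- aggregate_observers(joined, "normalized")
  pooled_data <- merge(stats::setNames(mx, c("case", "metric_mean")),
                       stats::setNames(mt, c("case", "normalized_mean")),
                       by = "case", sort = FALSE)
  pooled <- fit_linear(pooled_data$metric_mean, pooled_data$normalized_mean)

  out <- list(predictor = predictor, per_observer = per_observer,
              pooled = pooled, data = joined, pooled_data = pooled_data)
  class(out) <- "study_report"
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Normalized modification time ~ %s\n", toupper(x$predictor)))
  cat("Per-observer OLS fits:\n")
  print(x$per_observer, row.names = FALSE, digits = 3)
  cat("Pooled (per-case means): ")
  print(x$pooled)
  rng <- range(x$data[[x$predictor]])
  if (diff(rng) < 0.05) {
    cat(sprintf("note: predictor range is narrow (%.3f-%.3f); fit may be ",
                rng[1L], rng[2L]), "degenerate\n", sep = "")
  }
  invisible(x)
}

#' Scatter plot of a study report with fitted lines
#'
#' @param report a `study_report` from [run_study()].
#' @param pooled plot per-case means with the pooled fit instead of
#'   per-observer points and lines.
#' @return a ggplot object.
#' @export
plot_study <- function(report, pooled = FALSE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_study(): ggplot2 is not installed", call. = FALSE)
  }
  xlab <- toupper(report$predictor)
  if (pooled) {
    df <- report$pooled_data
    ggplot2::ggplot(df, ggplot2::aes(x = metric_mean,
                                     y = normalized_mean)) +
      ggplot2::geom_point() +
      ggplot2::geom_abline(slope = report$pooled$slope,
                           intercept = report$pooled$intercept) +
      ggplot2::labs(x = paste("Mean", xlab),
                    y = "Mean normalized modification time")
  } else {
    df <- report$data
    df$.metric <- df[[report$predictor]]
    ggplot2::ggplot(df, ggplot2::aes(x = .metric, y = normalized,
                                     colour = observer)) +
      ggplot2::geom_point() +
      ggplot2::geom_abline(
        data = report$per_observer,
        ggplot2::aes(slope = slope, intercept = intercept,
                     colour = observer)) +
      ggplot2::labs(x = xlab, y = "Normalized modification time",
                    colour = "Observer")
  }
}

utils::globalVariables(c("metric_mean", "normalized_mean", ".metric",
                         "normalized", "observer", "slope", "intercept"))
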