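#' Define a target yield interval
#'
#' The statistical interval of a yield-frequency analysis: plots whose
#' yields fall inside it are treated as coming from "successful" dose
#' combinations. Bounds are both-inclusive by default.
#'
#' @param lower,upper interval bounds (g/plant), `lower <= upper`.
#' @param lower_inclusive,upper_inclusive closure flags per bound.
#' @return a `yield_interval` object.
#' @examples
#' yield_interval(296, 413)
#' @export
yield_interval <- function(lower, upper, lower_inclusive = TRUE,
                           upper_inclusive = TRUE) {
  stopifnot(is.numeric(lower), is.numeric(upper), lower <= upper)
  structure(list(lower = lower, upper = upper,
                 lower_inclusive = isTRUE(lower_inclusive),
                 upper_inclusive = isTRUE(upper_inclusive)),
            class = "yield_interval")
}

in_interval <- function(y, interval) {
  lo <- if (interval$lower_inclusive) y >= interval$lower
        else y > interval$lower
  hi <- if (interval$upper_inclusive) y <= interval$upper
        else y < interval$upper
  lo & hi
}

#' @export
print.yield_interval <- function(x, ...) {
  cat(if (x$lower_inclusive) "[" else "(", x$lower, ", ", x$upper,
      if (x$upper_inclusive) "]" else ")", " g/plant\n", sep = "")
  invisible(x)
}

#' Count plot frequencies per factor level inside a yield interval
#'
#' Counts individual replicate plots (not treatments) whose yield falls
#' in the target interval, grouped by the plot's level of one factor.
#'
#' @param trial a [trial_data()] object with plot-level yields.
#' @param interval a [yield_interval()].
#' @param factor_id one of `"N"`, `"P"`, `"K"`.
#' @return a `freq_table`: data frame with columns `level`, `dose`
#'   (g/plant), `count` and `rate_pct`, plus attributes `factor_id` and
#'   `total`.
#' @examples
#' count_frequencies(lonicera_trial(), yield_interval(296, 413), "K")
#' @export
count_frequencies <- function(trial, interval, factor_id) {
  factor_id <- toupper(factor_id)
  if (!factor_id %in% fert_factors()) {
    stop("unknown factor: '", factor_id, "' (expected N, P or K)",
         call. = FALSE)
  }
  design <- trial$design
  plots <- trial$plots
  lev <- design_levels(design, plots$treatment, factor_id)
  hit <- in_interval(plots$yield, interval)
  counts <- vapply(0:3, function(l) sum(hit & lev == l), integer(1))
  lvl2 <- attr(design, "level2")[[factor_id]]
  doses <- level_multipliers() * lvl2
  total <- sum(counts)
  out <- data.frame(level = 0:3, dose = unname(doses), count = counts,
                    rate_pct = if (total > 0) 100 * counts / total
                               else rep(0, 4L))
  attr(out, "factor_id") <- factor_id
  attr(out, "total") <- total
  class(out) <- c("freq_table", "data.frame")
  out
}

#' Frequency-weighted mean dose
#'
#' Mean of the level doses weighted by how often plots at each level hit
#' the yield interval: sum(u_j n_j) / sum(n_j).
#'
#' @param table a [count_frequencies()] result.
#' @return g/plant.
#' @export
freq_weighted_mean <- function(table) {
  total <- sum(table$count)
  if (total == 0) {
    stop("no plots in the yield interval: weighted mean undefined",
         call. = FALSE)
  }
  sum(table$dose * table$count) / total
}

#' Frequency-weighted standard deviation of the dose
#'
#' sqrt( sum(n_j (u_j - mean)^2) / (total - 1) ).
#'
#' @param table a [count_frequencies()] result.
#' @param mean dose mean; defaults to [freq_weighted_mean()] but may be
#'   supplied externally (e.g. a published mean) to push through the
#'   downstream formulas verbatim.
#' @return g/plant.
#' @export
freq_weighted_sd <- function(table, mean = freq_weighted_mean(table)) {
  total <- sum(table$count)
  if (total < 2) {
    stop("need at least two plots in the interval for a standard deviation",
         call. = FALSE)
  }
  sqrt(sum(table$count * (table$dose - mean)^2) / (total - 1))
}

#' Standard error of the weighted mean dose
#'
#' @param sd standard deviation (g/plant).
#' @param total number of plots in the interval, > 0.
#' @return g/plant.
#' @export
standard_error <- function(sd, total) {
  stopifnot(total > 0, sd >= 0)
  sd / sqrt(total)
}

#' Confidence interval for the recommended dose
#'
#' mean +/- quantile x sd / sqrt(total). The default normal quantile
#' (1.959964 at 95%) is the conventional large-sample choice; a
#' Student-t quantile with total - 1 degrees of freedom is available and
#' is slightly wider at these sample sizes.
#'
#' @param mean weighted mean dose (g/plant).
#' @param sd standard deviation (g/plant), >= 0.
#' @param total plots in the interval, >= 2.
#' @param quantile_rule `"normal"` or `"t"`.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)` in g/plant.
#' @examples
#' confidence_interval(12, 6.40, 41)
#' @export
confidence_interval <- function(mean, sd, total,
                                quantile_rule = c("normal", "t"),
                                level = 0.95) {
  quantile_rule <- match.arg(quantile_rule)
  if (total < 2) stop("need total >= 2 for a confidence interval",
                      call. = FALSE)
  stopifnot(sd >= 0)
  q <- switch(quantile_rule,
              normal = stats::qnorm(1 - (1 - level) / 2),
              t = stats::qt(1 - (1 - level) / 2, df = total - 1))
  half <- q * standard_error(sd, total)
  c(lower = mean - half, upper = mean + half)
}

#' Frequency-analysis dose recommendation
#'
#' Runs the full count / weighted-mean / SD / SE / CI chain for each of
#' N, P and K, then predicts the yield of the point recommendation from a
#' ternary effect function. The point doses default to the weighted
#' means but can be overridden (e.g. rounded values carried forward from
#' a report).
#'
#' @param trial a [trial_data()] object with plot-level yields.
#' @param interval a [yield_interval()].
#' @param ternary_fit an [effect_function()] spanning N, P and K.
#' @param quantile_rule `"normal"` (default) or `"t"`, see
#'   [confidence_interval()].
#' @param point_doses optional named triple overriding the per-factor
#'   weighted means as the point recommendation.
#' @param level confidence level.
#' @return a `dose_recommendation`: list with `summary` (data frame:
#'   factor, total, mean, sd, se, ci_lower, ci_upper), `tables` (the
#'   three `freq_table`s), `point_doses` and `predicted_yield`.
#' @examples
#' trial <- lonicera_trial()
#' fit <- lonicera_effect_functions()$NPK
#' recommend_doses(trial, yield_interval(296, 413), fit)
#' @export
recommend_doses <- function(trial, interval, ternary_fit,
                            quantile_rule = c("normal", "t"),
                            point_doses = NULL, level = 0.95) {
  quantile_rule <- match.arg(quantile_rule)
  if (!setequal(ternary_fit$factors, fert_factors())) {
    stop("ternary_fit must span factors N, P and K", call. = FALSE)
  }
  tables <- lapply(stats::setNames(fert_factors(), fert_factors()),
                   function(f) count_frequencies(trial, interval, f))
  rows <- lapply(fert_factors(), function(f) {
    tab <- tables[[f]]
    total <- sum(tab$count)
    m <- freq_weighted_mean(tab)
    s <- freq_weighted_sd(tab, m)
    ci <- confidence_interval(m, s, total, quantile_rule, level)
    data.frame(factor = f, total = total, mean = m, sd = s,
               se = standard_error(s, total),
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  if (is.null(point_doses)) {
    point_doses <- stats::setNames(summary$mean, summary$factor)
  } else {
    if (is.null(names(point_doses))) names(point_doses) <- fert_factors()
    point_doses <- point_doses[fert_factors()]
  }
  structure(list(summary = summary, tables = tables,
                 point_doses = point_doses,
                 predicted_yield = evaluate_effect_function(ternary_fit,
                                                            point_doses),
                 quantile_rule = quantile_rule, level = level,
                 interval = interval),
            class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat("frequency-analysis dose recommendation (interval ")
  print(x$interval)
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %.2f g/plant (sd %.2f, se %.2f, %d%% CI %.2f-%.2f, n = %d)\n",
                s$factor[i], s$mean[i], s$sd[i], s$se[i],
                round(100 * x$level), s$ci_lower[i], s$ci_upper[i],
                s$total[i]))
  }
  cat(sprintf("point doses (g/plant): N = %.2f, P2O5 = %.2f, K2O = %.2f\n",
              x$point_doses[["N"]], x$point_doses[["P"]],
              x$point_doses[["K"]]))
  cat(sprintf("predicted yield at point doses: %.2f g/plant\n",
              x$predicted_yield))
  invisible(x)
}
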