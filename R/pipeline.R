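#' Pipeline configuration
#'
#' Bundles the knobs of [run_full_analysis()] into a validated list.
#' Unknown keys are rejected.
#'
#' @param level2 named level-2 dose triple (g/plant).
#' @param prices a [price_schedule()].
#' @param interval a [yield_interval()] for the frequency analysis.
#' @param quantile_rule `"normal"` or `"t"` for the recommendation CIs.
#' @param fit_treatments named list of treatment index vectors per fit
#'   (names among N, P, K, NP, NK, PK, NPK); defaults to the canonical
#'   honeysuckle subsets.
#' @param point_doses optional point-dose override for the final
#'   recommendation.
#' @param seed integer seed recorded in the run log (and used by any
#'   simulation stage).
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(level2 = c(N = 30, P = 10, K = 16),
                            prices = lonicera_prices(),
                            interval = yield_interval(296, 413),
                            quantile_rule = c("normal", "t"),
                            fit_treatments = lonicera_fit_treatments(),
                            point_doses = NULL,
                            seed = 1L) {
  quantile_rule <- match.arg(quantile_rule)
  stopifnot(inherits(prices, "price_schedule"),
            inherits(interval, "yield_interval"))
  allowed <- c("N", "P", "K", "NP", "NK", "PK", "NPK")
  bad <- setdiff(names(fit_treatments), allowed)
  if (length(bad)) {
    stop("unknown fit names in fit_treatments: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(level2 = level2, prices = prices, interval = interval,
                 quantile_rule = quantile_rule,
                 fit_treatments = fit_treatments,
                 point_doses = point_doses, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys: `level2` (N/P/K), `prices` (crop_price_cny_kg,
#' n_price_cny_kg, p2o5_price_cny_kg, k2o_price_cny_kg, usd_per_cny),
#' `interval` (lower, upper, lower_inclusive, upper_inclusive),
#' `quantile_rule`, `point_doses` (N/P/K), `seed`. Unknown keys are an
#' error.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  allowed <- c("level2", "prices", "interval", "quantile_rule",
               "point_doses", "seed")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  args <- list()
  if (!is.null(raw$level2)) args$level2 <- unlist(raw$level2)
  if (!is.null(raw$prices)) {
    p <- raw$prices
    args$prices <- price_schedule(
      crop_price = p$crop_price_cny_kg,
      nutrient_prices = c(N = p$n_price_cny_kg, P = p$p2o5_price_cny_kg,
                          K = p$k2o_price_cny_kg),
      usd_per_cny = p$usd_per_cny)
  }
  if (!is.null(raw$interval)) {
    iv <- raw$interval
    args$interval <- yield_interval(
      iv$lower, iv$upper,
      lower_inclusive = !isFALSE(iv$lower_inclusive),
      upper_inclusive = !isFALSE(iv$upper_inclusive))
  }
  if (!is.null(raw$quantile_rule)) args$quantile_rule <- raw$quantile_rule
  if (!is.null(raw$point_doses)) args$point_doses <- unlist(raw$point_doses)
  if (!is.null(raw$seed)) args$seed <- raw$seed
  do.call(pipeline_config, args)
}

#' Run the full '3414' analysis pipeline
#'
#' Executes, in order: the nutrient-abundance report, the pairwise
#' combination gain ranking, the economic report, all configured effect
#' function fits with their typicality verdicts and stationary points,
#' the marginal-derivative economic optimum (only when the ternary fit is
#' typical; otherwise the refusal is recorded and frequency analysis is
#' the recommendation route), and the frequency-analysis dose
#' recommendation. Every artifact is written as CSV or JSON under
#' `out_dir` together with a run log recording the configuration, seed
#' and package version.
#'
#' @param trial a [trial_data()] object.
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed; `NULL` skips
#'   writing and just returns the results.
#' @return invisible list with elements `abundance`, `combinations`,
#'   `economics`, `fits`, `typicality`, `stationary`, `marginal_optimum`
#'   (or `NULL` with `marginal_refusal` message), `recommendation`.
#' @examples
#' res <- run_full_analysis(lonicera_trial(), pipeline_config())
#' res$recommendation$summary
#' @export
run_full_analysis <- function(trial, config = pipeline_config(),
                              out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()
  res$abundance <- stage("abundance", abundance_report(trial))
  res$combinations <- stage("combinations", combination_gain_ranking(trial))
  res$economics <- stage("economics",
                         economic_report(trial, config$prices))
  res$fits <- stage("fits", {
    fits <- list()
    for (nm in names(config$fit_treatments)) {
      factors <- unique(strsplit(nm, "")[[1L]])
      fits[[nm]] <- fit_effect_function(trial, factors = factors,
                                        treatments =
                                          config$fit_treatments[[nm]])
    }
    fits
  })
  res$typicality <- lapply(res$fits, classify_typicality)
  res$stationary <- stage("stationary", lapply(res$fits, function(f) {
    tryCatch(stationary_point(f), error = function(e) NULL)
  }))
  tern <- res$fits$NPK
  if (!is.null(tern) && classify_typicality(tern)$is_typical) {
    res$marginal_optimum <- stage("marginal_optimum",
                                  marginal_optimum(tern, config$prices))
    res["marginal_refusal"] <- list(NULL)
  } else {
    res["marginal_optimum"] <- list(NULL)
    res$marginal_refusal <- paste(
      "ternary fit is atypical: marginal-derivative optimum refused;",
      "frequency analysis used for the recommendation")
  }
  res$recommendation <- stage("recommendation", {
    fit_for_pred <- if (!is.null(tern)) tern else
      fit_effect_function(trial, factors = fert_factors())
    recommend_doses(trial, config$interval, fit_for_pred,
                    quantile_rule = config$quantile_rule,
                    point_doses = config$point_doses)
  })
  if (!is.null(out_dir)) {
    write_report_bundle(res, trial, config, out_dir)
  }
  invisible(res)
}

# Serialize the pipeline results as CSV/JSON artifacts plus a run log.
write_report_bundle <- function(res, trial, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  w(res$abundance, "abundance.csv")
  w(res$combinations, "combination_gains.csv")
  w(res$economics, "economics.csv")
  coef_rows <- do.call(rbind, lapply(names(res$fits), function(nm) {
    cf <- coef.effect_function(res$fits[[nm]])
    data.frame(fit = nm, term = names(cf), estimate = unname(cf),
               stringsAsFactors = FALSE)
  }))
  w(coef_rows, "effect_coefficients.csv")
  fit_report <- lapply(res$fits, function(f) {
    sp <- tryCatch(stationary_point(f), error = function(e) NULL)
    list(coefficients = as.list(coef.effect_function(f)),
         r_squared = f$r_squared, f_statistic = f$f_statistic,
         p_value = f$p_value, n_points = f$n_points,
         typical = classify_typicality(f)$is_typical,
         stationary = if (!is.null(sp))
           list(doses = as.list(sp$doses),
                predicted_yield = sp$predicted_yield,
                nature = sp$nature))
  })
  jsonlite::write_json(fit_report, file.path(out_dir, "effect_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rec <- res$recommendation
  w(rec$summary, "recommendation.csv")
  jsonlite::write_json(
    list(interval = list(lower = rec$interval$lower,
                         upper = rec$interval$upper,
                         lower_inclusive = rec$interval$lower_inclusive,
                         upper_inclusive = rec$interval$upper_inclusive),
         quantile_rule = rec$quantile_rule,
         point_doses = as.list(rec$point_doses),
         predicted_yield = rec$predicted_yield,
         marginal_refusal = res$marginal_refusal),
    file.path(out_dir, "recommendation.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    paste("fert3414 version:",
          as.character(utils::packageVersion("fert3414"))),
    paste("timestamp:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste("seed:", config$seed),
    paste("quantile_rule:", config$quantile_rule),
    paste("interval:", config$interval$lower, "-", config$interval$upper),
    paste("plots:", nrow(trial$plots)),
    paste("treatments:", nrow(trial$means))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
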