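#' Price schedule for economic evaluation
#'
#' @param crop_price crop price (currency per kg fresh buds), > 0.
#' @param nutrient_prices named vector of fertilizer prices (currency per
#'   kg) for N, P (as P2O5) and K (as K2O); nonnegative.
#' @param usd_per_cny optional exchange fraction used for USD views.
#' @return a `price_schedule` object.
#' @export
price_schedule <- function(crop_price,
                           nutrient_prices = c(N = 4.8, P = 6, K = 8),
                           usd_per_cny = NULL) {
  stopifnot(is.numeric(crop_price), length(crop_price) == 1L,
            crop_price > 0)
  if (is.null(names(nutrient_prices)) ||
      !setequal(names(nutrient_prices), fert_factors())) {
    stop("nutrient_prices must be named N, P, K", call. = FALSE)
  }
  nutrient_prices <- nutrient_prices[fert_factors()]
  if (any(nutrient_prices < 0)) {
    stop("nutrient prices must be nonnegative", call. = FALSE)
  }
  if (!is.null(usd_per_cny)) stopifnot(usd_per_cny > 0)
  structure(list(crop_price = crop_price,
                 nutrient_prices = nutrient_prices,
                 usd_per_cny = usd_per_cny),
            class = "price_schedule")
}

#' Relative yield of an omission treatment
#'
#' The mean yield of a nutrient-omission treatment as a fraction of the
#' full-fertilizer reference mean; the standard abundance index of the
#' soil's supply of that nutrient.
#'
#' @param omission_mean mean yield of the omission treatment (g/plant).
#' @param reference_mean mean yield of the full-fertilizer treatment
#'   (g/plant), > 0.
#' @return relative yield as a fraction.
#' @examples
#' relative_yield(295.77, 399.83)
#' @export
relative_yield <- function(omission_mean, reference_mean) {
  if (any(reference_mean <= 0)) {
    stop("reference mean must be positive", call. = FALSE)
  }
  omission_mean / reference_mean
}

#' Classify soil nutrient abundance from relative yield
#'
#' Fixed thresholds: below 50% extremely low, 50-75% low, 75-95% medium,
#' 95% and above high. Bins are lower-inclusive, so every nonnegative
#' relative yield falls in exactly one class.
#'
#' @param ry relative yield as a fraction (0.787 for 78.7%).
#' @return character vector of class labels among `"extremely_low"`,
#'   `"low"`, `"medium"`, `"high"`.
#' @export
classify_abundance <- function(ry) {
  if (any(ry < 0)) stop("relative yield must be nonnegative", call. = FALSE)
  cut(ry, breaks = c(-Inf, 0.5, 0.75, 0.95, Inf), right = FALSE,
      labels = c("extremely_low", "low", "medium", "high")) |>
    as.character()
}

#' Yield gain per gram of nutrient
#'
#' (full-fertilizer mean - omission mean) / level-2 dose of the omitted
#' nutrient: the average fresh-bud mass gained per gram of fertilizer
#' within the tested range.
#'
#' @param full_mean full-fertilizer mean yield (g/plant).
#' @param omission_mean omission-treatment mean yield (g/plant).
#' @param dose dose of the omitted nutrient in the full treatment
#'   (g/plant), > 0.
#' @return g yield per g nutrient.
#' @export
per_gram_gain <- function(full_mean, omission_mean, dose) {
  if (any(dose <= 0)) stop("dose must be positive", call. = FALSE)
  (full_mean - omission_mean) / dose
}

#' Nutrient abundance report
#'
#' For the unfertilized control and each single-nutrient omission
#' treatment, the relative yield against the full-fertilizer reference,
#' its abundance class, and the per-gram yield gain of the omitted
#' nutrient.
#'
#' @param trial a [trial_data()] object.
#' @param reference full-fertilizer treatment code (all factors level 2).
#' @return data frame with one row per treatment (control first).
#' @examples
#' abundance_report(lonicera_trial())
#' @export
abundance_report <- function(trial, reference = "N2P2K2") {
  design <- trial$design
  ref_row <- design_row(design, reference)
  ref_mean <- unname(treatment_means(trial, ref_row$treatment))
  ctrl <- design$treatment[design$n_level == 0 & design$p_level == 0 &
                             design$k_level == 0]
  if (!length(ctrl)) {
    stop("control treatment (all levels 0) missing from design",
         call. = FALSE)
  }
  omis <- c(
    N = design$treatment[design$n_level == 0 & design$p_level == 2 &
                           design$k_level == 2][1L],
    P = design$treatment[design$n_level == 2 & design$p_level == 0 &
                           design$k_level == 2][1L],
    K = design$treatment[design$n_level == 2 & design$p_level == 2 &
                           design$k_level == 0][1L]
  )
  if (anyNA(omis)) {
    stop("omission treatment missing for factor: ",
         paste(names(omis)[is.na(omis)], collapse = ", "), call. = FALSE)
  }
  ref_doses <- design_doses(design, ref_row$treatment)
  rows <- lapply(c(control = ctrl[1L], omis), function(code) {
    m <- unname(treatment_means(trial, code))
    data.frame(treatment = code, mean_yield = m,
               relative_yield_pct = 100 * relative_yield(m, ref_mean),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$omitted_factor <- c(NA, names(omis))
  out$abundance_class <- classify_abundance(out$relative_yield_pct / 100)
  out$per_gram_gain <- c(NA, vapply(names(omis), function(f) {
    per_gram_gain(ref_mean, out$mean_yield[out$treatment == omis[[f]]],
                  ref_doses[[f]])
  }, numeric(1)))
  rownames(out) <- NULL
  out
}

#' Pairwise-combination yield gain ranking
#'
#' For each nutrient pair, the yield gain over the unfertilized control of
#' the treatment supplying exactly that pair at level 2 (the third
#' nutrient omitted), sorted descending; ties keep the fixed order PK,
#' NP, NK.
#'
#' @param trial a [trial_data()] object.
#' @return data frame with columns `pair`, `treatment`, `gain_pct`.
#' @examples
#' combination_gain_ranking(lonicera_trial())
#' @export
combination_gain_ranking <- function(trial) {
  design <- trial$design
  find <- function(n, p, k) {
    code <- design$treatment[design$n_level == n & design$p_level == p &
                               design$k_level == k]
    if (!length(code)) {
      stop("treatment with levels N", n, "P", p, "K", k,
           " missing from trial", call. = FALSE)
    }
    code[1L]
  }
  ctrl_mean <- unname(treatment_means(trial, find(0, 0, 0)))
  pairs <- data.frame(
    pair = c("PK", "NP", "NK"),
    treatment = c(find(0, 2, 2), find(2, 2, 0), find(2, 0, 2)),
    stringsAsFactors = FALSE
  )
  pairs$gain_pct <- vapply(pairs$treatment, function(code) {
    100 * yield_increase_pct(unname(treatment_means(trial, code)), ctrl_mean)
  }, numeric(1))
  pairs[order(-pairs$gain_pct), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

#' Output value of a plant's yield
#'
#' yield (g) x crop price (per kg) / 1000.
#'
#' @param mean_yield mean yield (g/plant), >= 0.
#' @param prices a [price_schedule()].
#' @return currency per plant.
#' @export
output_value <- function(mean_yield, prices) {
  if (any(mean_yield < 0)) stop("yield must be nonnegative", call. = FALSE)
  mean_yield * prices$crop_price / 1000
}

#' Fertilizer cost of a dose triple
#'
#' Sum over nutrients of dose (g) x price (per kg) / 1000.
#'
#' @param doses numeric triple of doses (g/plant) for N, P2O5, K2O (named
#'   or in that order).
#' @param prices a [price_schedule()].
#' @return currency per plant.
#' @examples
#' fertilizer_cost(c(N = 30, P = 10, K = 16), lonicera_prices())
#' @export
fertilizer_cost <- function(doses, prices) {
  if (is.null(names(doses))) names(doses) <- fert_factors()
  doses <- doses[fert_factors()]
  if (any(doses < 0)) stop("doses must be nonnegative", call. = FALSE)
  sum(doses * prices$nutrient_prices) / 1000
}

#' Profit-to-investment ratio
#'
#' Output value divided by fertilizer cost; undefined for the zero-cost
#' control.
#'
#' @param output_value currency per plant.
#' @param cost fertilizer cost, currency per plant, > 0.
#' @return unitless ratio.
#' @export
profit_to_investment <- function(output_value, cost) {
  if (any(cost <= 0)) {
    stop("ratio undefined: fertilizer cost must be positive", call. = FALSE)
  }
  output_value / cost
}

#' Yield increase over the control
#'
#' @param treatment_mean treatment mean yield (g/plant).
#' @param control_mean control mean yield (g/plant), > 0.
#' @return fractional increase (0.3818 for 38.18%).
#' @export
yield_increase_pct <- function(treatment_mean, control_mean) {
  if (any(control_mean <= 0)) {
    stop("control mean must be positive", call. = FALSE)
  }
  (treatment_mean - control_mean) / control_mean
}

#' Gross USD gain over the control
#'
#' (treatment mean - control mean) x USD crop price / 1000; the gross
#' output-value gain without cost subtraction.
#'
#' @param treatment_mean treatment mean yield (g/plant).
#' @param control_mean control mean yield (g/plant).
#' @param usd_crop_price crop price in USD per kg, > 0.
#' @return USD per plant.
#' @export
usd_gain_vs_control <- function(treatment_mean, control_mean,
                                usd_crop_price) {
  if (any(usd_crop_price <= 0)) {
    stop("USD crop price must be positive", call. = FALSE)
  }
  (treatment_mean - control_mean) * usd_crop_price / 1000
}

#' Per-treatment economic report
#'
#' Output value, fertilizer cost, profit-to-investment ratio and gains
#' over the unfertilized control for every treatment, from the dose
#' schedule and a price schedule. The control's ratio is `NA` (zero
#' cost). Values are unrounded; round only for display.
#'
#' @param trial a [trial_data()] object.
#' @param prices a [price_schedule()]; if it carries `usd_per_cny`, a
#'   `usd_gain_vs_control` column is included.
#' @param control control treatment code.
#' @return data frame with one row per treatment, in design order.
#' @examples
#' head(economic_report(lonicera_trial(), lonicera_prices()))
#' @export
economic_report <- function(trial, prices, control = "N0P0K0") {
  design <- trial$design
  ctrl_mean <- unname(treatment_means(trial, control))
  means <- treatment_means(trial)
  codes <- design$treatment[design$treatment %in% names(means)]
  rows <- lapply(codes, function(code) {
    m <- unname(means[[code]])
    doses <- design_doses(design, code)
    cost <- fertilizer_cost(doses, prices)
    data.frame(
      treatment = code,
      mean_yield = m,
      output_value = output_value(m, prices),
      fertilizer_cost = cost,
      ratio = if (cost > 0) profit_to_investment(output_value(m, prices),
                                                 cost) else NA_real_,
      increase_vs_control_pct =
        if (code == control) NA_real_
        else 100 * yield_increase_pct(m, ctrl_mean),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(prices$usd_per_cny)) {
    usd_crop <- prices$crop_price * prices$usd_per_cny
    out$usd_gain_vs_control <- ifelse(
      out$treatment == control, NA_real_,
      usd_gain_vs_control(out$mean_yield, ctrl_mean, usd_crop))
  }
  rownames(out) <- NULL
  out
}
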