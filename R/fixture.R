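#' Canonical honeysuckle '3414' trial
#'
#' The packaged example data set: a '3414' NPK trial on 4-year-old
#' *Lonicera japonica* (honeysuckle) in the hilly-gully Loess Plateau,
#' level-2 doses 30 g N, 10 g P2O5 and 16 g K2O per plant, three replicate
#' plots per treatment, fresh-bud yield in g/plant.
#'
#' Two granularities are carried, mirroring how such trials are reported:
#' plot-level yields rounded to whole grams (used for frequency counting)
#' and treatment means at two decimals (used for regression and the
#' economic report). The rounded plot means can differ from the two-decimal
#' treatment means in the second decimal, so the object stores both and
#' [treatment_means()] returns the two-decimal values.
#'
#' @return a [trial_data()] object with 42 plots and 14 treatment means.
#' @examples
#' trial <- lonicera_trial()
#' treatment_means(trial)
#' @export
lonicera_trial <- function() {
  design <- build_3414_design(c(N = 30, P = 10, K = 16))
  reps <- matrix(c(
    297, 296, 295,
    337, 338, 340,
    386, 396, 387,
    313, 307, 325,
    376, 370, 390,
    391, 402, 407,
    406, 412, 408,
    324, 323, 322,
    370, 369, 378,
    395, 397, 394,
    407, 413, 405,
    364, 373, 366,
    390, 381, 390,
    359, 341, 360
  ), ncol = 3L, byrow = TRUE)
  plots <- data.frame(
    treatment = rep(design$treatment, each = 3L),
    replicate = rep(1:3, times = nrow(design)),
    yield = as.numeric(t(reps)),
    stringsAsFactors = FALSE
  )
  means <- data.frame(
    treatment = design$treatment,
    yield = c(295.77, 338.53, 389.70, 314.67, 378.50, 399.83, 408.70,
              322.73, 372.27, 395.27, 407.93, 367.80, 386.73, 353.40),
    stringsAsFactors = FALSE
  )
  trial_data(plots, design = design, means = means)
}

#' Price schedule of the honeysuckle trial
#'
#' Fresh buds at 24 CNY/kg; urea-N, P2O5 and K2O at 4.8, 6 and 8 CNY/kg.
#' The USD conversion (0.1376 USD/CNY) matches the quoted dollar prices
#' (3.3024 USD/kg crop, 0.6605/0.8256/1.1008 USD/kg nutrients).
#'
#' @return a [price_schedule()] object.
#' @export
lonicera_prices <- function() {
  price_schedule(crop_price = 24,
                 nutrient_prices = c(N = 4.8, P = 6, K = 8),
                 usd_per_cny = 0.1376)
}

#' Published fertilizer effect functions of the honeysuckle trial
#'
#' The quadratic effect functions reported for the canonical trial, as
#' printed (coefficients rounded to the reported precision), usable as
#' fixed inputs for evaluation and classification:
#' single-factor `N`, `P`, `K`; two-factor `NP`, `NK`, `PK`; and the
#' ternary `NPK` surface. Doses are in g/plant throughout.
#'
#' @return named list of [effect_function()] objects.
#' @examples
#' fns <- lonicera_effect_functions()
#' evaluate_effect_function(fns$NPK, c(N = 22.5, P = 7.5, K = 12))
#' @export
lonicera_effect_functions <- function() {
  list(
    N = effect_function(340.95, c(N = 3.60), c(N = -0.048)),
    P = effect_function(316.55, c(P = 14.31), c(P = -0.55)),
    K = effect_function(322.40, c(K = 8.11), c(K = -0.21)),
    NP = effect_function(303.10, c(N = 1.94, P = 9.72),
                         c(N = -0.051, P = -0.60), c("N:P" = 0.18)),
    NK = effect_function(382.48, c(N = -0.80, K = 1.35),
                         c(N = -0.042, K = -0.24), c("N:K" = 0.25)),
    PK = effect_function(260.41, c(P = 11.11, K = 7.36),
                         c(P = -0.50, K = -0.24), c("P:K" = 0.15)),
    NPK = effect_function(296.66, c(N = -0.81, P = 11.53, K = 4.05),
                          c(N = -0.051, P = -0.60, K = -0.28),
                          c("N:P" = 0.13, "N:K" = 0.20, "P:K" = -0.029))
  )
}

#' Treatment subsets used for the honeysuckle effect-function fits
#'
#' Row indices (Table-order treatment numbers) of the design used when
#' fitting each effect function: single-factor fits vary one nutrient with
#' the others held at level 2; two-factor fits pool the treatments varying
#' that pair.
#'
#' @return named list of integer vectors.
#' @export
lonicera_fit_treatments <- function() {
  list(
    N = c(2L, 3L, 6L, 11L),
    P = c(4L, 5L, 6L, 7L),
    K = c(6L, 8L, 9L, 10L),
    NP = c(2L, 3L, 4L, 5L, 6L, 7L, 11L, 12L),
    NK = c(2L, 3L, 6L, 8L, 9L, 10L, 11L, 13L),
    PK = c(4L, 5L, 6L, 7L, 8L, 9L, 10L, 14L),
    NPK = 1:14
  )
}
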