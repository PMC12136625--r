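#' Simulate a '3414' trial from a known response surface
#'
#' Generates plot-level yields as the surface value at each treatment's
#' doses plus independent zero-mean Gaussian plot noise. Noise draws use
#' one stream per plot, seeded deterministically from the root seed and
#' the (treatment, replicate) pair, so increasing `replicates` never
#' perturbs earlier draws. Yields are truncated at zero; the number of
#' truncations is recorded in the `"truncated"` attribute and warned
#' about.
#'
#' @param design a [build_3414_design()] object.
#' @param surface an [effect_function()] spanning N, P and K (the true
#'   surface).
#' @param sd plot-noise standard deviation (g/plant), >= 0.
#' @param replicates plots per treatment, >= 1.
#' @param seed root integer seed.
#' @return a [trial_data()] object (means computed from the simulated
#'   plots).
#' @examples
#' surf <- lonicera_effect_functions()$NPK
#' sim <- simulate_trial(build_3414_design(), surf, sd = 5, seed = 42)
#' @export
simulate_trial <- function(design, surface, sd = 5, replicates = 3,
                           seed = 1) {
  stopifnot(sd >= 0)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("replicates must be a positive integer", call. = FALSE)
  }
  if (!setequal(surface$factors, fert_factors())) {
    stop("surface must span factors N, P and K", call. = FALSE)
  }
  nT <- nrow(design)
  truth <- vapply(seq_len(nT), function(i) {
    evaluate_effect_function(surface, design_doses(design, i))
  }, numeric(1))
  idx_t <- rep(seq_len(nT), each = replicates)
  idx_r <- rep(seq_len(replicates), times = nT)
  eps <- if (sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    draws <- vapply(seq_along(idx_t), function(k) {
      set.seed(plot_seed(seed, idx_t[k], idx_r[k]))
      stats::rnorm(1L, 0, sd)
    }, numeric(1))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    draws
  } else {
    numeric(length(idx_t))
  }
  y <- truth[idx_t] + eps
  truncated <- sum(y < 0)
  y[y < 0] <- 0
  if (truncated > 0L) {
    warning(truncated, " simulated yield(s) truncated at zero",
            call. = FALSE)
  }
  plots <- data.frame(treatment = design$treatment[idx_t],
                      replicate = idx_r, yield = y,
                      stringsAsFactors = FALSE)
  out <- trial_data(plots, design = design)
  attr(out, "truncated") <- truncated
  out
}

# Deterministic per-plot seed derived from (root seed, treatment index,
# replicate index); kept inside 32-bit integer range.
plot_seed <- function(seed, i, r) {
  as.integer((as.double(seed) * 48271 + i * 6991 + r * 101) %% 2147483647)
}

#' Parameter-recovery study on simulated '3414' trials
#'
#' Repeatedly simulates a trial from a known ternary surface, refits the
#' ternary quadratic effect function on treatment means, and aggregates
#' per-coefficient bias and RMSE; also reports how often the typicality
#' classification of the refit matches that of the true surface.
#'
#' @param surface an [effect_function()] spanning N, P and K.
#' @param sd plot-noise standard deviation (g/plant).
#' @param replicates plots per treatment per simulated trial.
#' @param n_sims number of simulated trials, >= 1.
#' @param seed root seed; each simulation derives its own sub-seed.
#' @param level2 level-2 dose triple of the simulated design.
#' @return data frame with one row per coefficient (`term`, `true`,
#'   `bias`, `rmse`) and attribute `typicality_match` (fraction of
#'   simulations whose verdict equals the surface's).
#' @export
parameter_recovery_report <- function(surface, sd = 5, replicates = 3,
                                      n_sims = 200, seed = 1,
                                      level2 = c(N = 30, P = 10, K = 16)) {
  stopifnot(n_sims >= 1)
  design <- build_3414_design(level2)
  true_coef <- coef.effect_function(surface)
  true_typical <- classify_typicality(surface)$is_typical
  est <- matrix(NA_real_, nrow = n_sims, ncol = length(true_coef),
                dimnames = list(NULL, names(true_coef)))
  match_typ <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    sub_seed <- as.integer((as.double(seed) * 10007 + s) %% 2147483647)
    sim <- suppressWarnings(
      simulate_trial(design, surface, sd = sd, replicates = replicates,
                     seed = sub_seed))
    fit <- fit_effect_function(sim, factors = fert_factors())
    est[s, ] <- coef.effect_function(fit)
    match_typ[s] <- classify_typicality(fit)$is_typical == true_typical
  }
  err <- sweep(est, 2L, true_coef)
  out <- data.frame(term = names(true_coef), true = unname(true_coef),
                    bias = colMeans(err),
                    rmse = sqrt(colMeans(err^2)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "typicality_match") <- mean(match_typ)
  attr(out, "n_sims") <- n_sims
  out
}
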