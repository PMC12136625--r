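trial <- lonicera_trial()
fns <- lonicera_effect_functions()
subsets <- lonicera_fit_treatments()

test_that("single-factor refits on report means reproduce the published coefficients", {
  fp <- fit_effect_function(trial, "P", treatments = subsets$P)
  expect_equal(round(unname(fp$linear), 2), 14.31)
  expect_equal(round(unname(fp$quadratic), 2), -0.55)
  fk <- fit_effect_function(trial, "K", treatments = subsets$K)
  expect_equal(unname(fk$quadratic), -0.2113, tolerance = 1e-3)
  expect_equal(round(unname(fk$quadratic), 2), -0.21)
  fn <- fit_effect_function(trial, "N", treatments = subsets$N)
  expect_equal(round(unname(fn$quadratic), 3), -0.048)
  # dose-unit fitting: the ternary intercept sits near the control mean
  ftern <- fit_effect_function(trial)
  expect_lt(abs(ftern$intercept - 295.77), 10)
})

test_that("points on an exact quadratic are interpolated with r_squared 1", {
  x <- c(0, 5, 10, 15)
  y <- 100 + 2 * x - 0.1 * x^2
  tr <- trial_data(data.frame(treatment = c("N2P0K2", "N2P1K2", "N2P2K2",
                                            "N2P3K2"),
                              replicate = 1L, yield = y))
  f <- fit_effect_function(tr, "P", treatments = c("N2P0K2", "N2P1K2",
                                                   "N2P2K2", "N2P3K2"))
  expect_equal(f$intercept, 100, tolerance = 1e-8)
  expect_equal(unname(f$linear), 2, tolerance = 1e-8)
  expect_equal(unname(f$quadratic), -0.1, tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
})

test_that("every fixture fit matches the pseudoinverse oracle to 1e-8", {
  for (nm in names(subsets)) {
    factors <- unique(strsplit(nm, "")[[1L]])
    fit <- fit_effect_function(trial, factors, treatments = subsets[[nm]])
    X <- dose_matrix(trial, subsets[[nm]], factors)
    y <- unname(treatment_means(trial, subsets[[nm]]))
    expect_equal(unname(coef(fit)), oracle_quadratic_fit(X, y),
                 tolerance = 1e-8, info = nm)
  }
})

test_that("plot-level and mean-level fits agree on balanced trials", {
  balanced <- trial_data(trial$plots)  # means recomputed from plots
  for (nm in c("P", "NPK")) {
    factors <- unique(strsplit(nm, "")[[1L]])
    fm <- fit_effect_function(balanced, factors, treatments = subsets[[nm]],
                              data = "means")
    fp <- fit_effect_function(balanced, factors, treatments = subsets[[nm]],
                              data = "plots")
    expect_equal(coef(fm), coef(fp), tolerance = 1e-10)
  }
})

test_that("r_squared is invariant under affine rescaling of yield units", {
  f1 <- fit_effect_function(trial, "P", treatments = subsets$P)
  scaled <- trial
  scaled$means$yield <- 0.35 * scaled$means$yield + 12
  f2 <- fit_effect_function(scaled, "P", treatments = subsets$P)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
})

test_that("underdetermined and collinear fits raise rank diagnostics", {
  expect_error(fit_effect_function(trial, c("N", "P", "K"),
                                   treatments = subsets$P),
               "underdetermined")
  # one distinct dose cannot identify a quadratic
  tr <- trial_data(data.frame(treatment = "N2P2K2", replicate = 1:4,
                              yield = c(1, 2, 3, 4)))
  expect_error(fit_effect_function(tr, "P", treatments = "N2P2K2",
                                   data = "plots"),
               "collinear|rank")
})

test_that("effect functions evaluate the quadratic polynomial exactly", {
  expect_equal(round(evaluate_effect_function(fns$NPK, c(22.5, 7.5, 12)), 2),
               386.95)
  expect_equal(evaluate_effect_function(fns$NPK, c(0, 0, 0)), 296.66)
  expect_equal(evaluate_effect_function(fns$N, 37.5),
               340.95 + 3.60 * 37.5 - 0.048 * 37.5^2)
  expect_equal(evaluate_effect_function(fns$N, 37.5), 408.45)
  # named doses are reordered to the factor order
  expect_equal(evaluate_effect_function(fns$NPK, c(K = 12, N = 22.5, P = 7.5)),
               evaluate_effect_function(fns$NPK, c(22.5, 7.5, 12)))
  expect_error(evaluate_effect_function(fns$NPK, c(1, 2)), "3 dose")
})

test_that("stationary points solve the zero-gradient condition", {
  sp <- stationary_point(fit_effect_function(trial, "P",
                                             treatments = subsets$P))
  expect_equal(unname(sp$doses), 13, tolerance = 0.01)
  expect_equal(sp$nature, "maximum")
  spn <- stationary_point(fns$N)
  expect_equal(unname(spn$doses), 37.5)
  expect_equal(spn$predicted_yield, 408.45)
  # even pure quadratic: vertex at zero
  sp0 <- stationary_point(effect_function(50, c(P = 0), c(P = -0.3)))
  expect_equal(unname(sp0$doses), 0)
  expect_equal(sp0$nature, "maximum")
  expect_equal(sp0$predicted_yield, 50)
  # ternary surface: gradient vanishes at the solution
  sp3 <- stationary_point(fns$NPK)
  Q <- fert3414:::quadratic_matrix(fns$NPK)
  grad <- unname(fns$NPK$linear) + drop(2 * Q %*% sp3$doses)
  expect_lt(sqrt(sum(grad^2)), 1e-9)
  expect_error(stationary_point(effect_function(1, c(P = 2), c(P = 0))),
               "singular")
})

test_that("typicality follows the strict diminishing-returns sign rule", {
  v <- classify_typicality(fns$NPK)
  expect_false(v$is_typical)
  expect_equal(v$violations$term, "N")
  expect_equal(v$violations$observed, -0.81)
  expect_true(classify_typicality(fns$P)$is_typical)
  # zero coefficients violate the strict inequalities on every term
  z <- classify_typicality(effect_function(0, c(N = 0, P = 0, K = 0),
                                           c(N = 0, P = 0, K = 0),
                                           c("N:P" = 0, "N:K" = 0,
                                             "P:K" = 0)))
  expect_false(z$is_typical)
  expect_equal(nrow(z$violations), 6L)
})

test_that("marginal optimum equates marginal yield value with nutrient price", {
  flat <- price_schedule(crop_price = 1,
                         nutrient_prices = c(N = 1, P = 1, K = 1))
  f <- effect_function(100, c(P = 2), c(P = -0.1))
  mo <- marginal_optimum(f, flat)
  expect_equal(unname(mo$doses), 5)  # solves 2 - 0.2x = 1
  # zero fertilizer price: optimum coincides with the yield maximum
  free <- price_schedule(crop_price = 24,
                         nutrient_prices = c(N = 0, P = 0, K = 0))
  expect_equal(marginal_optimum(f, free)$doses, stationary_point(f)$doses)
  # atypical fits are refused
  expect_error(marginal_optimum(fns$NPK, lonicera_prices()),
               "typical.*frequency analysis")
  # economic dose is below the maximum-yield dose at positive prices
  for (b in c(1.5, 3, 8)) {
    g <- effect_function(100, c(K = b), c(K = -0.12))
    expect_lt(unname(marginal_optimum(g, flat)$doses),
              unname(stationary_point(g)$doses))
  }
})
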