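trial <- lonicera_trial()
iv <- yield_interval(296, 413)

test_that("plot-level counting reproduces the P and K frequency columns", {
  for (f in c("P", "K")) {
    tab <- count_frequencies(trial, iv, f)
    expect_equal(tab$count, c(5L, 9L, 24L, 3L), info = f)
    expect_equal(sum(tab$count), 41L)
    expect_equal(round(tab$rate_pct, 2), c(12.20, 21.95, 58.54, 7.32))
  }
  tabP <- count_frequencies(trial, iv, "P")
  expect_equal(tabP$dose, c(0, 5, 10, 15))
  tabK <- count_frequencies(trial, iv, "K")
  expect_equal(tabK$dose, c(0, 8, 16, 24))
  expect_error(count_frequencies(trial, iv, "Q"), "unknown factor")
})

test_that("interval closure matters and empty intervals count nothing", {
  degenerate <- yield_interval(350, 350, lower_inclusive = FALSE,
                               upper_inclusive = FALSE)
  expect_equal(count_frequencies(trial, degenerate, "P")$count,
               rep(0L, 4L))
  # the 413 plot is counted only under an inclusive upper bound
  open_up <- yield_interval(296, 413, upper_inclusive = FALSE)
  expect_equal(sum(count_frequencies(trial, open_up, "P")$count), 40L)
})

test_that("counts grow monotonically with the interval", {
  set.seed(42)
  for (i in 1:20) {
    lo <- runif(1, 280, 380); hi <- runif(1, lo, 420)
    inner <- count_frequencies(trial, yield_interval(lo, hi), "K")$count
    outer <- count_frequencies(trial, yield_interval(lo - 10, hi + 10),
                               "K")$count
    expect_true(all(outer >= inner))
  }
})

test_that("weighted dose statistics follow the frequency formulas", {
  tabP <- count_frequencies(trial, iv, "P")
  tabK <- count_frequencies(trial, iv, "K")
  expect_equal(freq_weighted_mean(tabP), 330 / 41)  # 8.05 g/plant
  expect_equal(freq_weighted_mean(tabK), 528 / 41)  # 12.88 g/plant
  # direct-summation oracle for the sd
  sd_oracle <- function(dose, n, m) {
    sqrt(sum(n * (dose - m)^2) / (sum(n) - 1))
  }
  mK <- freq_weighted_mean(tabK)
  expect_equal(freq_weighted_sd(tabK), sd_oracle(tabK$dose, tabK$count, mK))
  expect_equal(round(freq_weighted_sd(tabK), 2), 6.42)
  # published mean pushed through the sd formula verbatim
  expect_equal(round(freq_weighted_sd(tabP, mean = 7.5), 2), 4.05)
  # mass on one level: mean is that dose, sd is zero
  one <- tabP
  one$count <- c(0L, 0L, 7L, 0L)
  expect_equal(freq_weighted_mean(one), 10)
  expect_equal(freq_weighted_sd(one), 0)
  # weighted mean stays inside the dose range
  set.seed(7)
  for (i in 1:25) {
    rnd <- tabP
    rnd$count <- rpois(4, 5)
    if (sum(rnd$count) >= 1) {
      m <- freq_weighted_mean(rnd)
      expect_gte(m, min(rnd$dose)); expect_lte(m, max(rnd$dose))
    }
  }
  none <- tabP
  none$count <- rep(0L, 4L)
  expect_error(freq_weighted_mean(none), "undefined")
  lone <- tabP
  lone$count <- c(0L, 0L, 1L, 0L)
  expect_error(freq_weighted_sd(lone), "at least two")
})

test_that("standard errors and confidence intervals match the published chain", {
  expect_equal(round(standard_error(13.17, 37), 2), 2.17)
  expect_equal(round(standard_error(4.05, 41), 2), 0.63)
  expect_equal(round(standard_error(6.40, 41), 2), 1.00)
  expect_equal(standard_error(0, 12), 0)
  ciK <- confidence_interval(12, 6.40, 41, "normal")
  expect_equal(round(unname(ciK), 2), c(10.04, 13.96))
  ciN <- confidence_interval(22.5, 13.17, 37, "normal")
  expect_true(all(abs(unname(ciN) - c(18.25, 26.75)) <= 0.01))
  ciP <- confidence_interval(7.5, 4.05, 41, "normal")
  expect_true(all(abs(unname(ciP) - c(6.27, 8.73)) <= 0.01))
  # zero sd collapses the interval
  expect_equal(unname(confidence_interval(9, 0, 10)), c(9, 9))
  # width scales as 1/sqrt(total)
  w <- function(n) unname(diff(confidence_interval(10, 4, n, "normal")))
  expect_equal(w(10) / w(40), 2, tolerance = 1e-12)
  # Student-t is wider than normal at finite n
  expect_gt(diff(confidence_interval(10, 4, 20, "t")),
            diff(confidence_interval(10, 4, 20, "normal")))
})

test_that("recommend_doses chains counting to a predicted optimized yield", {
  fit <- lonicera_effect_functions()$NPK
  rec <- recommend_doses(trial, iv, fit,
                         point_doses = c(N = 22.5, P = 7.5, K = 12))
  expect_equal(round(rec$predicted_yield, 2), 386.95)
  expect_equal(rec$summary$factor, c("N", "P", "K"))
  expect_equal(rec$summary$total, c(41L, 41L, 41L))
  # default point doses are the weighted means
  rec2 <- recommend_doses(trial, iv, fit)
  expect_equal(unname(rec2$point_doses),
               rec2$summary$mean[match(c("N", "P", "K"),
                                       rec2$summary$factor)])
  # an all-covering interval on a trial restricted to one K level
  sub <- trial_data(trial$plots[trial$plots$treatment %in%
                                  c("N0P2K2", "N1P2K2", "N2P2K2"), ])
  wide <- yield_interval(0, 1e6)
  tabK <- count_frequencies(sub, wide, "K")
  expect_equal(freq_weighted_mean(tabK), 16)
  expect_equal(freq_weighted_sd(tabK), 0)
})

test_that("recommended ranges track the optimum of a known surface", {
  surf <- effect_function(300, c(N = 3, P = 10, K = 6.4),
                          c(N = -0.05, P = -0.5, K = -0.2),
                          c("N:P" = 0, "N:K" = 0, "P:K" = 0))
  vertex <- stationary_point(surf)$doses  # (30, 10, 16)
  design <- build_3414_design()
  lvl2 <- attr(design, "level2")
  n_rep <- 200L
  ok <- matrix(NA, n_rep, 3, dimnames = list(NULL, c("N", "P", "K")))
  for (s in seq_len(n_rep)) {
    sim <- simulate_trial(design, surf, sd = 5, replicates = 3,
                          seed = 5000 + s)
    top <- yield_interval(stats::median(sim$plots$yield),
                          max(sim$plots$yield))
    rec <- recommend_doses(sim, top, surf)
    for (f in c("N", "P", "K")) {
      # optimum region: between the design doses flanking the vertex
      lo <- 0.5 * lvl2[[f]]; hi <- 1.5 * lvl2[[f]]
      r <- rec$summary[rec$summary$factor == f, ]
      ok[s, f] <- r$ci_lower <= hi && r$ci_upper >= lo &&
        rec$point_doses[[f]] >= lo && rec$point_doses[[f]] <= hi
    }
  }
  expect_true(all(colMeans(ok) >= 0.9))
})
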