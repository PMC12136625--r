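#' Construct a quadratic fertilizer effect function
#'
#' A fertilizer effect function relates nutrient doses x (g/plant) to
#' yield Y (g/plant) through a quadratic polynomial with pairwise
#' interactions:
#'
#'   Y = b0 + sum_i b_i x_i + sum_i b_ii x_i^2 + sum_{i<j} b_ij x_i x_j
#'
#' @param intercept b0, yield at zero dose (g/plant).
#' @param linear named vector of linear coefficients, one per factor
#'   (names from N, P, K; order defines the factor order).
#' @param quadratic named vector of pure quadratic coefficients, same
#'   names as `linear`.
#' @param interactions named vector of interaction coefficients for each
#'   unordered factor pair, names like `"N:P"`; required (and only
#'   allowed) when there are two or more factors.
#' @return an `effect_function` object.
#' @examples
#' effect_function(100, c(P = 2), c(P = -0.1))
#' @export
effect_function <- function(intercept, linear, quadratic,
                            interactions = NULL) {
  factors <- names(linear)
  if (is.null(factors) || !all(factors %in% fert_factors())) {
    stop("linear coefficients must be named with factors among N, P, K",
         call. = FALSE)
  }
  if (!identical(sort(names(quadratic)), sort(factors))) {
    stop("quadratic coefficients must cover the same factors as linear",
         call. = FALSE)
  }
  quadratic <- quadratic[factors]
  k <- length(factors)
  pairs <- interaction_names(factors)
  if (k >= 2L) {
    if (is.null(interactions) ||
        !identical(sort(names(interactions)), sort(pairs))) {
      stop("interactions must be named: ", paste(pairs, collapse = ", "),
           call. = FALSE)
    }
    interactions <- interactions[pairs]
  } else {
    interactions <- stats::setNames(numeric(0), character(0))
  }
  coefs <- c(intercept, linear, quadratic, interactions)
  if (any(!is.finite(coefs))) {
    stop("all coefficients must be finite", call. = FALSE)
  }
  structure(list(factors = factors, intercept = unname(intercept),
                 linear = linear, quadratic = quadratic,
                 interactions = interactions),
            class = "effect_function")
}

interaction_names <- function(factors) {
  k <- length(factors)
  if (k < 2L) return(character(0))
  cmb <- utils::combn(factors, 2L)
  paste(cmb[1L, ], cmb[2L, ], sep = ":")
}

#' @export
print.effect_function <- function(x, digits = 4, ...) {
  term <- function(b, sym) {
    sprintf("%s %s%s", ifelse(b < 0, "-", "+"),
            format(abs(b), digits = digits), sym)
  }
  parts <- c(format(x$intercept, digits = digits),
             mapply(term, x$linear, x$factors),
             mapply(term, x$quadratic, paste0(x$factors, "^2")),
             if (length(x$interactions))
               mapply(term, x$interactions,
                      gsub(":", "*", names(x$interactions))))
  cat("Y =", paste(parts, collapse = " "), " (doses g/plant)\n")
  if (inherits(x, "effect_fit")) {
    cat(sprintf("fit on %d points: R^2 = %.4f, F(%d,%d) = %.2f, p = %.4f\n",
                x$n_points, x$r_squared, x$df[1L], x$df[2L],
                x$f_statistic, x$p_value))
  }
  invisible(x)
}

#' @export
coef.effect_function <- function(object, ...) {
  c(intercept = object$intercept,
    stats::setNames(object$linear, object$factors),
    stats::setNames(object$quadratic, paste0(object$factors, "^2")),
    object$interactions)
}

#' Fit a quadratic fertilizer effect function by least squares
#'
#' Regresses yield on dose polynomials (doses in g/plant, not coded
#' levels) over a chosen subset of factors and treatments. The default
#' fits treatment means; plot-level fitting is available and, on balanced
#' trials, yields the same coefficients.
#'
#' @param trial a [trial_data()] object.
#' @param factors subset of `c("N", "P", "K")` entering the polynomial.
#' @param treatments treatment codes or design row indices to fit on;
#'   `NULL` uses every treatment.
#' @param data `"means"` (default) to fit treatment-mean yields, or
#'   `"plots"` to fit individual replicate plots.
#' @return an `effect_fit` (subclass of [effect_function()]) with
#'   elements `r_squared`, `f_statistic`, `p_value`, `df`, `n_points`,
#'   `residuals` and `fitted` in addition to the coefficients.
#' @examples
#' fit <- fit_effect_function(lonicera_trial(), "P", treatments = 4:7)
#' coef(fit)
#' @export
fit_effect_function <- function(trial, factors = c("N", "P", "K"),
                                treatments = NULL,
                                data = c("means", "plots")) {
  data <- match.arg(data)
  factors <- match.arg(factors, fert_factors(), several.ok = TRUE)
  design <- trial$design
  if (is.null(treatments)) treatments <- design$treatment
  rows <- design_row(design, treatments)
  if (data == "means") {
    y <- unname(treatment_means(trial, rows$treatment))
    codes <- rows$treatment
  } else {
    keep <- trial$plots$treatment %in% rows$treatment
    y <- trial$plots$yield[keep]
    codes <- trial$plots$treatment[keep]
  }
  dose_cols <- c(N = "n_dose", P = "p_dose", K = "k_dose")
  X <- sapply(factors, function(f) {
    design[[dose_cols[[f]]]][match(codes, design$treatment)]
  })
  X <- matrix(X, ncol = length(factors),
              dimnames = list(NULL, factors))
  M <- effect_model_matrix(X, factors)
  n <- length(y)
  p <- ncol(M)
  if (n < p) {
    stop("underdetermined fit: ", p, " coefficients but only ", n,
         " points (need ", p - n, " more)", call. = FALSE)
  }
  qrM <- qr(M)
  if (qrM$rank < p) {
    stop("rank-deficient design: dose columns are collinear (rank ",
         qrM$rank, " < ", p, " coefficients)", call. = FALSE)
  }
  fit <- stats::lm.fit(M, y)
  beta <- fit$coefficients
  fitted <- drop(M %*% beta)
  resid <- y - fitted
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  df1 <- p - 1L
  df2 <- n - p
  fstat <- if (df2 > 0 && ss_res > 0) {
    ((ss_tot - ss_res) / df1) / (ss_res / df2)
  } else {
    Inf
  }
  pval <- if (is.finite(fstat)) stats::pf(fstat, df1, df2,
                                          lower.tail = FALSE) else 0
  k <- length(factors)
  pairs <- interaction_names(factors)
  obj <- effect_function(
    intercept = beta[1L],
    linear = stats::setNames(beta[1L + seq_len(k)], factors),
    quadratic = stats::setNames(beta[1L + k + seq_len(k)], factors),
    interactions = if (k >= 2L)
      stats::setNames(beta[1L + 2L * k + seq_along(pairs)], pairs)
  )
  obj$r_squared <- r2
  obj$f_statistic <- fstat
  obj$p_value <- pval
  obj$df <- c(df1, df2)
  obj$n_points <- n
  obj$residuals <- resid
  obj$fitted <- fitted
  obj$data <- data
  obj$treatments <- rows$treatment
  class(obj) <- c("effect_fit", class(obj))
  obj
}

# Polynomial model matrix: intercept, linear, squares, pairwise products.
effect_model_matrix <- function(X, factors) {
  k <- length(factors)
  cols <- list(`(Intercept)` = rep(1, nrow(X)))
  for (f in factors) cols[[f]] <- X[, f]
  for (f in factors) cols[[paste0(f, "^2")]] <- X[, f]^2
  if (k >= 2L) {
    cmb <- utils::combn(factors, 2L)
    for (j in seq_len(ncol(cmb))) {
      cols[[paste(cmb[, j], collapse = ":")]] <- X[, cmb[1L, j]] * X[, cmb[2L, j]]
    }
  }
  do.call(cbind, cols)
}

#' Evaluate a fertilizer effect function
#'
#' @param fit an [effect_function()] or `effect_fit`.
#' @param doses numeric vector of doses (g/plant), one per fitted factor;
#'   if named, reordered to match the fit's factor order.
#' @return predicted yield (g/plant).
#' @examples
#' f <- lonicera_effect_functions()$NPK
#' evaluate_effect_function(f, c(22.5, 7.5, 12))
#' @export
evaluate_effect_function <- function(fit, doses) {
  k <- length(fit$factors)
  if (length(doses) != k) {
    stop("expected ", k, " dose(s) for factors ",
         paste(fit$factors, collapse = ", "), ", got ", length(doses),
         call. = FALSE)
  }
  if (!is.null(names(doses))) {
    if (!setequal(names(doses), fit$factors)) {
      stop("dose names must be: ", paste(fit$factors, collapse = ", "),
           call. = FALSE)
    }
    doses <- doses[fit$factors]
  }
  doses <- unname(doses)
  y <- fit$intercept + sum(fit$linear * doses) + sum(fit$quadratic * doses^2)
  if (k >= 2L) {
    cmb <- utils::combn(seq_len(k), 2L)
    y <- y + sum(fit$interactions * doses[cmb[1L, ]] * doses[cmb[2L, ]])
  }
  unname(y)
}

#' @export
predict.effect_function <- function(object, doses, ...) {
  evaluate_effect_function(object, doses)
}

# Symmetric quadratic-form matrix Q with Y = b0 + b'x + x'Qx.
quadratic_matrix <- function(fit) {
  k <- length(fit$factors)
  Q <- diag(fit$quadratic, k, k)
  dimnames(Q) <- list(fit$factors, fit$factors)
  if (k >= 2L) {
    cmb <- utils::combn(seq_len(k), 2L)
    for (j in seq_len(ncol(cmb))) {
      Q[cmb[1L, j], cmb[2L, j]] <- Q[cmb[2L, j], cmb[1L, j]] <-
        fit$interactions[j] / 2
    }
  }
  Q
}

#' Stationary point of a fitted effect function
#'
#' Solves the zero-gradient condition of the quadratic surface. For a
#' single factor the stationary dose is -b / (2 b_ii); in general it is
#' the solution of 2 Q x = -b. The nature of the point follows from the
#' definiteness of the quadratic-term matrix Q (negative definite:
#' maximum — the maximum-yield dose combination).
#'
#' @param fit an [effect_function()].
#' @param tol relative singularity tolerance for the quadratic matrix.
#' @return a `stationary_point`: list with `doses` (g/plant,
#'   named), `predicted_yield` (g/plant) and `nature` (`"maximum"`,
#'   `"minimum"` or `"saddle"`).
#' @examples
#' stationary_point(lonicera_effect_functions()$P)
#' @export
stationary_point <- function(fit, tol = 1e-9) {
  Q <- quadratic_matrix(fit)
  b <- unname(fit$linear)
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (min(abs(ev)) <= tol * max(abs(ev), 1)) {
    stop("quadratic-term matrix is singular: no stationary point",
         call. = FALSE)
  }
  x <- drop(solve(2 * Q, -b))
  grad <- b + drop(2 * Q %*% x)
  stopifnot(sqrt(sum(grad^2)) <= 1e-9 * max(1, sqrt(sum(b^2))))
  nature <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum"
            else "saddle"
  structure(list(doses = stats::setNames(x, fit$factors),
                 predicted_yield = evaluate_effect_function(fit, x),
                 nature = nature),
            class = "stationary_point")
}

#' @export
print.stationary_point <- function(x, ...) {
  cat("stationary point (", x$nature, ")\n", sep = "")
  cat("doses (g/plant):",
      paste(names(x$doses), round(x$doses, 2), sep = " = ",
            collapse = ", "), "\n")
  cat("predicted yield:", round(x$predicted_yield, 2), "g/plant\n")
  invisible(x)
}

#' Classify an effect function against the law of diminishing returns
#'
#' A *typical* fertilizer effect function has every linear coefficient
#' strictly positive (more nutrient helps at low doses) and every pure
#' quadratic coefficient strictly negative (returns diminish). Only for
#' typical functions is the marginal-derivative economic optimum
#' meaningful; atypical fits call for frequency analysis instead.
#' Zero coefficients count as violations (strict inequalities).
#'
#' @param fit an [effect_function()].
#' @return a `typicality_verdict`: list with logical `is_typical` and a
#'   data frame `violations` (columns `term`, `expected_sign`,
#'   `observed`).
#' @examples
#' classify_typicality(lonicera_effect_functions()$NPK)
#' @export
classify_typicality <- function(fit) {
  v <- data.frame(term = character(0), expected_sign = character(0),
                  observed = numeric(0), stringsAsFactors = FALSE)
  for (f in fit$factors) {
    if (!(fit$linear[[f]] > 0)) {
      v <- rbind(v, data.frame(term = f, expected_sign = "positive",
                               observed = fit$linear[[f]]))
    }
    if (!(fit$quadratic[[f]] < 0)) {
      v <- rbind(v, data.frame(term = paste0(f, "^2"),
                               expected_sign = "negative",
                               observed = fit$quadratic[[f]]))
    }
  }
  structure(list(is_typical = nrow(v) == 0L, violations = v),
            class = "typicality_verdict")
}

#' @export
print.typicality_verdict <- function(x, ...) {
  if (x$is_typical) {
    cat("typical effect function (diminishing returns hold)\n")
  } else {
    cat("atypical effect function;", nrow(x$violations),
        "sign violation(s):\n")
    print.data.frame(x$violations, row.names = FALSE)
  }
  invisible(x)
}

#' Economic optimum dose by the marginal-derivative method
#'
#' Finds the doses at which the value of the marginal yield response of
#' each nutrient equals its unit price: dY/dx_i * crop_price =
#' nutrient_price_i. Only defined for typical effect functions with a
#' negative-definite quadratic matrix; for atypical fits the method is
#' refused and frequency analysis should be used instead.
#'
#' @param fit an [effect_function()].
#' @param prices a [price_schedule()]; nutrient and crop prices must share
#'   the same mass unit so their ratio is dimensionless per gram of dose.
#' @return a `stationary_point` whose `doses` are the economic optimum and
#'   whose `predicted_yield` is the yield there.
#' @export
marginal_optimum <- function(fit, prices) {
  verdict <- classify_typicality(fit)
  if (!verdict$is_typical) {
    stop("marginal-derivative method requires a typical effect function; ",
         "sign violations on: ",
         paste(verdict$violations$term, collapse = ", "),
         " - use frequency analysis instead", call. = FALSE)
  }
  Q <- quadratic_matrix(fit)
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (!all(ev < 0)) {
    stop("quadratic matrix not negative definite: no economic optimum",
         call. = FALSE)
  }
  p_ratio <- unname(prices$nutrient_prices[fit$factors]) / prices$crop_price
  x <- drop(solve(2 * Q, p_ratio - unname(fit$linear)))
  structure(list(doses = stats::setNames(x, fit$factors),
                 predicted_yield = evaluate_effect_function(fit, x),
                 nature = "economic_optimum"),
            class = "stationary_point")
}
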