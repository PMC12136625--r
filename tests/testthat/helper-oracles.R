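# Independent least-squares oracle: Moore-Penrose pseudoinverse via SVD,
# applied to the same polynomial expansion the package fits.
pinv_solve <- function(X, y) {
  s <- svd(X)
  tol <- max(dim(X)) * max(s$d) * .Machine$double.eps
  dinv <- ifelse(s$d > tol, 1 / s$d, 0)
  drop(s$v %*% (dinv * crossprod(s$u, y)))
}

# Quadratic polynomial design matrix built independently of the package
# internals (plain loops over columns).
oracle_poly_matrix <- function(X) {
  X <- as.matrix(X)
  k <- ncol(X)
  M <- cbind(1, X)
  for (j in seq_len(k)) M <- cbind(M, X[, j]^2)
  if (k >= 2L) {
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) M <- cbind(M, X[, a] * X[, b])
    }
  }
  unname(M)
}

# Fit a quadratic by the pseudoinverse oracle; returns the coefficient
# vector in (intercept, linear, squares, pairwise) order.
oracle_quadratic_fit <- function(X, y) {
  pinv_solve(oracle_poly_matrix(X), y)
}

# Dose matrix (columns = factors) of selected treatments of a trial.
dose_matrix <- function(trial, treatments, factors) {
  design <- trial$design
  rows <- design[treatments, , drop = FALSE]
  cols <- c(N = "n_dose", P = "p_dose", K = "k_dose")[factors]
  m <- as.matrix(rows[, cols, drop = FALSE])
  colnames(m) <- factors
  m
}

# A tiny balanced synthetic trial on an exact quadratic (no noise), used
# by several interpolation tests.
exact_quadratic_trial <- function() {
  design <- build_3414_design(c(N = 20, P = 10, K = 10))
  surf <- effect_function(100, c(N = 2, P = 3, K = 1),
                          c(N = -0.1, P = -0.2, K = -0.05),
                          c("N:P" = 0.02, "N:K" = -0.01, "P:K" = 0.03))
  simulate_trial(design, surf, sd = 0, replicates = 3, seed = 1)
}
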