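# Brute-force normal-equations oracle: regress rows (order+1)..T on their own
# lags via an explicit (Z'Z)^{-1} Z'Y solve. Returns the stacked coefficient
# matrix (rows = lagged regressors, cols = equations), matching fit_var()$B.
ols_oracle <- function(values, order, drop_initial = order) {
  T <- nrow(values)
  n <- ncol(values)
  idx <- (drop_initial + 1):T
  y <- values[idx, , drop = FALSE]
  z <- do.call(cbind, lapply(seq_len(order), function(k)
    values[idx - k, , drop = FALSE]))
  solve(t(z) %*% z) %*% t(z) %*% y
}

# Stationary autocovariances of a bivariate VAR(1) x_t = A x_{t-1} + e_t,
# straight from the vectorized Lyapunov identity; used as the closed-form
# oracle for residual-GC innovation variances.
var1_autocov_oracle <- function(A, sigma = diag(nrow(A)), max_lag = 1) {
  n <- nrow(A)
  g0 <- matrix(solve(diag(n * n) - kronecker(A, A), as.vector(sigma)), n, n)
  out <- list(g0)
  for (h in seq_len(max_lag)) out[[h + 1]] <- A %*% out[[h]]
  out
}

random_small_panel <- function(n, T) {
  ts_panel(matrix(rnorm(T * n), T, n))
}

off_diag <- function(m) m[row(m) != col(m)]
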