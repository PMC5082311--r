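#' Vector autoregressive data-generating process
#'
#' Constructs a VAR(p) model
#' \deqn{x_t = \sum_{k=1}^{p} A_k x_{t-k} + \varepsilon_t,
#'       \quad \varepsilon_t \sim N(0, \Sigma),}
#' with no intercept. Entry `A_k[i, j]` is the linear effect of channel `j`
#' at lag `k` on channel `i` at time `t`.
#'
#' @param lag_coeffs list of `p` square n-by-n coefficient matrices
#'   `A_1 ... A_p`.
#' @param noise_cov n-by-n symmetric positive-definite innovation covariance;
#'   defaults to the identity (unit-variance Gaussian noise).
#' @param channel_labels optional character vector of channel names; defaults
#'   to `ch1 ... chn`.
#'
#' @return An object of class `var_model` with fields `n_channels`, `order`,
#'   `lag_coeffs` and `noise_cov`.
#' @seealso [var_preset()], [spectral_radius()], [simulate_var()]
#' @export
#' @examples
#' m <- var_model(list(matrix(c(0.5, 0, 0, 0.5), 2)))
#' spectral_radius(m)
var_model <- function(lag_coeffs, noise_cov = NULL, channel_labels = NULL) {
  if (!is.list(lag_coeffs) || length(lag_coeffs) < 1L)
    stop_input("`lag_coeffs` must be a non-empty list of square matrices")
  lag_coeffs <- lapply(lag_coeffs, function(a) {
    a <- as.matrix(a)
    storage.mode(a) <- "double"
    a
  })
  n <- nrow(lag_coeffs[[1L]])
  ok <- vapply(lag_coeffs, function(a) {
    nrow(a) == n && ncol(a) == n && all(is.finite(a))
  }, logical(1))
  if (!all(ok))
    stop_input("every lag coefficient matrix must be finite and %d x %d", n, n)
  if (is.null(noise_cov)) noise_cov <- diag(n)
  noise_cov <- as.matrix(noise_cov)
  if (nrow(noise_cov) != n || ncol(noise_cov) != n)
    stop_input("`noise_cov` must be %d x %d", n, n)
  if (max(abs(noise_cov - t(noise_cov))) > 1e-12)
    stop_input("`noise_cov` must be symmetric (tolerance 1e-12)")
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop_input("`noise_cov` must be positive definite")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n))
  if (length(channel_labels) != n)
    stop_input("`channel_labels` must have length %d", n)
  structure(
    list(
      n_channels = n,
      order = length(lag_coeffs),
      lag_coeffs = lag_coeffs,
      noise_cov = noise_cov,
      channel_labels = as.character(channel_labels)
    ),
    class = "var_model"
  )
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("VAR(%d) model, %d channels, spectral radius %.4f\n",
              x$order, x$n_channels, spectral_radius(x)))
  for (k in seq_len(x$order)) {
    cat(sprintf("A%d:\n", k))
    print(round(x$lag_coeffs[[k]], 4))
  }
  invisible(x)
}

## Grid of the tunable cross influence for each preset family.
preset_c_value <- function(name, k) {
  switch(name,
    model1  = -0.5 - 0.02 * k,
    model1b = -0.071 - 0.011 * k,
    model2  = -0.1 - 0.04 * k,
    model3  = -0.1 - 0.04 * k
  )
}

#' Preset bivariate VAR models for the signed-coefficient audit
#'
#' The four bivariate data-generating processes used throughout the
#' simulation study, each indexed by a grid position `k` (1..20) that sets
#' the strength of one cross influence `c`:
#'
#' * `model1`: order 3; no lag-1 interaction, antisymmetric lag-2 coupling
#'   (+0.6 from Y to X, -0.6 from X to Y), and a negative lag-3 influence
#'   `c = -0.5 - 0.02 k` from Y to X.
#' * `model1b`: order 1; a positive influence `0.186 + 0.005 k` from X to Y,
#'   a negative influence `-0.071 - 0.011 k` from Y to X, and
#'   autocorrelations 0.5. Its order-1 coefficients approximate what the
#'   underfitted order-1 fit recovers from `model1`.
#' * `model2`: as `model1` but with lag-1 autocorrelation 0.18 on both
#'   channels, lag-2 couplings of +/-0.8 and `c = -0.1 - 0.04 k`.
#' * `model3`: order 3; antisymmetric lag-1 coupling (+0.5 from Y to X,
#'   -0.5 from X to Y), no lag-2 term, and lag-3 influence
#'   `c = -0.1 - 0.04 k` from Y to X.
#'
#' All presets use unit-variance uncorrelated Gaussian innovations.
#'
#' @param name one of `"model1"`, `"model1b"`, `"model2"`, `"model3"`.
#' @param k integer grid index in 1..20.
#'
#' @return A [var_model()] with channels labelled `X`, `Y` and an attribute
#'   `c_value` holding the grid value of the varied influence.
#' @export
#' @examples
#' var_preset("model2", k = 5)
var_preset <- function(name, k) {
  name <- match.arg(name, c("model1", "model1b", "model2", "model3"))
  if (!is_count(k) || k < 1 || k > 20)
    stop_input("`k` must be an integer in 1..20 (got %s)", format(k))
  k <- as.integer(k)
  cval <- preset_c_value(name, k)
  mats <- switch(name,
    model1 = list(
      matrix(0, 2, 2),
      matrix(c(0, -0.6, 0.6, 0), 2, 2),
      matrix(c(0, 0, cval, 0), 2, 2)
    ),
    model1b = list(
      matrix(c(0.5, 0.186 + 0.005 * k, cval, 0.5), 2, 2)
    ),
    model2 = list(
      diag(0.18, 2),
      matrix(c(0, -0.8, 0.8, 0), 2, 2),
      matrix(c(0, 0, cval, 0), 2, 2)
    ),
    model3 = list(
      matrix(c(0, -0.5, 0.5, 0), 2, 2),
      matrix(0, 2, 2),
      matrix(c(0, 0, cval, 0), 2, 2)
    )
  )
  m <- var_model(mats, channel_labels = c("X", "Y"))
  attr(m, "preset") <- name
  attr(m, "k") <- k
  attr(m, "c_value") <- cval
  m
}

## p*n x p*n companion form of the VAR: top block row [A1 ... Ap],
## identity sub-diagonal, zeros elsewhere.
companion_matrix <- function(model) {
  n <- model$n_channels
  p <- model$order
  F <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) {
    F[seq_len(n), (k - 1L) * n + seq_len(n)] <- model$lag_coeffs[[k]]
  }
  if (p > 1L) {
    idx <- seq_len(n * (p - 1L))
    F[cbind(n + idx, idx)] <- 1
  }
  F
}

#' Companion spectral radius of a VAR model
#'
#' The largest eigenvalue modulus of the companion matrix. A value strictly
#' below 1 certifies a stable (jointly stationary) process.
#'
#' @param model a [var_model()].
#' @return Non-negative real.
#' @export
spectral_radius <- function(model) {
  stopifnot(inherits(model, "var_model"))
  max(Mod(eigen(companion_matrix(model), only.values = TRUE)$values))
}

#' Theoretical autocovariances of a stable VAR model
#'
#' Solves the discrete Lyapunov equation of the companion form for the
#' stationary covariance and extends it by the Yule-Walker recursion
#' \eqn{\Gamma(h) = \sum_k A_k \Gamma(h-k)}. `Gamma[[h + 1]]` is
#' \eqn{\Gamma(h) = Cov(x_t, x_{t-h})}.
#'
#' @param model a stable [var_model()].
#' @param max_lag largest lag to return.
#' @return List of `max_lag + 1` n-by-n matrices, lags 0..`max_lag`.
#' @export
var_autocov <- function(model, max_lag) {
  stopifnot(inherits(model, "var_model"), is_count(max_lag + 1))
  if (spectral_radius(model) >= 1)
    stop_input("autocovariances are defined only for a stable model")
  n <- model$n_channels
  p <- model$order
  F <- companion_matrix(model)
  Q <- matrix(0, n * p, n * p)
  Q[seq_len(n), seq_len(n)] <- model$noise_cov
  m <- n * p
  V <- matrix(solve(diag(m * m) - kronecker(F, F), as.vector(Q)), m, m)
  gam <- vector("list", max(max_lag + 1L, p))
  for (h in 0:(p - 1L)) {
    gam[[h + 1L]] <- V[seq_len(n), h * n + seq_len(n), drop = FALSE]
  }
  get_gamma <- function(h) if (h >= 0) gam[[h + 1L]] else t(gam[[-h + 1L]])
  if (max_lag >= p) {
    for (h in p:max_lag) {
      g <- matrix(0, n, n)
      for (k in seq_len(p)) {
        g <- g + model$lag_coeffs[[k]] %*% get_gamma(h - k)
      }
      gam[[h + 1L]] <- g
    }
  }
  gam[seq_len(max_lag + 1L)]
}
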