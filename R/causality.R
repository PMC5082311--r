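#' Signed path coefficients (order-1 joint fit)
#'
#' The "signed path coefficient" causality measure: fit the joint order-1
#' VAR across all channels and read influence off the lag-1 coefficient
#' matrix. Entry `[i, j]` (i != j) is the signed path coefficient from
#' channel j to channel i; the diagonal holds the fitted lag-1
#' autocorrelations. Higher lags of the data-generating process are ignored
#' by construction - this underfitting is exactly what the package's
#' simulation sweeps scrutinize.
#'
#' @param x a [ts_panel()] or matrix.
#' @return n-by-n numeric matrix with channel labels on both dimensions.
#' @seealso [residual_gc()], [sign_bias()]
#' @export
#' @examples
#' x <- simulate_var(var_preset("model3", 10), 1000, seed = 1)
#' signed_path_coefficients(x)
signed_path_coefficients <- function(x) {
  fit_var(x, order = 1L)$coeff_estimates[[1L]]
}

#' Residual-variance Granger causality for one directed pair
#'
#' The classical time-domain measure: the log ratio of the target channel's
#' residual variance in the restricted model (the target regressed on its
#' own past only) to that in the unrestricted model (the target and source
#' fitted jointly), both at the same lag order and on the same sample rows.
#' A value near zero means the source's past does not improve prediction of
#' the target.
#'
#' @param x a [ts_panel()] or matrix.
#' @param order lag order of both models; in "optimal order" workflows pass
#'   the AICc-selected order from [select_order()].
#' @param target target channel (index or label).
#' @param source putative causal source channel (index or label).
#'
#' @return `F_{source -> target}`, non-negative up to estimation noise.
#' @export
#' @examples
#' x <- simulate_var(var_preset("model3", 10), 1000, seed = 1)
#' residual_gc(x, order = 3, target = "Y", source = "X")
residual_gc <- function(x, order, target, source) {
  panel <- as_ts_panel(x)
  it <- resolve_channel(panel, target)
  is_ <- resolve_channel(panel, source)
  if (it == is_)
    stop_input("`target` and `source` must differ")
  if (!is_count(order))
    stop_input("`order` must be a positive integer")
  values <- scale(panel$values[, c(it, is_), drop = FALSE],
                  center = TRUE, scale = FALSE)
  T <- nrow(values)
  if (T - order <= 2 * order + 1L)
    stop_input("not enough time points (T = %d) for order %d", T, order)
  ## Both models on the rows (order+1)..T.
  restricted <- var_ols(values[, 1L, drop = FALSE], order, order)
  unrestricted <- var_ols(values, order, order)
  v0 <- restricted$sigma_ml[1L, 1L]
  v1 <- unrestricted$sigma_ml[1L, 1L]
  log(v0 / v1)
}

#' All pairwise residual Granger causalities
#'
#' Computes [residual_gc()] for every ordered channel pair, treating each
#' pair bivariately (the measure itself is defined for a pair; no
#' conditioning on remaining channels).
#'
#' @param x a [ts_panel()] or matrix.
#' @param order lag order passed to [residual_gc()].
#' @return n-by-n matrix with entry `[i, j] = F_{j -> i}`; diagonal `NA`.
#' @export
residual_gc_matrix <- function(x, order) {
  panel <- as_ts_panel(x)
  n <- ncol(panel$values)
  f <- matrix(NA_real_, n, n,
              dimnames = list(panel$channel_labels, panel$channel_labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) f[i, j] <- residual_gc(panel, order, target = i, source = j)
    }
  }
  f
}

#' Sign-bias statistic of a coefficient collection
#'
#' `(A+ - A-) / (A+ + A-)`: the normalized excess of positive over negative
#' values. Exact zeros (a probability-zero event for estimated coefficients)
#' are excluded from both counts.
#'
#' @param coeff_values numeric vector of coefficient estimates.
#' @return Value in `[-1, 1]`.
#' @export
#' @examples
#' sign_bias(c(1, 2, -3))
sign_bias <- function(coeff_values) {
  coeff_values <- as.numeric(coeff_values)
  if (length(coeff_values) == 0)
    stop_input("`coeff_values` must be non-empty")
  if (any(!is.finite(coeff_values)))
    stop_input("`coeff_values` must be finite")
  a_plus <- sum(coeff_values > 0)
  a_minus <- sum(coeff_values < 0)
  if (a_plus + a_minus == 0)
    stop_input("sign bias undefined: all values are zero")
  (a_plus - a_minus) / (a_plus + a_minus)
}

#' Full causality analysis of one panel
#'
#' Convenience wrapper producing both measures at once: the signed lag-1
#' path coefficients from the joint order-1 fit, and pairwise residual
#' Granger causality at a fixed or AICc-selected order, optionally with
#' permutation significance of each off-diagonal path coefficient.
#'
#' @param x a [ts_panel()] or matrix.
#' @param order `"auto"` (AICc-selected via [select_order()]) or a positive
#'   integer for the residual measure.
#' @param p_max candidate range when `order = "auto"`.
#' @param n_perm permutation count for coefficient significance; 0 skips
#'   the permutation test.
#' @param alpha two-tailed significance level.
#' @param seed seed for the permutation test.
#'
#' @return An object of class `causality_result` with fields
#'   `signed_coeffs`, `f_residual`, `order_used_residual`, `pvalues`
#'   (or `NULL`), `significance_mask` (or `NULL`) and `alpha`.
#' @export
causality <- function(x, order = "auto", p_max = 10, n_perm = 0,
                      alpha = 0.05, seed = NULL) {
  panel <- as_ts_panel(x)
  if (identical(order, "auto")) {
    sel <- select_order(panel, p_max = p_max, criterion = "aicc")
    order_used <- sel$selected_order_aicc
  } else {
    if (!is_count(order)) stop_input("`order` must be 'auto' or a positive integer")
    order_used <- as.integer(order)
  }
  coeffs <- signed_path_coefficients(panel)
  f <- residual_gc_matrix(panel, order_used)
  pvals <- mask <- NULL
  if (n_perm > 0) {
    n <- ncol(panel$values)
    off <- which(row(coeffs) != col(coeffs))
    stat <- function(p) signed_path_coefficients(p)[off]
    pt <- permutation_test(panel, stat, n_perm = n_perm, alpha = alpha,
                           seed = seed)
    pvals <- matrix(NA_real_, n, n, dimnames = dimnames(coeffs))
    pvals[off] <- pt$pvalue
    mask <- pvals <= alpha
  }
  structure(
    list(signed_coeffs = coeffs, f_residual = f,
         order_used_residual = order_used, pvalues = pvals,
         significance_mask = mask, alpha = alpha),
    class = "causality_result"
  )
}

#' @export
print.causality_result <- function(x, ...) {
  cat(sprintf("causality result (residual GC at order %d)\n",
              x$order_used_residual))
  cat("signed lag-1 path coefficients (column -> row):\n")
  print(round(x$signed_coeffs, 4))
  cat("residual Granger causality F (column -> row):\n")
  print(round(x$f_residual, 4))
  if (!is.null(x$pvalues)) {
    cat(sprintf("permutation p-values (alpha = %g):\n", x$alpha))
    print(round(x$pvalues, 4))
  }
  invisible(x)
}
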