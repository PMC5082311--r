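## Joint least-squares regression of rows (drop_initial+1)..T on their own
## `order` lags. Returns the stacked coefficient matrix B (rows = lagged
## regressors grouped by lag, cols = equations), residuals, and the ML
## residual covariance.
var_ols <- function(values, order, drop_initial) {
  T <- nrow(values)
  n <- ncol(values)
  idx <- (drop_initial + 1L):T
  y <- values[idx, , drop = FALSE]
  z <- matrix(0, length(idx), order * n)
  for (k in seq_len(order)) {
    z[, (k - 1L) * n + seq_len(n)] <- values[idx - k, , drop = FALSE]
  }
  qz <- qr(z)
  if (qz$rank < ncol(z)) {
    bad <- qz$pivot[(qz$rank + 1L):ncol(z)]
    ch <- unique((bad - 1L) %% n + 1L)
    labs <- colnames(values)
    if (is.null(labs)) labs <- paste0("ch", seq_len(n))
    stop_input(
      "rank-deficient regressor matrix; offending channel(s): %s",
      paste(labs[ch], collapse = ", "))
  }
  b <- qr.coef(qz, y)
  resid <- y - z %*% b
  list(B = b, residuals = resid,
       sigma_ml = crossprod(resid) / length(idx),
       n_obs_used = length(idx))
}

#' Fit a VAR(p) by multivariate least squares
#'
#' Estimates all lag matrices jointly by ordinary least squares with no
#' intercept; the panel is mean-centered per channel first (the modelled
#' processes are zero-mean). The residual covariance uses the maximum
#' likelihood divisor (the number of regression rows), and the parameter
#' count is `K = p * n^2`.
#'
#' @param x a [ts_panel()] or numeric matrix (rows = time points).
#' @param order lag order p.
#' @param drop_initial number of initial rows excluded from the regression;
#'   defaults to `order` (the maximal sample). [select_order()] passes
#'   `p_max` here when comparing candidates on a common sample.
#' @param center mean-center each channel before fitting (default `TRUE`).
#'
#' @return An object of class `var_fit` with fields `order`, `coeff_estimates`
#'   (list of p matrices, entry `[i, j]` = effect of channel j at that lag on
#'   channel i), `B` (stacked regressor-by-equation form), `residuals`,
#'   `sigma_ml`, `n_obs_used`, `n_params` and `channel_labels`.
#' @seealso [aicc()], [bic()], [select_order()]
#' @export
#' @examples
#' x <- simulate_var(var_preset("model3", 10), 500, seed = 1)
#' fit <- fit_var(x, order = 3)
#' fit$coeff_estimates[[1]]
fit_var <- function(x, order, drop_initial = order, center = TRUE) {
  panel <- as_ts_panel(x)
  if (!is_count(order))
    stop_input("`order` must be a positive integer")
  n <- ncol(panel$values)
  T <- nrow(panel$values)
  if (drop_initial < order)
    stop_input("`drop_initial` must be at least `order`")
  if (T - drop_initial <= order * n + 1L)
    stop_input(
      "not enough time points (T = %d) for a VAR(%d) on %d channels", T,
      order, n)
  values <- panel$values
  if (center) values <- scale(values, center = TRUE, scale = FALSE)
  ols <- var_ols(values, order, as.integer(drop_initial))
  coeffs <- lapply(seq_len(order), function(k) {
    a <- t(ols$B[(k - 1L) * n + seq_len(n), , drop = FALSE])
    dimnames(a) <- list(panel$channel_labels, panel$channel_labels)
    a
  })
  structure(
    list(
      order = as.integer(order),
      coeff_estimates = coeffs,
      B = ols$B,
      residuals = ols$residuals,
      sigma_ml = ols$sigma_ml,
      n_obs_used = ols$n_obs_used,
      n_params = as.integer(order) * n^2,
      n_channels = n,
      channel_labels = panel$channel_labels
    ),
    class = "var_fit"
  )
}

#' @export
print.var_fit <- function(x, ...) {
  cat(sprintf("VAR(%d) fit: %d channels, %d rows, K = %d, ln det(Sigma) = %.4f\n",
              x$order, x$n_channels, x$n_obs_used, x$n_params,
              determinant(x$sigma_ml)$modulus))
  invisible(x)
}

criterion_inputs <- function(fit) {
  stopifnot(inherits(fit, "var_fit"))
  list(T = fit$n_obs_used, K = fit$n_params,
       ldet = as.numeric(determinant(fit$sigma_ml, logarithm = TRUE)$modulus))
}

#' Small-sample corrected Akaike information criterion of a VAR fit
#'
#' `AICc = T ln det(Sigma) + 2 K T / (T - K - 1)`, with `T` the number of
#' regression rows, `Sigma` the ML residual covariance and `K = p n^2`.
#'
#' @param fit a [fit_var()] result.
#' @return The criterion value.
#' @export
aicc <- function(fit) {
  ci <- criterion_inputs(fit)
  if (ci$T - ci$K - 1 <= 0)
    stop_input(
      "AICc undefined: T - K - 1 = %d <= 0 (T = %d, K = %d)",
      ci$T - ci$K - 1, ci$T, ci$K)
  ci$T * ci$ldet + 2 * ci$K * ci$T / (ci$T - ci$K - 1)
}

#' Bayesian information criterion of a VAR fit
#'
#' `BIC = T ln det(Sigma) + K ln(T)` (natural logarithms), with `K = p n^2`.
#'
#' @param fit a [fit_var()] result.
#' @return The criterion value.
#' @export
bic <- function(fit) {
  ci <- criterion_inputs(fit)
  ci$T * ci$ldet + ci$K * log(ci$T)
}

#' Select the VAR model order by information criteria
#'
#' Fits every candidate order `1..p_max` and returns the AICc- and
#' BIC-minimizing orders. By default each candidate uses its own maximal
#' sample (candidate p drops its first p rows); `sample = "common"` instead
#' fits all candidates on the rows remaining after dropping the first
#' `p_max`, making the likelihood terms directly comparable. Candidates
#' whose AICc is undefined (`T - K - 1 <= 0`) or that have fewer rows than
#' regressors are skipped with a warning. Ties break toward the smallest
#' order.
#'
#' @param x a [ts_panel()] or matrix.
#' @param p_max largest candidate order.
#' @param criterion `"both"` (default), `"aicc"` or `"bic"`.
#' @param sample `"max"` (per-candidate maximal sample, default) or
#'   `"common"`.
#'
#' @return An object of class `order_selection`: a list with the candidate
#'   table (`candidates`: order, aicc, bic, T_eff) and the selected orders
#'   `selected_order_aicc`, `selected_order_bic`.
#' @export
#' @examples
#' x <- simulate_var(var_preset("model3", 10), 1000, seed = 1)
#' select_order(x, p_max = 8)
select_order <- function(x, p_max = 10,
                         criterion = c("both", "aicc", "bic"),
                         sample = c("max", "common")) {
  criterion <- match.arg(criterion)
  sample <- match.arg(sample)
  panel <- as_ts_panel(x)
  if (!is_count(p_max))
    stop_input("`p_max` must be a positive integer")
  n <- ncol(panel$values)
  T <- nrow(panel$values)
  want_aicc <- criterion %in% c("both", "aicc")
  want_bic <- criterion %in% c("both", "bic")
  tab <- data.frame(order = seq_len(p_max), aicc = NA_real_,
                    bic = NA_real_, T_eff = NA_integer_)
  skipped <- integer(0)
  for (p in seq_len(p_max)) {
    drop <- if (sample == "common") p_max else p
    t_eff <- T - drop
    if (t_eff <= p * n + 1L) {  # fewer rows than regressors: cannot fit
      skipped <- c(skipped, p)
      next
    }
    fit <- fit_var(panel, p, drop_initial = drop)
    tab$T_eff[p] <- fit$n_obs_used
    if (want_bic) tab$bic[p] <- bic(fit)
    if (want_aicc) {
      if (fit$n_obs_used - fit$n_params - 1 > 0) {
        tab$aicc[p] <- aicc(fit)
      } else {
        skipped <- c(skipped, p)
      }
    }
  }
  if (length(skipped) > 0)
    warning(sprintf(
      "candidate order(s) %s skipped: criterion undefined with T = %d, n = %d",
      paste(unique(skipped), collapse = ", "), T, n), call. = FALSE)
  pick <- function(v) {
    if (all(is.na(v))) return(NA_integer_)
    which.min(v)  # which.min returns the first (smallest-order) minimum
  }
  sel_aicc <- if (want_aicc) pick(tab$aicc) else NA_integer_
  sel_bic <- if (want_bic) pick(tab$bic) else NA_integer_
  if (want_aicc && is.na(sel_aicc) && want_bic && is.na(sel_bic))
    stop_input("no candidate order has a defined criterion (T = %d, n = %d)",
               T, n)
  structure(
    list(candidates = tab,
         selected_order_aicc = as.integer(sel_aicc),
         selected_order_bic = as.integer(sel_bic),
         criterion = criterion, sample = sample),
    class = "order_selection"
  )
}

#' @export
print.order_selection <- function(x, ...) {
  cat(sprintf("order selection (sample = %s): AICc -> %s, BIC -> %s\n",
              x$sample,
              ifelse(is.na(x$selected_order_aicc), "NA", x$selected_order_aicc),
              ifelse(is.na(x$selected_order_bic), "NA", x$selected_order_bic)))
  print(x$candidates, row.names = FALSE)
  invisible(x)
}
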