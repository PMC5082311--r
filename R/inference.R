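#' Time-shuffled surrogate panel
#'
#' Destroys the temporal (hence causal) structure of a panel by permuting
#' the time indices while preserving each channel's marginal distribution
#' exactly. By default every channel is permuted independently, which also
#' destroys instantaneous cross-correlation - a stricter null than
#' `joint = TRUE`, where one permutation is applied to whole rows.
#'
#' @param x a [ts_panel()] or matrix with at least 2 rows.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param joint permute whole rows with a single permutation.
#' @return A [ts_panel()] of the same shape and metadata.
#' @export
shuffle_surrogate <- function(x, seed = NULL, joint = FALSE) {
  panel <- as_ts_panel(x)
  T <- nrow(panel$values)
  if (T < 2L) stop_input("need at least 2 time points to shuffle")
  values <- with_rng_seed(seed, {
    if (joint) {
      panel$values[sample.int(T), , drop = FALSE]
    } else {
      apply(panel$values, 2, function(col) col[sample.int(T)])
    }
  })
  ts_panel(values, channel_labels = panel$channel_labels,
           sampling_interval_s = panel$sampling_interval_s)
}

#' Permutation significance test of a panel statistic
#'
#' Recomputes `statistic` on `n_perm` time-shuffled surrogates and compares
#' the observed value against the empirical null, two-tailed:
#' `p = (1 + #\{|null| >= |observed|\}) / (n_perm + 1)`. The add-one form
#' avoids zero p-values. `statistic` may return a named vector, in which
#' case all components share the same surrogates and a p-value is reported
#' per component.
#'
#' @param x a [ts_panel()] or matrix.
#' @param statistic function mapping a `ts_panel` to a numeric scalar or
#'   vector (for example, one or more signed path coefficients).
#' @param n_perm number of surrogates (at least 100 for a meaningful
#'   two-tailed test at conventional levels).
#' @param alpha significance level.
#' @param seed integer seed making the full test deterministic.
#' @param joint passed to [shuffle_surrogate()].
#'
#' @return An object of class `permutation_test`: `observed`, `null_values`
#'   (`n_perm` rows), `pvalue`, `alpha`, `significant`.
#' @export
#' @examples
#' x <- simulate_var(var_preset("model1b", 5), 300, seed = 2)
#' stat <- function(p) signed_path_coefficients(p)[2, 1]
#' permutation_test(x, stat, n_perm = 200, seed = 7)
permutation_test <- function(x, statistic, n_perm = 1000, alpha = 0.05,
                             seed = NULL, joint = FALSE) {
  panel <- as_ts_panel(x)
  if (!is.function(statistic)) stop_input("`statistic` must be a function")
  if (!is_count(n_perm) || n_perm < 100)
    stop_input("`n_perm` must be an integer >= 100")
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1)
    stop_input("`alpha` must lie in (0, 1)")
  observed <- statistic(panel)
  if (!is.numeric(observed) || any(!is.finite(observed)))
    stop_input("`statistic` must return finite numeric values")
  d <- length(observed)
  nulls <- with_rng_seed(seed, {
    out <- matrix(NA_real_, n_perm, d)
    for (b in seq_len(n_perm)) {
      surr <- shuffle_surrogate(panel, seed = NULL, joint = joint)
      val <- tryCatch(statistic(surr), error = function(e) {
        stop_input("statistic failed on surrogate %d: %s", b,
                   conditionMessage(e))
      })
      if (length(val) != d || any(!is.finite(val)))
        stop_input("statistic returned invalid values on surrogate %d", b)
      out[b, ] <- val
    }
    out
  })
  pval <- vapply(seq_len(d), function(j) {
    (1 + sum(abs(nulls[, j]) >= abs(observed[j]))) / (n_perm + 1)
  }, numeric(1))
  names(pval) <- names(observed)
  structure(
    list(observed = observed, null_values = nulls, pvalue = pval,
         alpha = alpha, significant = pval <= alpha, n_perm = n_perm),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("permutation test (%d surrogates, alpha = %g)\n",
              x$n_perm, x$alpha))
  print(data.frame(observed = x$observed, pvalue = x$pvalue,
                   significant = x$significant))
  invisible(x)
}
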