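## Most frequent integer in a vector; ties break toward the smallest value.
modal_value <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Monte-Carlo sweep over a preset model's influence grid
#'
#' For every grid index `k`, simulates `n_reps` independent panels from the
#' preset, and per panel computes: the AICc/BIC-selected orders, the signed
#' lag-1 path coefficients from the order-1 joint fit, residual Granger
#' causality in both directions at the AICc-selected order, and (optionally)
#' permutation significance of both off-diagonal coefficients. Aggregates
#' mirror the study's summary tables: sign counts `a_plus`/`a_minus` pooled
#' over the `2 * n_reps` off-diagonal coefficients, mean selected orders,
#' mean coefficients and mean causalities per direction, and significant
#' fractions.
#'
#' Directions are named from the preset's channel labels: `xy` is X to Y
#' (the Y-equation coefficient on lagged X, and `F_{X -> Y}`), `yx` the
#' reverse.
#'
#' @param preset preset family name, see [var_preset()].
#' @param k_range integer grid indices to sweep (subset of 1..20).
#' @param n_reps replicates per grid point.
#' @param n_timepoints panel length per replicate.
#' @param seed integer seed; the whole sweep is reproducible from it.
#' @param p_max candidate-order range for [select_order()].
#' @param n_perm permutations per replicate for coefficient significance;
#'   0 (default) skips significance and leaves the `sig_frac_*` columns `NA`.
#' @param alpha significance level for the permutation test.
#' @param burn_in simulation burn-in, passed to [simulate_var()].
#' @param sample order-selection sample convention, see [select_order()].
#'
#' @return A data frame of class `sweep_summary`, one row per grid index,
#'   with columns `k`, `c_value`, `a_plus`, `a_minus`, `mean_order_aicc`,
#'   `mean_order_bic`, `modal_order_aicc`, `modal_order_bic`,
#'   `mean_coeff_xy`, `mean_coeff_yx`, `mean_f_xy`, `mean_f_yx`,
#'   `sig_frac_xy`, `sig_frac_yx`.
#' @export
#' @examples
#' run_model_sweep("model2", k_range = 1, n_reps = 5, n_timepoints = 500,
#'                 seed = 1)
run_model_sweep <- function(preset, k_range = 1:20, n_reps = 100,
                            n_timepoints = 1000, seed = 1, p_max = 10,
                            n_perm = 0, alpha = 0.05, burn_in = 500,
                            sample = c("max", "common")) {
  sample <- match.arg(sample)
  if (!is_count(n_reps)) stop_input("`n_reps` must be a positive integer")
  k_range <- as.integer(k_range)
  if (length(k_range) > 0 && (min(k_range) < 1 || max(k_range) > 20))
    stop_input("`k_range` must lie within 1..20")
  rows <- vector("list", length(k_range))
  with_rng_seed(seed, {
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      model <- var_preset(preset, k)
      ord_a <- ord_b <- numeric(n_reps)
      cxy <- cyx <- fxy <- fyx <- numeric(n_reps)
      sxy <- syx <- rep(NA, n_reps)
      a_plus <- a_minus <- 0L
      for (r in seq_len(n_reps)) {
        panel <- simulate_var(model, n_timepoints, seed = NULL,
                              burn_in = burn_in)
        sel <- select_order(panel, p_max = p_max, sample = sample)
        ord_a[r] <- sel$selected_order_aicc
        ord_b[r] <- sel$selected_order_bic
        coef1 <- signed_path_coefficients(panel)
        cxy[r] <- coef1[2L, 1L]
        cyx[r] <- coef1[1L, 2L]
        a_plus <- a_plus + sum(c(cxy[r], cyx[r]) > 0)
        a_minus <- a_minus + sum(c(cxy[r], cyx[r]) < 0)
        fxy[r] <- residual_gc(panel, sel$selected_order_aicc,
                              target = 2L, source = 1L)
        fyx[r] <- residual_gc(panel, sel$selected_order_aicc,
                              target = 1L, source = 2L)
        if (n_perm > 0) {
          stat <- function(p) {
            b <- signed_path_coefficients(p)
            c(xy = b[2L, 1L], yx = b[1L, 2L])
          }
          pt <- permutation_test(panel, stat, n_perm = n_perm,
                                 alpha = alpha, seed = NULL)
          sxy[r] <- pt$significant[["xy"]]
          syx[r] <- pt$significant[["yx"]]
        }
      }
      rows[[ki]] <- data.frame(
        k = k,
        c_value = attr(model, "c_value"),
        a_plus = a_plus,
        a_minus = a_minus,
        mean_order_aicc = mean(ord_a),
        mean_order_bic = mean(ord_b),
        modal_order_aicc = modal_value(ord_a),
        modal_order_bic = modal_value(ord_b),
        mean_coeff_xy = mean(cxy),
        mean_coeff_yx = mean(cyx),
        mean_f_xy = mean(fxy),
        mean_f_yx = mean(fyx),
        sig_frac_xy = if (n_perm > 0) mean(sxy) else NA_real_,
        sig_frac_yx = if (n_perm > 0) mean(syx) else NA_real_
      )
    }
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(k = integer(0), c_value = numeric(0),
                      a_plus = integer(0), a_minus = integer(0),
                      mean_order_aicc = numeric(0), mean_order_bic = numeric(0),
                      modal_order_aicc = integer(0), modal_order_bic = integer(0),
                      mean_coeff_xy = numeric(0), mean_coeff_yx = numeric(0),
                      mean_f_xy = numeric(0), mean_f_yx = numeric(0),
                      sig_frac_xy = numeric(0), sig_frac_yx = numeric(0))
  }
  attr(out, "preset") <- preset
  attr(out, "n_reps") <- as.integer(n_reps)
  attr(out, "n_timepoints") <- as.integer(n_timepoints)
  attr(out, "seed") <- seed
  class(out) <- c("sweep_summary", "data.frame")
  out
}

#' ROI-combination sweep over channel-group sizes
#'
#' Replicates the group-size analysis applied to ROI panels: for each group
#' size `g`, forms `n_combinations` channel groups by the cyclic window rule
#' (channels `k .. k+g-1` modulo n, for `k = 1 .. n_combinations`), and per
#' group computes the AICc/BIC-selected order and the off-diagonal lag-1
#' coefficients of the joint order-1 fit. Coefficients are pooled across
#' groups into sign counts and the sign-bias statistic.
#'
#' @param x a [ts_panel()] or matrix with at least `max(group_sizes)`
#'   channels.
#' @param group_sizes channel-group sizes to evaluate.
#' @param n_combinations number of cyclic windows per group size; defaults
#'   to the channel count.
#' @param p_max candidate-order range for [select_order()].
#' @param random_combinations draw each group as a random channel subset
#'   instead of cyclic windows.
#' @param seed seed for `random_combinations`.
#'
#' @return A data frame of class `roi_sweep_summary`, one row per group
#'   size, with columns `group_size`, `n_combinations`, `mean_order_aicc`,
#'   `mean_order_bic`, `a_plus`, `a_minus`, `sign_bias`, `mean_coeff`.
#'   Orders average over the groups where the criterion is defined.
#' @export
run_roi_sweep <- function(x, group_sizes = c(2, 4, 8, 16, 32),
                          n_combinations = NULL, p_max = 10,
                          random_combinations = FALSE, seed = NULL) {
  panel <- as_ts_panel(x)
  n <- ncol(panel$values)
  group_sizes <- as.integer(group_sizes)
  if (any(group_sizes < 2))
    stop_input("group sizes must be at least 2")
  if (max(group_sizes) > n)
    stop_input("group size %d exceeds the panel's %d channels",
               max(group_sizes), n)
  if (is.null(n_combinations)) n_combinations <- n
  if (!is_count(n_combinations))
    stop_input("`n_combinations` must be a positive integer")
  rows <- vector("list", length(group_sizes))
  with_rng_seed(seed, {
    for (gi in seq_along(group_sizes)) {
      g <- group_sizes[gi]
      ord_a <- ord_b <- rep(NA_real_, n_combinations)
      coeffs <- c()
      for (k in seq_len(n_combinations)) {
        idx <- if (random_combinations) {
          sample.int(n, g)
        } else {
          (k - 1L + 0:(g - 1L)) %% n + 1L
        }
        sub <- ts_panel(panel$values[, idx, drop = FALSE],
                        channel_labels = panel$channel_labels[idx],
                        sampling_interval_s = panel$sampling_interval_s)
        sel <- suppressWarnings(
          tryCatch(select_order(sub, p_max = p_max), error = function(e) NULL))
        if (!is.null(sel)) {
          ord_a[k] <- sel$selected_order_aicc
          ord_b[k] <- sel$selected_order_bic
        }
        b <- signed_path_coefficients(sub)
        coeffs <- c(coeffs, b[row(b) != col(b)])
      }
      rows[[gi]] <- data.frame(
        group_size = g,
        n_combinations = n_combinations,
        mean_order_aicc = mean(ord_a, na.rm = TRUE),
        mean_order_bic = mean(ord_b, na.rm = TRUE),
        a_plus = sum(coeffs > 0),
        a_minus = sum(coeffs < 0),
        sign_bias = sign_bias(coeffs),
        mean_coeff = mean(coeffs)
      )
    }
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("roi_sweep_summary", "data.frame")
  out
}

#' Zero-phase bandpass filter a panel
#'
#' Applies a zero-phase (forward-backward) Butterworth bandpass to every
#' channel. Requires the panel to carry its sampling interval.
#'
#' @param x a [ts_panel()] with `sampling_interval_s` set.
#' @param low_hz,high_hz band edges in Hz; `0 < low < high < ` Nyquist.
#' @param filter_order Butterworth order of the underlying one-pass filter.
#' @return A filtered [ts_panel()] with unchanged metadata.
#' @export
bandpass_filter <- function(x, low_hz, high_hz, filter_order = 2) {
  panel <- as_ts_panel(x)
  if (is.null(panel$sampling_interval_s))
    stop_input("panel has no `sampling_interval_s`; a bandpass needs one")
  nyquist <- 1 / (2 * panel$sampling_interval_s)
  if (!is_scalar_number(low_hz) || !is_scalar_number(high_hz) ||
      low_hz <= 0 || high_hz <= low_hz || high_hz >= nyquist)
    stop_input("band edges must satisfy 0 < low < high < Nyquist (%.4g Hz)",
               nyquist)
  bf <- signal::butter(filter_order, c(low_hz, high_hz) / nyquist,
                       type = "pass")
  ## channels are demeaned first: the mean is outside any passband, and
  ## removing it up front avoids DC leakage through filtfilt edge transients
  filtered <- apply(panel$values, 2, function(col)
    as.numeric(signal::filtfilt(bf, col - mean(col))))
  ts_panel(filtered, channel_labels = panel$channel_labels,
           sampling_interval_s = panel$sampling_interval_s)
}

#' Compare an ROI sweep with and without bandpass filtering
#'
#' Runs [run_roi_sweep()] on the raw panel and on its bandpass-filtered
#' copy, returning both summaries stacked with an `arm` column
#' (`"raw"` / `"filtered"`).
#'
#' @param x a [ts_panel()] with `sampling_interval_s` set.
#' @param band numeric length-2 vector `c(low_hz, high_hz)`; the default
#'   0.01-0.08 Hz is the de-facto resting-state standard.
#' @param group_sizes,n_combinations,p_max passed to [run_roi_sweep()].
#' @return A data frame of class `roi_sweep_comparison`.
#' @export
compare_filtering <- function(x, band = c(0.01, 0.08),
                              group_sizes = c(2, 4, 8, 16, 32),
                              n_combinations = NULL, p_max = 10) {
  if (length(band) != 2)
    stop_input("`band` must be c(low_hz, high_hz)")
  raw <- run_roi_sweep(x, group_sizes, n_combinations, p_max)
  filt <- run_roi_sweep(bandpass_filter(x, band[1], band[2]),
                        group_sizes, n_combinations, p_max)
  raw$arm <- "raw"
  filt$arm <- "filtered"
  out <- rbind(as.data.frame(raw), as.data.frame(filt))
  class(out) <- c("roi_sweep_comparison", "data.frame")
  out
}
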