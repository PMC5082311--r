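test_that("sweep sign counts conserve 2 coefficients per replicate", {
  for (k in c(1, 10, 20)) {
    s <- run_model_sweep("model1", k_range = k, n_reps = 1,
                         n_timepoints = 300, seed = k)
    expect_equal(s$a_plus + s$a_minus, 2)
  }
})

test_that("sweeps are bit-identical under the same seed", {
  a <- run_model_sweep("model2", k_range = c(3, 9), n_reps = 4,
                       n_timepoints = 400, seed = 99)
  b <- run_model_sweep("model2", k_range = c(3, 9), n_reps = 4,
                       n_timepoints = 400, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("sweep summaries carry the fixed column layout", {
  s <- run_model_sweep("model3", k_range = 2, n_reps = 2,
                       n_timepoints = 300, seed = 1)
  expect_identical(
    names(s),
    c("k", "c_value", "a_plus", "a_minus", "mean_order_aicc",
      "mean_order_bic", "modal_order_aicc", "modal_order_bic",
      "mean_coeff_xy", "mean_coeff_yx", "mean_f_xy", "mean_f_yx",
      "sig_frac_xy", "sig_frac_yx"))
  expect_equal(s$c_value, -0.1 - 0.04 * 2)
  # model1's grid differs
  s1 <- run_model_sweep("model1", k_range = 2, n_reps = 1,
                        n_timepoints = 300, seed = 1)
  expect_equal(s1$c_value, -0.5 - 0.02 * 2)
})

test_that("scaled-down sweeps agree with larger ones within noise", {
  small <- run_model_sweep("model2", k_range = 15, n_reps = 25,
                           n_timepoints = 1000, seed = 7)
  large <- run_model_sweep("model2", k_range = 15, n_reps = 100,
                           n_timepoints = 1000, seed = 8)
  p_small <- small$a_plus / (2 * 25)
  p_large <- large$a_plus / (2 * 100)
  se <- sqrt(p_large * (1 - p_large) * (1 / 50 + 1 / 200))
  expect_lt(abs(p_small - p_large), 2.5 * se + 0.05)
  expect_lt(abs(small$mean_order_aicc - large$mean_order_aicc), 0.35)
})

test_that("sweep significance fractions populate when permutations run", {
  s <- run_model_sweep("model2", k_range = 20, n_reps = 3,
                       n_timepoints = 500, seed = 5, n_perm = 100)
  expect_true(s$sig_frac_xy >= 0 && s$sig_frac_xy <= 1)
  expect_true(s$sig_frac_yx >= 0 && s$sig_frac_yx <= 1)
  # strongest coupling: both directions should mostly be significant
  expect_gte(s$sig_frac_yx, 2 / 3)
})

test_that("roi sweep validates group sizes and pools coefficients", {
  x <- generate_fmri_like(6, 300, seed = 30)
  expect_error(run_roi_sweep(x, group_sizes = 8), "exceeds")
  expect_error(run_roi_sweep(x, group_sizes = 1), "at least 2")
  s <- run_roi_sweep(x, group_sizes = c(2, 4), n_combinations = 6,
                     p_max = 4)
  expect_equal(s$group_size, c(2, 4))
  expect_equal(s$a_plus + s$a_minus, c(6 * 2, 6 * 12))
  expect_true(all(abs(s$sign_bias) <= 1))
})

test_that("independent noise shows no systematic sign bias", {
  x <- ts_panel(matrix(rnorm(2000 * 24), 2000, 24),
                sampling_interval_s = 1)
  s <- run_roi_sweep(x, group_sizes = c(2, 4, 8), n_combinations = 24,
                     p_max = 3)
  expect_true(all(abs(s$sign_bias) < 0.2))
  expect_lt(abs(s$sign_bias[s$group_size == 8]), 0.1)
  expect_true(all(abs(s$mean_coeff) < 0.02))
})

test_that("bandpass keeps in-band sinusoids and removes DC", {
  T <- 500
  tr <- 0.645
  t <- (1:T) * tr
  sine <- sin(2 * pi * 0.04 * t)  # inside 0.01-0.08 Hz
  x <- ts_panel(cbind(sine, rep(5, T)), sampling_interval_s = tr)
  f <- bandpass_filter(x, 0.01, 0.08)
  core <- 100:(T - 100)
  amp_in <- max(abs(sine[core]))
  amp_out <- max(abs(f$values[core, 1]))
  expect_lt(abs(amp_out - amp_in) / amp_in, 0.05)
  expect_lt(abs(mean(f$values[, 2])), 1e-6)
})

test_that("bandpass validates its band and metadata", {
  x <- ts_panel(matrix(rnorm(200), 100, 2), sampling_interval_s = 0.645)
  expect_error(bandpass_filter(x, 0.08, 0.08), "band edges")
  expect_error(bandpass_filter(x, 0, 0.08), "band edges")
  expect_error(bandpass_filter(x, 0.01, 1), "band edges")
  no_tr <- ts_panel(matrix(rnorm(200), 100, 2))
  expect_error(bandpass_filter(no_tr, 0.01, 0.08), "sampling_interval_s")
  expect_error(compare_filtering(x, band = 0.05), "band")
})

test_that("filtering comparison returns paired arms on white noise", {
  x <- ts_panel(matrix(rnorm(800 * 8), 800, 8), sampling_interval_s = 0.645)
  cmp <- compare_filtering(x, group_sizes = c(2, 4), n_combinations = 8,
                           p_max = 3)
  expect_setequal(unique(cmp$arm), c("raw", "filtered"))
  expect_equal(nrow(cmp), 4)
  raw <- cmp[cmp$arm == "raw", ]
  expect_true(all(abs(raw$sign_bias) < 0.4))
})
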