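test_that("model3's X-to-Y path coefficient recovers -0.5", {
  vals <- sapply(1:40, function(s) {
    x <- simulate_var(var_preset("model3", 10), 1000, seed = 500 + s)
    signed_path_coefficients(x)[2, 1]
  })
  expect_lt(abs(mean(vals) + 0.5), 0.03)
})

test_that("independent channels give near-zero path coefficients", {
  x <- simulate_var(var_model(list(matrix(0, 2, 2))), 10000, seed = 9)
  expect_lt(max(abs(off_diag(signed_path_coefficients(x)))), 0.05)
})

test_that("an order-1 process is recovered exactly in the large-T limit", {
  m <- var_preset("model1b", 1)
  x <- simulate_var(m, 100000, seed = 10)
  expect_lt(max(abs(signed_path_coefficients(x) - m$lag_coeffs[[1]])), 0.02)
})

test_that("residual GC vanishes when the source is decoupled", {
  m <- var_model(list(diag(c(0.5, 0.4))))
  x <- simulate_var(m, 10000, seed = 12)
  expect_lt(residual_gc(x, 1, target = 1, source = 2), 0.005)
  expect_lt(residual_gc(x, 1, target = 2, source = 1), 0.005)
})

test_that("residual GC matches the Yule-Walker innovation-variance oracle", {
  m <- var_preset("model1b", 10)
  A <- m$lag_coeffs[[1]]
  gam <- var1_autocov_oracle(A, max_lag = 1)
  # restricted: univariate AR(1) on Y's own past; unrestricted: true model
  v0 <- gam[[1]][2, 2] - gam[[2]][2, 2]^2 / gam[[1]][2, 2]
  f_theory <- log(v0 / 1)
  est <- sapply(1:5, function(s) {
    x <- simulate_var(m, 50000, seed = 600 + s)
    residual_gc(x, 1, target = "Y", source = "X")
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - f_theory), 2 * se + 1e-6)
})

test_that("residual GC grows with the strength of the lag-3 influence", {
  f_yx <- sapply(c(3, 10, 17), function(k) {
    mean(sapply(1:10, function(s) {
      x <- simulate_var(var_preset("model2", k), 1000, seed = 700 + 20 * k + s)
      residual_gc(x, 3, target = "X", source = "Y")
    }))
  })
  expect_true(all(diff(f_yx) > 0))
})

test_that("nested fits keep residual GC non-negative", {
  set.seed(13)
  for (i in 1:20) {
    x <- random_small_panel(2, sample(60:200, 1))
    expect_gte(residual_gc(x, sample(1:3, 1), 1, 2), 0)
  }
})

test_that("relabeling channels transposes both measures", {
  x <- simulate_var(var_preset("model2", 10), 500, seed = 14)
  sw <- ts_panel(x$values[, 2:1], channel_labels = x$channel_labels[2:1])
  b <- signed_path_coefficients(x)
  bs <- signed_path_coefficients(sw)
  expect_equal(unname(bs), unname(b[2:1, 2:1]), tolerance = 1e-12)
  expect_equal(residual_gc(x, 3, "Y", "X"), residual_gc(sw, 3, "Y", "X"),
               tolerance = 1e-12)
})

test_that("order-1 truth: signed coefficients agree with the selected-order fit", {
  x <- simulate_var(var_preset("model1b", 5), 5000, seed = 15)
  sel <- select_order(x, p_max = 6)
  fit <- fit_var(x, sel$selected_order_aicc)
  expect_lt(max(abs(signed_path_coefficients(x) - fit$coeff_estimates[[1]])),
            0.05)
})

test_that("sign_bias counts positives and negatives, excluding zeros", {
  expect_equal(sign_bias(c(1, 2, 0.5)), 1)
  expect_equal(sign_bias(c(1, -1, 2, -2)), 0)
  expect_equal(sign_bias(c(rep(1, 195), rep(-1, 5))), 0.95)
  expect_equal(sign_bias(c(0, 0, 3)), 1)
  expect_error(sign_bias(c(0, 0)), "zero")
  expect_error(sign_bias(numeric(0)), "non-empty")
})

test_that("the causality wrapper assembles aligned matrices", {
  x <- simulate_var(var_preset("model2", 10), 600, seed = 16)
  res <- causality(x, order = "auto", p_max = 6, n_perm = 100, seed = 17)
  expect_equal(dim(res$signed_coeffs), c(2, 2))
  expect_true(all(is.na(diag(res$f_residual))))
  expect_true(all(res$f_residual[!is.na(res$f_residual)] >= 0))
  expect_identical(res$significance_mask, res$pvalues <= res$alpha)
  expect_gte(res$order_used_residual, 1)
})
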