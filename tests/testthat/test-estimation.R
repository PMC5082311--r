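test_that("fit_var equals the explicit normal-equations solution", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(1:3, 1)
    T <- sample(20:50, 1)
    p <- sample(1:2, 1)
    x <- matrix(rnorm(T * n), T, n)
    fit <- fit_var(x, p, center = FALSE)
    expect_lt(max(abs(fit$B - ols_oracle(x, p))), 1e-8)
  }
})

test_that("var_fit bookkeeping follows K = p n^2 and the ML divisor", {
  x <- simulate_var(var_preset("model2", 3), 400, seed = 5)
  fit <- fit_var(x, 3)
  expect_equal(fit$n_params, 3 * 4)
  expect_equal(fit$n_obs_used, 400 - 3)
  expect_equal(nrow(fit$residuals), fit$n_obs_used)
  expect_equal(fit$sigma_ml, crossprod(fit$residuals) / fit$n_obs_used)
  expect_equal(fit$sigma_ml, t(fit$sigma_ml))
  expect_true(all(eigen(fit$sigma_ml, only.values = TRUE)$values > -1e-12))
})

test_that("rank-deficient regressors raise an error naming the channel", {
  x <- matrix(rnorm(60), 30, 2)
  x <- cbind(x, dup = x[, 2])
  colnames(x) <- c("a", "b", "b_copy")
  expect_error(fit_var(x, 1, center = FALSE), "b_copy|rank-deficient")
})

test_that("information criteria match their closed forms", {
  fake <- structure(
    list(order = 1L, sigma_ml = diag(2), n_obs_used = 100L,
         n_params = 4L, n_channels = 2L),
    class = "var_fit")
  expect_equal(aicc(fake), 800 / 95, tolerance = 1e-12)
  expect_equal(bic(fake), 4 * log(100), tolerance = 1e-12)

  # AICc strictly increases with det(Sigma), all else fixed
  bigger <- fake
  bigger$sigma_ml <- diag(1.5, 2)
  expect_gt(aicc(bigger), aicc(fake))
  expect_gt(bic(bigger), bic(fake))

  # undefined when the correction denominator is non-positive
  tiny <- fake
  tiny$n_obs_used <- 5L
  expect_error(aicc(tiny), "undefined")
})

test_that("estimates recover model3 at the true order on long data", {
  x <- simulate_var(var_preset("model3", 10), 100000, seed = 7)
  fit <- fit_var(x, 3)
  truth <- var_preset("model3", 10)$lag_coeffs
  for (k in 1:3) {
    expect_lt(max(abs(fit$coeff_estimates[[k]] - truth[[k]])), 0.02)
  }
})

test_that("white noise yields near-zero coefficients", {
  x <- simulate_var(var_model(list(matrix(0, 2, 2))), 10000, seed = 8)
  fit <- fit_var(x, 1)
  expect_lt(max(abs(fit$coeff_estimates[[1]])), 0.05)
})

test_that("coefficient error shrinks with sample size for every preset", {
  for (nm in c("model1", "model1b", "model2", "model3")) {
    truth <- var_preset(nm, 10)$lag_coeffs
    p <- length(truth)
    err <- sapply(c(500, 2000, 8000), function(T) {
      mean(sapply(1:3, function(s) {
        x <- simulate_var(var_preset(nm, 10), T, seed = 100 * T + s)
        fit <- fit_var(x, p)
        mean(abs(unlist(fit$coeff_estimates) - unlist(truth)))
      }))
    })
    expect_true(all(diff(err) < 0), info = nm)
  }
})

test_that("the likelihood term never worsens with added lags on a common sample", {
  set.seed(55)
  for (i in 1:5) {
    x <- simulate_var(var_preset("model2", 8), 300, seed = i)
    ldet <- sapply(1:6, function(p) {
      f <- fit_var(x, p, drop_initial = 6)
      f$n_obs_used * determinant(f$sigma_ml)$modulus
    })
    expect_true(all(diff(ldet) < 1e-8))
  }
})

test_that("order selection finds model3's order and breaks ties downward", {
  sel3 <- sapply(1:25, function(s) {
    x <- simulate_var(var_preset("model3", 10), 1000, seed = 200 + s)
    sel <- select_order(x, p_max = 8)
    c(sel$selected_order_aicc, sel$selected_order_bic)
  })
  modal <- function(v) as.integer(names(which.max(table(v))))
  expect_equal(modal(sel3[1, ]), 3)
  expect_equal(modal(sel3[2, ]), 3)

  # single candidate: selected by construction
  x <- simulate_var(var_preset("model1b", 5), 300, seed = 1)
  sel <- select_order(x, p_max = 1)
  expect_equal(sel$selected_order_aicc, 1L)
  expect_equal(sel$selected_order_bic, 1L)
})

test_that("BIC picks order 1 on white noise almost always", {
  picks <- sapply(1:100, function(s) {
    x <- simulate_var(var_model(list(matrix(0, 2, 2))), 1000,
                      seed = 300 + s)
    select_order(x, p_max = 6, criterion = "bic")$selected_order_bic
  })
  expect_gte(mean(picks == 1), 0.95)
})

test_that("BIC never selects a higher order than AICc", {
  set.seed(77)
  for (i in 1:20) {
    nm <- sample(c("model1", "model2", "model3", "model1b"), 1)
    x <- simulate_var(var_preset(nm, sample(1:20, 1)), 600, seed = 400 + i)
    sel <- select_order(x, p_max = 8)
    expect_lte(sel$selected_order_bic, sel$selected_order_aicc)
  }
})

test_that("candidates with undefined criteria are skipped with a warning", {
  x <- matrix(rnorm(40 * 4), 40, 4)  # K = 16 p quickly exceeds T
  expect_warning(sel <- select_order(x, p_max = 5), "skipped")
  expect_false(is.na(sel$selected_order_aicc))
})
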