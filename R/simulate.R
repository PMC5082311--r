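#' Simulate a VAR model
#'
#' Iterates the VAR recursion from a zero initial state with multivariate
#' Gaussian innovations, discards `burn_in` initial points, and returns the
#' remaining `n_timepoints` rows. The run is reproducible: identical
#' `(model, n_timepoints, seed, burn_in)` yield identical panels.
#'
#' Unstable models (companion spectral radius at or above 1) are refused
#' unless `force = TRUE`, because their trajectories diverge and no
#' stationary regime exists to burn in to.
#'
#' @param model a [var_model()].
#' @param n_timepoints number of time points returned.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param burn_in number of initial points discarded; must be at least the
#'   model order. Default 500 clears initialization transients for all
#'   presets at their slowest mixing.
#' @param force simulate even if the model is unstable.
#' @param sampling_interval_s optional sampling interval recorded on the
#'   returned panel.
#'
#' @return A [ts_panel()] with `n_timepoints` rows.
#' @export
#' @examples
#' m <- var_preset("model3", k = 10)
#' x <- simulate_var(m, 200, seed = 1)
simulate_var <- function(model, n_timepoints, seed = NULL, burn_in = 500,
                         force = FALSE, sampling_interval_s = NULL) {
  stopifnot(inherits(model, "var_model"))
  if (!is_count(n_timepoints))
    stop_input("`n_timepoints` must be a positive integer")
  if (!is_scalar_number(burn_in) || burn_in < model$order || burn_in != round(burn_in))
    stop_input("`burn_in` must be an integer >= model order (%d)", model$order)
  rho <- spectral_radius(model)
  if (rho >= 1 && !force)
    stop_input(paste0(
      "model is unstable (companion spectral radius %.4f >= 1); ",
      "simulation would diverge. Use force = TRUE to override."), rho)
  n <- model$n_channels
  p <- model$order
  total <- as.integer(n_timepoints + burn_in)
  L <- chol(model$noise_cov)
  values <- with_rng_seed(seed, {
    e <- matrix(stats::rnorm(total * n), total, n) %*% L
    x <- matrix(0, total, n)
    a <- model$lag_coeffs
    for (t in (p + 1L):total) {
      acc <- e[t, ]
      for (k in seq_len(p)) {
        acc <- acc + a[[k]] %*% x[t - k, ]
      }
      x[t, ] <- acc
    }
    x
  })
  ts_panel(values[(burn_in + 1L):total, , drop = FALSE],
           channel_labels = model$channel_labels,
           sampling_interval_s = sampling_interval_s)
}

#' Generate a resting-state-fMRI-like multichannel panel
#'
#' Emulates the statistical structure of ROI-averaged resting-state BOLD
#' series without any imaging data: a latent stable VAR(1) process on a fine
#' time grid (`fine_step_s`, default 0.1 s) with
#'
#' * positive diagonal lag-1 coefficients of magnitude `autocorr_strength`
#'   (slow haemodynamic-scale memory),
#' * sparse random cross couplings (Erdos-Renyi topology of density
#'   `coupling_density`, signs split 50/50) whose magnitude is
#'   `coupling_scale * (1 - autocorr_strength) / sqrt(coupling_density * (n-1))`,
#'   so the default topology remains stable at any channel count,
#' * positively correlated innovations (`noise_corr`), standing in for
#'   shared physiological/global fluctuations,
#'
#' which is then decimated to the scanner sampling grid (every
#' `round(sampling_interval_s / fine_step_s)` points) and overlaid with white
#' measurement noise of standard deviation `obs_noise_sd` times the signal's
#' standard deviation (thermal/scanner noise).
#'
#' The measurement noise and shared innovation correlation matter: they make
#' the observed process VARMA rather than VAR(1), which is what produces the
#' empirically observed behaviour of such data - a best-fitting VAR order
#' that rises at shorter sampling intervals and after bandpass filtering,
#' and a positive bias of off-diagonal lag-1 coefficients that filtering
#' attenuates.
#'
#' @param n_channels number of channels (ROIs).
#' @param n_timepoints number of returned (decimated) time points.
#' @param sampling_interval_s scanner sampling interval (TR), seconds.
#' @param autocorr_strength latent lag-1 autocorrelation in `[0, 1)`.
#' @param coupling_scale non-negative cross-coupling strength on a 0..1
#'   scale of the stability headroom; 0 disables coupling.
#' @param seed integer seed (topology and noise), or `NULL`.
#' @param noise_corr common pairwise correlation of latent innovations.
#' @param obs_noise_sd measurement-noise standard deviation relative to the
#'   latent signal's standard deviation.
#' @param coupling_density probability that an ordered channel pair is
#'   coupled.
#' @param fine_step_s latent fine time step, seconds.
#' @param burn_in fine-grid burn-in, points.
#'
#' @return A [ts_panel()] with `sampling_interval_s` recorded.
#' @export
#' @examples
#' x <- generate_fmri_like(4, 300, sampling_interval_s = 0.645, seed = 1)
generate_fmri_like <- function(n_channels, n_timepoints,
                               sampling_interval_s = 0.645,
                               autocorr_strength = 0.9,
                               coupling_scale = 0.5,
                               seed = NULL,
                               noise_corr = 0.3,
                               obs_noise_sd = 0.5,
                               coupling_density = 0.2,
                               fine_step_s = 0.1,
                               burn_in = 500) {
  if (!is_count(n_channels) || n_channels < 1)
    stop_input("`n_channels` must be a positive integer")
  if (!is_count(n_timepoints))
    stop_input("`n_timepoints` must be a positive integer")
  if (!is_scalar_number(sampling_interval_s) || sampling_interval_s <= 0)
    stop_input("`sampling_interval_s` must be positive")
  if (!is_scalar_number(autocorr_strength) ||
      autocorr_strength < 0 || autocorr_strength >= 1)
    stop_input("`autocorr_strength` must lie in [0, 1)")
  if (!is_scalar_number(coupling_scale) || coupling_scale < 0)
    stop_input("`coupling_scale` must be non-negative")
  if (!is_scalar_number(noise_corr) || noise_corr < 0 || noise_corr >= 1)
    stop_input("`noise_corr` must lie in [0, 1)")
  n <- as.integer(n_channels)
  m <- max(1L, as.integer(round(sampling_interval_s / fine_step_s)))
  with_rng_seed(seed, {
    A <- diag(autocorr_strength, n)
    if (n > 1L && coupling_scale > 0) {
      mask <- matrix(stats::runif(n * n) < coupling_density, n, n)
      diag(mask) <- FALSE
      signs <- matrix(sample(c(-1, 1), n * n, replace = TRUE), n, n)
      scale <- coupling_scale * (1 - autocorr_strength) /
        sqrt(max(1, coupling_density * (n - 1)))
      A <- A + mask * signs * scale
    }
    sigma <- matrix(noise_corr, n, n)
    diag(sigma) <- 1
    latent <- var_model(list(A), noise_cov = sigma)
    if (spectral_radius(latent) >= 1)
      stop_input(paste0(
        "implied latent model is unstable (spectral radius %.3f); ",
        "reduce `autocorr_strength` or `coupling_scale`"),
        spectral_radius(latent))
    fine <- simulate_var(latent, n_timepoints * m, seed = NULL,
                         burn_in = burn_in)
    x <- fine$values[seq(m, n_timepoints * m, by = m), , drop = FALSE]
    if (obs_noise_sd > 0) {
      s <- stats::sd(as.vector(x))
      x <- x + matrix(stats::rnorm(length(x), sd = obs_noise_sd * s),
                      nrow(x), ncol(x))
    }
    ts_panel(x, sampling_interval_s = sampling_interval_s)
  })
}
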