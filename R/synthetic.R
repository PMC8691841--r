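# Ground-truth generators: population tensors with planted rotational
# (and optionally expansive) latent dynamics, and spike-train smoothing
# utilities. These make every analysis stage testable without a trained
# network.

#' Specification for a planted-dynamics population
#'
#' Latent trajectories follow `zdot = S z` with `S` block-diagonal: one
#' 2 x 2 skew (rotation) block per plane frequency, plus an optional 1-D
#' symmetric expansion block. Each condition gets a random initial phase
#' and amplitude on the same planes (conditions share the dynamics and
#' differ in initial state). Latents are projected to units through a
#' random orthonormal loading, with additive iid Gaussian noise.
#'
#' @param n_units,n_conditions,n_steps Tensor dimensions.
#' @param frequencies Plane rotation frequencies (Hz), one per plane.
#' @param amplitudes Latent amplitude per plane (recycled).
#' @param expansion_gain Growth rate (1/s) of an extra expansion mode;
#'   0 disables it.
#' @param noise_sd Additive noise SD; overridden by `snr` when given.
#' @param snr Signal-to-noise variance ratio; sets `noise_sd` from the
#'   generated signal variance.
#' @param dt Sample interval (s).
#' @param seed RNG seed.
#' @return A list of class `planted_spec`.
#' @export
planted_spec <- function(n_units = 60, n_conditions = 8, n_steps = 30,
                         frequencies = c(2.0, 0.5), amplitudes = 1,
                         expansion_gain = 0, noise_sd = 0, snr = NULL,
                         dt = 0.010, seed = 1L) {
  stopifnot(all(frequencies >= 0),
            n_units >= 2 * length(frequencies))
  structure(list(n_units = n_units, n_conditions = n_conditions,
                 n_steps = n_steps, frequencies = frequencies,
                 amplitudes = rep_len(amplitudes, length(frequencies)),
                 expansion_gain = expansion_gain, noise_sd = noise_sd,
                 snr = snr, dt = dt, seed = seed),
            class = "planted_spec")
}

#' Generate a population tensor with planted rotational structure
#'
#' @param spec A [planted_spec()].
#' @return A [population_tensor()] (kind `"network"`) with attributes-like
#'   list fields `truth`: the true dynamics matrix `S`, the orthonormal
#'   `loadings`, the clean `latents` (latent x condition x time) and the
#'   noise SD actually used.
#' @export
planted_rotation_population <- function(spec) {
  set.seed(spec$seed)
  n_planes <- length(spec$frequencies)
  n_lat <- 2L * n_planes + as.integer(spec$expansion_gain != 0)
  S <- matrix(0, n_lat, n_lat)
  for (k in seq_len(n_planes)) {
    w <- 2 * pi * spec$frequencies[k]
    i <- 2L * k - 1L
    S[i, i + 1L] <- w
    S[i + 1L, i] <- -w
  }
  if (spec$expansion_gain != 0) S[n_lat, n_lat] <- spec$expansion_gain
  tt <- (seq_len(spec$n_steps) - 1) * spec$dt
  lat <- array(0, c(n_lat, spec$n_conditions, spec$n_steps))
  for (ci in seq_len(spec$n_conditions)) {
    for (k in seq_len(n_planes)) {
      phi <- stats::runif(1, 0, 2 * pi)
      amp <- spec$amplitudes[k] * stats::runif(1, 0.5, 1.5)
      w <- 2 * pi * spec$frequencies[k]
      i <- 2L * k - 1L
      lat[i, ci, ] <- amp * cos(w * tt + phi)
      lat[i + 1L, ci, ] <- -amp * sin(w * tt + phi)
    }
    if (spec$expansion_gain != 0) {
      z0 <- stats::rnorm(1)
      lat[n_lat, ci, ] <- z0 * exp(spec$expansion_gain * tt)
    }
  }
  Q <- qr.Q(qr(matrix(stats::rnorm(spec$n_units * n_lat), spec$n_units)))
  signal <- array(Q %*% matrix(lat, n_lat), c(spec$n_units,
                                              spec$n_conditions,
                                              spec$n_steps))
  noise_sd <- spec$noise_sd
  if (!is.null(spec$snr)) {
    noise_sd <- sqrt(stats::var(as.vector(signal)) / spec$snr)
  }
  x <- signal + array(stats::rnorm(length(signal), 0, noise_sd),
                      dim(signal))
  out <- population_tensor(x, time = tt, kind = "network")
  out$truth <- list(S = S, loadings = Q, latents = lat,
                    noise_sd = noise_sd)
  out
}

#' Smooth spike timestamps into a rate tensor
#'
#' Convolves spike times with a Gaussian kernel (SD `kernel_sd`) on the
#' simulation grid, averaging across trials. The kernel integrates to one,
#' so a lone spike contributes unit area. The causal variant uses a
#' half-Gaussian that draws only on past spikes (zero rate strictly before
#' a spike), the convention for displaying perturbation-locked responses
#' without acausal smear.
#'
#' @param spikes Tibble/data frame with columns `unit`, `condition`,
#'   `trial`, `time` (s), one row per spike.
#' @param kernel_sd Kernel standard deviation (s).
#' @param causal Use the half-Gaussian (past-only) kernel.
#' @param dt Output grid step (s).
#' @param t_range Length-2 trial time span (s); defaults to `c(0,
#'   max(spike time))`.
#' @return A [population_tensor()] of kind `"spikes"` (units x conditions
#'   x time, spikes/s).
#' @export
smooth_spikes <- function(spikes, kernel_sd = 0.030, causal = FALSE,
                          dt = 0.010, t_range = NULL) {
  if (kernel_sd < 0) stop("`kernel_sd` must be nonnegative")
  spikes <- tibble::as_tibble(spikes)
  stopifnot(all(c("unit", "condition", "trial", "time") %in%
                  names(spikes)))
  if (is.null(t_range)) t_range <- c(0, max(spikes$time))
  if (any(spikes$time < t_range[1] | spikes$time > t_range[2])) {
    stop("spike timestamps outside the trial bounds")
  }
  grid <- seq(t_range[1], t_range[2], by = dt)
  units <- sort(unique(spikes$unit))
  conds <- sort(unique(spikes$condition))
  n_trials <- length(unique(spikes$trial))
  kern <- function(delta) {
    k <- stats::dnorm(delta, sd = kernel_sd)
    if (causal) k[delta < 0] <- 0
    k
  }
  x <- array(0, c(length(units), length(conds), length(grid)))
  for (ui in seq_along(units)) {
    for (ci in seq_along(conds)) {
      st <- spikes$time[spikes$unit == units[ui] &
                          spikes$condition == conds[ci]]
      if (length(st) == 0) next
      W <- kern(outer(grid, st, `-`))
      # each spike's discrete kernel is normalized to unit area on the
      # grid (handles the half-Gaussian's jump and edge truncation)
      area <- colSums(W) * dt
      rate <- as.vector(W %*% (1 / area)) / n_trials
      x[ui, ci, ] <- rate
    }
  }
  population_tensor(x, time = grid, kind = "spikes")
}
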