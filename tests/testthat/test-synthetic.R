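test_that("noiseless single-plane latents are fit at the closed-form
          discretization values", {
  # For an exact rotation sampled at dt, the first-difference derivative is
  # zdot = [(R - I)/dt] z with R the 2x2 rotation by w*dt. The best skew
  # fit recovers exactly its skew part sin(w*dt)/dt (independent of the
  # sample correlations), the unconstrained fit is exact, and the
  # constrained residual is the symmetric part (cos(w*dt) - 1)/dt |z|.
  tens <- planted_rotation_population(
    planted_spec(n_units = 12, n_conditions = 8, n_steps = 40,
                 frequencies = 2, noise_sd = 0, seed = 1))
  dt <- 0.010; w <- 2 * pi * 2
  lat <- do.call(cbind, lapply(1:8, function(ci)
    matrix(tens$truth$latents[, ci, ], 2)))     # 2 x CT, condition-major
  dp <- rotdyn:::derivative_pairs(lat, 8, 40, dt)
  fit_u <- fit_dynamics(dp$X, dp$Xdot, constrain = FALSE)
  fit_c <- fit_dynamics(dp$X, dp$Xdot, constrain = TRUE)
  expect_equal(fit_u$r2, 1, tolerance = 1e-12)
  expect_equal(fit_c$M[1, 2], sin(w * dt) / dt, tolerance = 1e-10)
  # frozen oracle for the constrained R2
  sym <- (cos(w * dt) - 1) / dt
  resid <- sum((sym * dp$X)^2)
  denom <- sum((dp$Xdot - rowMeans(dp$Xdot))^2)
  expect_equal(fit_c$r2, 1 - resid / denom, tolerance = 1e-10)
  expect_gt(fit_c$r2, 0.99)

  # on the full projected two-plane tensor, leakage between planes is the
  # only error source: frequencies recover within the 5% property bound
  tens2 <- planted_rotation_population(
    planted_spec(n_units = 30, n_conditions = 8, n_steps = 80,
                 frequencies = c(2, 0.5), noise_sd = 0, seed = 1))
  j <- jpca(tens2, ncomp = 4)
  expect_gt(j$r2_constrained, 0.95)
  expect_gt(j$r2_unconstrained, 1 - 1e-9)
  expect_lt(abs(j$frequencies[1] - 2.0) / 2.0, 0.05)
  expect_lt(abs(j$frequencies[2] - 0.5) / 0.5, 0.05)
})

test_that("pure expansion yields high unconstrained but near-zero
          constrained fits", {
  tens <- planted_rotation_population(
    planted_spec(n_units = 30, n_conditions = 8, n_steps = 30,
                 frequencies = numeric(0), amplitudes = numeric(0),
                 expansion_gain = 2, noise_sd = 1e-6, seed = 2))
  suppressWarnings(j <- jpca(tens, ncomp = 2))
  expect_gt(j$r2_unconstrained, 0.99)
  expect_lt(j$r2_constrained, 0.05)
})

test_that("the generator is seed-deterministic and returns its ground
          truth", {
  sp <- planted_spec(seed = 7)
  t1 <- planted_rotation_population(sp)
  t2 <- planted_rotation_population(sp)
  expect_identical(t1$data, t2$data)
  expect_equal(dim(t1$truth$latents), c(4, 8, 30))
  expect_equal(t1$truth$S[1, 2], 2 * pi * 2)
  expect_equal(crossprod(t1$truth$loadings), diag(4), tolerance = 1e-12)
})

test_that("frequency recovery degrades gracefully with noise", {
  # 0.8 s of data: a 0.5 Hz plane needs an appreciable fraction of its
  # period in view to be resolvable at all
  j10 <- jpca(planted_rotation_population(
    planted_spec(n_steps = 80, snr = 10, seed = 30)), ncomp = 4)
  expect_lt(abs(j10$frequencies[1] - 2) / 2, 0.05)
  expect_lt(abs(j10$frequencies[2] - 0.5) / 0.5, 0.05)
  j3 <- jpca(planted_rotation_population(
    planted_spec(n_steps = 80, snr = 3, seed = 30)), ncomp = 4)
  expect_lt(abs(j3$frequencies[1] - 2) / 2, 0.15)
  expect_lt(abs(j3$frequencies[2] - 0.5) / 0.5, 0.15)
})

test_that("spike smoothing matches the kernel definition", {
  sp <- tibble::tibble(unit = 1, condition = 1, trial = 1, time = 0.5)
  tens <- smooth_spikes(sp, kernel_sd = 0.030, t_range = c(0, 1))
  rate <- tens$data[1, 1, ]
  grid <- tens$time
  # a Gaussian bump centered at the spike with SD 30 ms, unit integral
  expect_equal(grid[which.max(rate)], 0.5)
  expect_equal(sum(rate) * 0.010, 1, tolerance = 0.01)
  expect_equal(rate, dnorm(grid, 0.5, 0.030), tolerance = 1e-9)

  # causal kernel: zero rate strictly before the spike
  ct <- smooth_spikes(sp, kernel_sd = 0.030, causal = TRUE,
                      t_range = c(0, 1))
  crate <- ct$data[1, 1, ]
  expect_true(all(crate[grid < 0.5] == 0))
  expect_equal(sum(crate) * 0.010, 1, tolerance = 0.02)

  expect_error(smooth_spikes(sp, kernel_sd = -1), "nonnegative")
  expect_error(smooth_spikes(sp, t_range = c(0, 0.4)), "bounds")
})

test_that("homogeneous Poisson spikes smooth to their rate", {
  set.seed(15)
  r <- 20; n_trials <- 100; T_end <- 1
  rows <- lapply(seq_len(n_trials), function(tr) {
    n <- rpois(1, r * T_end)
    if (n == 0) return(NULL)
    tibble::tibble(unit = 1, condition = 1, trial = tr,
                   time = sort(runif(n, 0, T_end)))
  })
  sp <- dplyr::bind_rows(rows)
  tens <- smooth_spikes(sp, kernel_sd = 0.030, t_range = c(0, T_end))
  # interior of the trial (away from edge truncation of the kernel)
  interior <- tens$time > 0.1 & tens$time < 0.9
  est <- mean(tens$data[1, 1, interior])
  se <- sqrt(r / (n_trials * T_end))
  expect_lt(abs(est - r), 3 * se)
})
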