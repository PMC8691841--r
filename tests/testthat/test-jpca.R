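# brute-force oracle: direct numerical minimization over the
# d(d-1)/2 skew parameters
brute_force_skew <- function(X, Xdot) {
  d <- nrow(X)
  B <- rotdyn:::skew_basis(d)
  obj <- function(par) {
    M <- Reduce(`+`, Map(`*`, B, par))
    sum((Xdot - M %*% X)^2)
  }
  opt <- optim(rep(0, length(B)), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  Reduce(`+`, Map(`*`, B, opt$par))
}

test_that("preprocessing removes condition-independent signal and
          normalizes by range", {
  set.seed(5)
  x <- array(rnorm(8 * 4 * 10), c(8, 4, 10))
  # unit 3 identical in every condition -> all-zero row after centering
  common <- sin(seq_len(10))
  for (ci in 1:4) x[3, ci, ] <- common
  pp <- preprocess_tensor(population_tensor(x, kind = "network"))
  expect_equal(max(abs(pp$X[3, ])), 0)
  # with constant 0 each unit's normalized range is exactly 1
  pp0 <- preprocess_tensor(population_tensor(x, kind = "muscle"))
  arr_norm <- x / apply(x, 1, function(u) max(u) - min(u))
  expect_equal(apply(arr_norm, 1, function(u) max(u) - min(u)),
               rep(1, 8), tolerance = 1e-12)
  # kind defaults: network 5e-4, spikes 5, muscle and kinematics 0
  expect_equal(population_tensor(x, kind = "network")$softnorm, 5e-4)
  expect_equal(population_tensor(x, kind = "spikes")$softnorm, 5)
  expect_equal(population_tensor(x, kind = "muscle")$softnorm, 0)
  expect_equal(population_tensor(x, kind = "kinematics")$softnorm, 0)
  expect_error(preprocess_tensor(x, softnorm = -1), "nonnegative")
})

test_that("PCA reduction preserves variance bookkeeping", {
  set.seed(6)
  # 6-dimensional data embedded in 6 units: reduction is lossless
  z <- matrix(rnorm(6 * 120), 6, 120)
  x <- array(z, c(6, 4, 30))
  j <- jpca(population_tensor(x, kind = "network"), ncomp = 6)
  expect_equal(j$var_captured, 1, tolerance = 1e-12)
  # eigen-decomposition oracle: discarded variance = trailing eigenvalues
  x2 <- array(rnorm(20 * 4 * 30), c(20, 4, 30))
  pp <- preprocess_tensor(population_tensor(x2, kind = "network"))
  ev <- eigen(tcrossprod(pp$X), symmetric = TRUE)$values
  j2 <- jpca(population_tensor(x2, kind = "network"), ncomp = 6)
  expect_equal(j2$var_captured, sum(ev[1:6]) / sum(ev), tolerance = 1e-10)
  recon_err <- sum((pp$X - j2$basis %*% j2$X_red)^2)
  expect_equal(recon_err, sum(ev[7:20]), tolerance = 1e-8)
})

test_that("the constrained fit recovers a planted skew system exactly and
          rejects pure expansion", {
  set.seed(7)
  S <- matrix(0, 6, 6)
  S[1, 2] <- 4; S[2, 1] <- -4; S[3, 4] <- 1.5; S[4, 3] <- -1.5
  X <- matrix(rnorm(6 * 200), 6, 200)
  Xdot <- S %*% X
  fit <- fit_dynamics(X, Xdot, constrain = TRUE)
  expect_lt(max(abs(fit$M - S)), 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)

  # pure expansion Xdot = a X: the best skew fit explains nothing
  Xdot_e <- 2 * X
  fit_e <- fit_dynamics(X, Xdot_e, constrain = TRUE)
  expect_lt(fit_e$r2, 0.05)
  bf <- brute_force_skew(X, Xdot_e)
  resid_bf <- sum((Xdot_e - bf %*% X)^2)
  resid_cf <- sum((Xdot_e - fit_e$M %*% X)^2)
  expect_equal(resid_cf, resid_bf, tolerance = 1e-8)
})

test_that("closed-form skew solution matches the brute-force optimizer on
          random instances", {
  set.seed(8)
  for (i in 1:10) {
    X <- matrix(rnorm(6 * 200), 6, 200)
    Xdot <- matrix(rnorm(6 * 200), 6, 200)
    M_cf <- fit_dynamics(X, Xdot, constrain = TRUE)$M
    M_bf <- brute_force_skew(X, Xdot)
    expect_lt(norm(M_cf - M_bf, "F"), 1e-6)
  }
})

test_that("plane frequencies come from the skew eigenvalues", {
  M <- matrix(0, 6, 6)
  w <- 2 * pi * 2
  M[1, 2] <- w; M[2, 1] <- -w
  sp <- rotdyn:::skew_planes(M)
  expect_equal(sp$frequencies[1], 2, tolerance = 1e-12)
  expect_equal(sp$frequencies[2:3], c(0, 0))
  sp0 <- rotdyn:::skew_planes(matrix(0, 6, 6))
  expect_equal(sp0$frequencies, rep(0, 3))
})

test_that("jPCA recovers planted plane frequencies within 5% at SNR 10", {
  tens <- planted_rotation_population(
    planted_spec(n_units = 60, n_conditions = 8, n_steps = 80,
                 frequencies = c(2.0, 0.5), snr = 10, seed = 21))
  j <- jpca(tens, ncomp = 4)
  expect_lt(abs(j$frequencies[1] - 2.0) / 2.0, 0.05)
  expect_lt(abs(j$frequencies[2] - 0.5) / 0.5, 0.05)
})

test_that("constrained fits never beat unconstrained ones and skew fits are
          exactly antisymmetric", {
  set.seed(9)
  for (i in 1:8) {
    x <- array(rnorm(15 * 5 * 12), c(15, 5, 12))
    j <- jpca(population_tensor(x, kind = "network"), ncomp = 4)
    expect_lte(j$r2_constrained, j$r2_unconstrained + 1e-12)
    expect_equal(j$M_skew + t(j$M_skew), matrix(0, 4, 4))
    expect_true(all(j$plane_vaf >= 0))
    expect_lte(sum(j$plane_vaf), j$var_captured + 1e-10)
  }
})

test_that("glance and tidy expose the fit summaries", {
  tens <- planted_rotation_population(planted_spec(snr = 10, seed = 3))
  j <- jpca(tens)
  g <- glance(j)
  expect_equal(g$r2_ratio, g$r2_constrained / g$r2_unconstrained)
  td <- tidy(j)
  expect_equal(nrow(td), 3L)
  expect_equal(td$frequency_hz, j$frequencies)
  pt <- plane_trajectories(j, 1)
  expect_equal(nrow(pt), j$C * j$T)
})

test_that("down-sampling at k = N reproduces the full-population fit and is
          seed-deterministic", {
  tens <- planted_rotation_population(
    planted_spec(n_units = 10, n_conditions = 6, n_steps = 20,
                 frequencies = c(1.5), snr = 5, seed = 4))
  full <- jpca(tens, ncomp = 4)
  ctrl <- downsample_compare(tens, k = 10, ncomp = 4, n_iter = 5, seed = 2)
  expect_equal(unique(round(ctrl$draws$r2_constrained, 12)),
               round(full$r2_constrained, 12))
  ctrl2 <- downsample_compare(tens, k = 10, ncomp = 4, n_iter = 5, seed = 2)
  expect_identical(ctrl$draws, ctrl2$draws)
  expect_error(downsample_compare(tens, k = 11), "cannot sample")
  # empirical p: all subsample fits equal the full fit, so a smaller value
  # has p = 0 and the full value has p = 1
  expect_equal(downsample_p(ctrl, full$r2_constrained - 0.1), 0)
  expect_equal(downsample_p(ctrl, full$r2_constrained), 1)
})

test_that("down-sampled subpopulations retain most planted rotational
          structure", {
  # a k-unit subsample sees the latents through a non-orthogonal loading,
  # which genuinely distorts pure rotations: the subsample median must
  # stay clearly rotational on clean planted data but cannot exceed the
  # full population's fit
  tens <- planted_rotation_population(
    planted_spec(n_units = 40, n_conditions = 8, n_steps = 30,
                 frequencies = c(2, 0.5), noise_sd = 0, seed = 5))
  full <- jpca(tens, ncomp = 4)
  ctrl <- downsample_compare(tens, k = 6, ncomp = 4, n_iter = 40, seed = 3)
  med <- median(ctrl$draws$r2_constrained)
  expect_gt(med, 0.5)
  expect_lt(med, full$r2_constrained + 1e-8)
})
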