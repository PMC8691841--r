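test_that("leak fractions follow from the default time constants", {
  np <- network_params()
  expect_identical(np$l_n, 0.5)   # 10 ms / 20 ms
  expect_equal(np$l_m, 0.2)   # 10 ms / 50 ms
  expect_identical(np$delay_steps, 5L)
  expect_error(network_params(delay = 0.055), "multiple")
})

test_that("zero weights give a zero fixed point and biased units converge
          to tanh(b)", {
  np <- network_params(n = 4)
  w <- init_weights(np, 3, seed = 1)
  for (nm in names(w)[1:5]) w[[nm]][] <- 0
  st <- step_network(rep(0, 4), rep(0, 4), rep(0, 3), w, np)
  expect_equal(unname(as.vector(st$h)), rep(0, 4))
  expect_equal(unname(as.vector(st$o)), rep(0, 4))

  # with only a bias b_h = atanh(0.5), iterating converges to h* = 0.5
  w$b_h <- rep(atanh(0.5), 4)
  h <- rep(0, 4); o <- rep(0, 4)
  for (i in 1:200) {
    st <- step_network(h, o, rep(0, 3), w, np)
    h <- st$h; o <- st$o
  }
  expect_equal(unname(as.vector(h)), rep(0.5, 4), tolerance = 1e-10)
})

test_that("muscle layer decays under nonpositive drive and converges to a
          constant positive drive", {
  np <- network_params(n = 3)
  w <- init_weights(np, 2, seed = 1)
  w$W_ou <- matrix(-1, 6, 3)           # drive always rectified to zero
  m0 <- runif(6)
  expect_equal(unname(as.vector(step_muscle(m0, rep(1, 3), w, np))),
               0.8 * m0)
  # constant drive d: m converges geometrically to d
  w$W_ou <- matrix(0, 6, 3); w$W_ou[, 1] <- c(1, 2, 3, 4, 5, 6) / 10
  m <- rep(0, 6)
  for (i in 1:200) m <- step_muscle(m, c(1, 0, 0), w, np)
  expect_equal(unname(as.vector(m)), c(1, 2, 3, 4, 5, 6) / 10,
               tolerance = 1e-9)
})

test_that("weight initialization follows the uniform and gaussian schemes", {
  np <- network_params(n = 500)
  w <- init_weights(np, 13, seed = 2)
  expect_identical(w$b_h, rep(0, 500))
  expect_identical(w$b_o, rep(0, 500))
  expect_lte(max(abs(w$W_sh)), 1 / 13)
  expect_lte(max(abs(w$W_hh)), 1 / 500)

  npg <- network_params(n = 500, init = "gaussian", gain = 1.5)
  wg <- init_weights(npg, 13, seed = 3)
  expect_lt(abs(sd(wg$W_hh) - 1.5 / sqrt(500)) / (1.5 / sqrt(500)), 0.05)

  npl <- network_params(n = 500, init = "gaussian", gain = 1.5,
                        literal_gn = TRUE)
  wl <- init_weights(npl, 13, seed = 3)
  expect_lt(abs(sd(wl$W_hh) - 1.5 / 500) / (1.5 / 500), 0.05)

  # NO-REC recurrent matrices are exactly zero
  wn <- init_weights(network_params(n = 20, rec = FALSE), 10, seed = 1)
  expect_true(all(wn$W_hh == 0) && all(wn$W_oo == 0))
})

test_that("delayed feedback lags by exactly delay/dt samples", {
  T <- 20L
  xh <- array(0, c(4, 2, T)); mh <- array(0, c(6, 2, T))
  xh[1, 1, ] <- seq_len(T)          # ramp to read the lag off directly
  fb <- delayed_feedback(xh, mh, t = 10L, delay_steps = 5L)
  expect_equal(fb$x[1, 1], 5)
  # delay 0 is the identity
  fb0 <- delayed_feedback(xh, mh, t = 10L, delay_steps = 0L)
  expect_equal(fb0$x[1, 1], 10)
  # before the delay has elapsed, the initial sample is returned
  fb1 <- delayed_feedback(xh, mh, t = 3L, delay_steps = 5L)
  expect_equal(fb1$x[1, 1], 1)
  # an impulse at step k first appears in feedback at step k + 5
  xh[] <- 0; xh[2, 1, 8] <- 1
  seen <- vapply(seq_len(T), function(t)
    delayed_feedback(xh, mh, t, 5L)$x[2, 1], numeric(1))
  expect_equal(which(seen != 0), 13L)
  expect_error(delayed_feedback(xh, mh, 3L, 2.5), "integer")
})

test_that("rollout activities respect the tanh and rectification bounds", {
  task <- tiny_posture_task()
  np <- network_params(n = 12)
  w <- small_random_weights(np, rotdyn:::task_input_dim(task))
  b <- evaluate_network(w, task, np)
  expect_true(all(abs(b$h) < 1))
  expect_true(all(abs(b$o) < 1))
  expect_true(all(b$m >= 0))
})

test_that("NO-REC layers are memoryless: permuting a frozen input sequence
          permutes the outputs identically", {
  np <- network_params(n = 6, rec = FALSE)
  w <- small_random_weights(np, 5)
  set.seed(9)
  inputs <- matrix(rnorm(5 * 20), 5, 20)
  run <- function(ins) {
    h <- rep(0, 6); o <- rep(0, 6)
    hs <- matrix(0, 6, ncol(ins))
    for (t in seq_len(ncol(ins))) {
      st <- step_network(h, o, ins[, t], w, np)
      h <- st$h; o <- st$o
      hs[, t] <- h
    }
    hs
  }
  perm <- sample(20)
  expect_equal(run(inputs)[, perm], run(inputs[, perm]))
})

test_that("rollouts are bit-identical on replay", {
  task <- tiny_posture_task()
  np <- network_params(n = 10)
  w <- small_random_weights(np, rotdyn:::task_input_dim(task))
  b1 <- evaluate_network(w, task, np)
  b2 <- evaluate_network(w, task, np)
  expect_identical(b1$o, b2$o)
  expect_identical(b1$x, b2$x)
})

test_that("weight checkpoints survive a JSON round trip", {
  skip_if_not_installed("jsonlite")
  np <- network_params(n = 5)
  w <- small_random_weights(np, 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_weights(w, path)
  w2 <- read_weights(path)
  expect_equal(w2$W_sh, w$W_sh, tolerance = 1e-12)
  expect_equal(w2$b_o, w$b_o, tolerance = 1e-12)
})
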