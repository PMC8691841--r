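test_that("analysis windows follow the task alignment rules", {
  np <- network_params(n = 8)
  task <- posture_task()
  w <- small_random_weights(np, rotdyn:::task_input_dim(task))
  b <- evaluate_network(w, task, np)
  idx <- rotdyn:::window_indices(b, np)
  # 31 samples starting 70 ms after load onset at the 50 ms delay
  expect_equal(nrow(idx), 31L)
  expect_equal(idx[1, 1], task$events$load_on + 7L)
  # no delay: the window starts at load onset
  np0 <- network_params(n = 8, delay = 0)
  expect_equal(rotdyn:::posture_window_start(np0), 0L)
  expect_equal(rotdyn:::posture_window_start(network_params(delay = 0.1)),
               12L)
  # the null training condition is excluded from analysis tensors
  tens <- analysis_tensors(b, np)
  expect_equal(dim(tens$output$data), c(8, 8, 31))
  expect_equal(dim(tens$muscle$data)[1], 6)
  expect_equal(dim(tens$kinematics$data)[1], 4)
  expect_equal(tens$output$softnorm, 5e-4)
  expect_equal(tens$muscle$softnorm, 0)
})

test_that("current ratios are zero without recurrence and scale linearly
          with the recurrent weights", {
  task <- tiny_posture_task()
  np <- network_params(n = 10)
  w <- small_random_weights(np, rotdyn:::task_input_dim(task))
  ctrl <- structure(list(weights = w, np = np, task = task),
                    class = "trained_controller")
  b <- evaluate_network(w, task, np)
  cr <- current_ratio(ctrl, b)
  expect_equal(nrow(cr), 10L)
  expect_true(all(cr$current_ratio >= 0))

  w0 <- w; w0$W_hh[] <- 0
  ctrl0 <- ctrl; ctrl0$weights <- w0
  cr0 <- current_ratio(ctrl0, b)
  expect_equal(cr0$current_ratio, rep(0, 10))

  # doubling W_hh doubles each unit's current ratio (same rollout)
  w2 <- w; w2$W_hh <- 2 * w$W_hh
  ctrl2 <- ctrl; ctrl2$weights <- w2
  cr2 <- current_ratio(ctrl2, b)
  expect_equal(cr2$current_ratio, 2 * cr$current_ratio, tolerance = 1e-12)
  expect_equal(cr2$weight_ratio, 2 * cr$weight_ratio, tolerance = 1e-12)
})

test_that("feedback gating modes behave as specified", {
  task <- tiny_posture_task()
  np <- network_params(n = 8)
  w <- small_random_weights(np, rotdyn:::task_input_dim(task))
  bc <- evaluate_network(w, task, np, feedback_mode = "continuous")
  bn <- evaluate_network(w, task, np, feedback_mode = "none")
  bp <- evaluate_network(w, task, np, feedback_mode = "pulse")
  # without feedback the input channels stay at the initial condition
  expect_equal(bn$inputs[1:4, , 20],
               matrix(task$x0[, 1], 4, task$C), tolerance = 1e-12)
  # pulse: live only while the delayed sample is within 200 ms of the load
  on <- task$events$load_on
  live <- bp$live
  expect_false(live[on - 1L])
  expect_true(live[on + np$delay_steps])
  expect_true(all(bc$live))
})

test_that("motor noise is multiplicative, seed-stable and absent at level
          zero", {
  task <- tiny_posture_task()
  np <- network_params(n = 8)
  w <- small_random_weights(np, rotdyn:::task_input_dim(task))
  b0 <- evaluate_network(w, task, np, motor_noise = 0)
  b0b <- evaluate_network(w, task, np)
  expect_identical(b0$m, b0b$m)
  b1 <- evaluate_network(w, task, np, motor_noise = 0.8, noise_seed = 4)
  b2 <- evaluate_network(w, task, np, motor_noise = 0.8, noise_seed = 4)
  expect_identical(b1$m, b2$m)
  expect_gt(max(abs(b1$m - b0$m)), 0)
  expect_true(all(b1$m >= 0))
})

test_that("the cartesian variant feeds hand-space kinematics back", {
  task <- tiny_posture_task()
  np <- network_params(n = 8, feedback = "cartesian")
  w <- small_random_weights(np, rotdyn:::task_input_dim(task))
  b <- evaluate_network(w, task, np)
  t0 <- 12L
  d <- t0 - np$delay_steps
  hk <- hand_kinematics(b$x[, , d], task$ap)
  expect_equal(b$inputs[1:2, , t0], hk$pos, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(b$inputs[3:4, , t0], hk$vel, tolerance = 1e-12,
               ignore_attr = TRUE)
  # explicit short window: the tiny fixture trial is only 30 steps long
  tens <- analysis_tensors(b, np, window_ms = c(70, 200))
  # kinematic tensor holds hand position/velocity, not joint angles
  expect_equal(dim(tens$kinematics$data)[1], 4)
  idx <- rotdyn:::window_indices(b, np, window_ms = c(70, 200))
  expect_false(isTRUE(all.equal(tens$kinematics$data[1, 1, ],
                                b$x[1, 1, idx[, 1]])))
})

test_that("experiment reports are reproducible given seeds and expose tidy
          summaries", {
  fix <- trained_posture()
  td <- tidy(fix$report)
  expect_setequal(td$signal, c("output", "input", "muscle", "kinematics"))
  expect_true(all(td$r2_unconstrained >= td$r2_constrained))
  g <- glance(fix$report)
  expect_equal(g$task, "posture")
  # a fresh rollout + analysis from the same weights is identical
  rep2 <- run_task_experiment(fix$task, fix$np, controller = fix$ctrl)
  expect_equal(tidy(rep2), td, tolerance = 1e-12)
})

test_that("feedback decoding is accurate in time and destroyed by temporal
          shuffling", {
  fix <- trained_posture()
  dec <- decode_jpc_from_feedback(fix$report)
  expect_gt(dec$r2_overall, 0.8)
  shuf <- decode_jpc_from_feedback(fix$report, shuffle = TRUE)
  expect_lt(shuf$r2_overall, dec$r2_overall - 0.3)
})
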