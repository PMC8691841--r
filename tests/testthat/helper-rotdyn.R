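# Shared fixtures. Trained controllers are expensive, so they are built
# once per test run and cached; all fixtures are generated in code.

.fixtures <- new.env(parent = emptyenv())

# a shortened posture task (30 steps, early load onset) for gradient and
# rollout checks where full trial lengths are irrelevant
tiny_posture_task <- function(T = 30L, load_on = 10L) {
  task <- posture_task()
  lv <- task$load[, , task$T]
  task$T <- T
  task$x_star <- task$x_star[, , seq_len(T)]
  task$load <- task$load[, , seq_len(T)]
  task$load[] <- 0
  for (t in load_on:T) task$load[, , t] <- lv
  task$kin_w <- c(rep(1, load_on - 1L), rep(0, 10), rep(1, T - load_on - 9L))
  task$alpha_t <- c(rep(1e-2, load_on - 1L), rep(1e-4, T - load_on + 1L))
  task$events$load_on <- load_on
  task
}

# small random weights with nonzero biases (keeps activity off the exact
# relu/tanh kinks so finite differences are clean)
small_random_weights <- function(np, n_input, seed = 7L) {
  w <- init_weights(np, n_input, seed)
  set.seed(seed + 1L)
  for (nm in c("W_sh", "W_hh", "W_ho", "W_oo", "W_ou")) {
    if (!np$rec && nm %in% c("W_hh", "W_oo")) next
    w[[nm]] <- w[[nm]] + matrix(stats::rnorm(length(w[[nm]]), 0, 0.05),
                                nrow(w[[nm]]))
  }
  w$b_h <- stats::rnorm(np$n, 0, 0.05)
  w$b_o <- stats::rnorm(np$n, 0, 0.05)
  w
}

# desk-scale training configuration used by the slower behavioral tests
desk_cfg <- function(max_epochs = 800L) {
  train_config(lr = 1e-2, max_epochs = max_epochs, plateau_window = 150L)
}

# the reach task needs a longer budget to approach its loss plateau

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

trained_posture <- function() {
  cached("posture_rec", function() {
    task <- posture_task()
    np <- network_params(n = 100)
    ctrl <- train_network(task, np, cfg = desk_cfg(), seed = 1L)
    list(task = task, np = np, ctrl = ctrl,
         report = run_task_experiment(task, np, controller = ctrl))
  })
}

trained_posture_norec <- function() {
  cached("posture_norec", function() {
    task <- posture_task()
    np <- network_params(n = 100, rec = FALSE)
    ctrl <- train_network(task, np, cfg = desk_cfg(), seed = 1L)
    list(task = task, np = np, ctrl = ctrl,
         report = run_task_experiment(task, np, controller = ctrl))
  })
}

trained_reach <- function() {
  cached("reach_rec", function() {
    task <- reach_task()
    np <- network_params(n = 100)
    ctrl <- train_network(task, np, cfg = desk_cfg(1000L), seed = 1L)
    list(task = task, np = np, ctrl = ctrl,
         report = run_task_experiment(task, np, controller = ctrl))
  })
}

trained_tracking <- function() {
  cached("tracking_rec", function() {
    task <- tracking_task()
    np <- network_params(n = 100)
    ctrl <- train_network(task, np, cfg = desk_cfg(1000L), seed = 1L)
    list(task = task, np = np, ctrl = ctrl,
         report = run_task_experiment(task, np, controller = ctrl))
  })
}
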