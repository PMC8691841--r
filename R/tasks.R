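#' @importFrom stats dnorm rnorm runif sd quantile median setNames
#' @importFrom utils head tail
NULL

#' Loss penalty weights
#'
#' Quadratic penalty weights of the training objective: kinematic error
#' plus `alpha |m|^2 + beta |h|^2 + gamma |o|^2` summed over time, with a
#' raised muscle penalty `alpha_hold` during the posture pre-load period
#' (so muscles are not tonically active before a load arrives).
#'
#' @param alpha,beta,gamma Muscle, input-layer and output-layer penalties.
#' @param alpha_hold Muscle penalty during the posture hold period.
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 1e-4, beta = 1e-5, gamma = 1e-5,
                         alpha_hold = 1e-2) {
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 alpha_hold = alpha_hold), class = "loss_weights")
}

home_state <- function(ap) arm_state(pi / 2, pi / 4, 0, 0)

gauss_smooth_step <- function(x, sd_steps) {
  if (sd_steps <= 0) return(x)
  half <- ceiling(4 * sd_steps)
  k <- stats::dnorm(seq(-half, half), sd = sd_steps)
  k <- k / sum(k)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  stats::filter(xp, k, sides = 2)[(half + 1):(half + length(x))]
}

new_task <- function(kind, C, T, dt, x0, x_star, goal, go, load,
                     kin_w, alpha_t, lw, events, conditions, ap) {
  structure(list(kind = kind, C = C, T = T, dt = dt, x0 = x0,
                 x_star = x_star, goal = goal, go = go, load = load,
                 kin_w = kin_w, alpha_t = alpha_t, lw = lw,
                 events = events, conditions = conditions, ap = ap),
            class = c(paste0(kind, "_task"), "rotdyn_task"))
}

#' Posture perturbation task
#'
#' Hold the limb at the home posture while a constant joint torque is
#' applied after a hold period. The eight loads are the single-joint
#' flexion/extension torques and their four combinations at `magnitude`
#' N m; an optional null (no-load) condition is appended for training.
#' The network receives no explicit information about the load direction:
#' only delayed sensory feedback signals the perturbation. The kinematic
#' penalty is active during the initial hold and again from
#' `settle` seconds after load onset to the trial end.
#'
#' @param magnitude Load magnitude (N m).
#' @param include_null Append a ninth, unloaded condition (used for
#'   training; analyses use the eight loaded conditions).
#' @param pre,post Hold duration before load onset and loaded duration (s).
#' @param settle Time after load onset at which the kinematic penalty
#'   resumes (s).
#' @param lw A [loss_weights()] object.
#' @param ap An [arm_params()] object.
#' @return A task object; conditions are described in `$conditions`.
#' @export
posture_task <- function(magnitude = 0.2, include_null = TRUE,
                         pre = 0.5, post = 1.5, settle = 1.0,
                         lw = loss_weights(alpha = 1e-4, beta = 1e-5,
                                           gamma = 1e-5),
                         ap = arm_params()) {
  dt <- ap$dt
  T <- as.integer(round((pre + post) / dt))
  t_on <- as.integer(round(pre / dt)) + 1L   # first loaded step
  dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  labs <- c("SF", "SE", "EF", "EE", "SF+EF", "SF+EE", "SE+EF", "SE+EE")
  if (include_null) {
    dirs <- rbind(dirs, c(0, 0))
    labs <- c(labs, "NULL")
  }
  C <- nrow(dirs)
  loadvec <- t(dirs) * magnitude                      # 2 x C (sho, elb)
  load <- array(0, c(2L, C, T))
  for (t in t_on:T) load[, , t] <- loadvec
  x0 <- matrix(home_state(ap), 4L, C)
  x_star <- array(rep(x0, T), c(4L, C, T))
  kin_w <- numeric(T)
  kin_w[seq_len(t_on - 1L)] <- 1
  t_settle <- t_on + as.integer(round(settle / dt))
  kin_w[t_settle:T] <- 1
  alpha_t <- rep(lw$alpha, T)
  alpha_t[seq_len(t_on - 1L)] <- lw$alpha_hold
  conditions <- tibble::tibble(
    condition = seq_len(C), label = labs,
    load_sho = loadvec[1, ], load_elb = loadvec[2, ])
  new_task("posture", C, T, dt, x0, x_star, NULL, NULL, load, kin_w,
           alpha_t, lw, list(load_on = t_on, settle = t_settle),
           conditions, ap)
}

#' Delayed center-out reach task
#'
#' Hold at the home posture while the target is visible; after the GO cue
#' (a step smoothed with a 20 ms SD Gaussian kernel; high = hold,
#' low = move) the hand must acquire the target within `acquire` seconds
#' and hold it with zero velocity for the trial remainder. Targets are
#' `n_dirs` directions uniformly spaced, at each of the `dists` amplitudes.
#' The task-goal input carries the target's spatial (hand-space) position.
#'
#' @param n_dirs Number of reach directions.
#' @param dists Target distances from the home hand position (m).
#' @param delay Hold duration before the GO cue (s).
#' @param movement Post-GO duration (s).
#' @param acquire Time after GO at which the kinematic penalty resumes (s).
#' @param go_sd SD of the GO-cue smoothing kernel (s).
#' @param goal_scale Gain applied to the target's displacement from the
#'   home hand position to form the task-goal input channels. The default
#'   10 maps the centimeter-scale workspace onto roughly unit range,
#'   commensurate with the radian-scale feedback channels.
#' @param lw A [loss_weights()] object.
#' @param ap An [arm_params()] object.
#' @export
reach_task <- function(n_dirs = 16, dists = c(0.02, 0.05), delay = 0.5,
                       movement = 1.0, acquire = 0.5, go_sd = 0.020,
                       goal_scale = 10,
                       lw = loss_weights(alpha = 1e-3, beta = 1e-6,
                                         gamma = 1e-6),
                       ap = arm_params()) {
  dt <- ap$dt
  T <- as.integer(round((delay + movement) / dt))
  t_go <- as.integer(round(delay / dt)) + 1L
  home <- home_state(ap)
  hand0 <- hand_kinematics(home, ap)$pos[, 1]
  ang <- rep(2 * pi * (seq_len(n_dirs) - 1L) / n_dirs, times = length(dists))
  dist <- rep(dists, each = n_dirs)
  C <- length(ang)
  targ <- rbind(hand0[1] + dist * cos(ang), hand0[2] + dist * sin(ang))
  th_targ <- inverse_kinematics(targ, ap)
  x0 <- matrix(home, 4L, C)
  x_star <- array(0, c(4L, C, T))
  for (t in seq_len(T)) {
    if (t < t_go) {
      x_star[, , t] <- x0
    } else {
      x_star[, , t] <- rbind(th_targ["theta_elb", ], th_targ["theta_sho", ],
                             0, 0)
    }
  }
  # goal input: target displacement from home, scaled to ~unit range
  goal <- array(rep(goal_scale * (targ - hand0), T), c(2L, C, T))
  go_step <- c(rep(1, t_go - 1L), rep(0, T - t_go + 1L))
  go <- as.numeric(gauss_smooth_step(go_step, go_sd / dt))
  kin_w <- numeric(T)
  kin_w[seq_len(t_go - 1L)] <- 1
  t_acq <- t_go + as.integer(round(acquire / dt))
  kin_w[t_acq:T] <- 1
  conditions <- tibble::tibble(
    condition = seq_len(C), direction = ang, distance = dist,
    target_x = targ[1, ], target_y = targ[2, ])
  new_task("reach", C, T, dt, x0, x_star, goal, go,
           array(0, c(2L, C, T)), kin_w, rep(lw$alpha, T), lw,
           list(go_on = t_go, acquire = t_acq), conditions, ap)
}

#' Constant-velocity tracking task
#'
#' After a rest period the target moves radially outward at constant
#' velocity, reaching `dist` at the trial end; its instantaneous position
#' is fed to the network as a ramping task-goal input (no GO cue). The
#' kinematic penalty is active at every step and includes the velocity
#' components of the desired state, so the hand must match the target's
#' speed, not just its position.
#'
#' @param n_targets Number of radial directions.
#' @param dist Final target distance (m).
#' @param rest Rest duration before target motion (s).
#' @param movement Target motion duration (s).
#' @param goal_scale Gain on the target's displacement from home used for
#'   the ramping task-goal input (see [reach_task()]).
#' @param lw A [loss_weights()] object.
#' @param ap An [arm_params()] object.
#' @export
tracking_task <- function(n_targets = 15, dist = 0.05, rest = 0.3,
                          movement = 1.2, goal_scale = 10,
                          lw = loss_weights(alpha = 1e-3, beta = 1e-6,
                                            gamma = 1e-6),
                          ap = arm_params()) {
  dt <- ap$dt
  T <- as.integer(round((rest + movement) / dt))
  t_move <- as.integer(round(rest / dt)) + 1L
  home <- home_state(ap)
  hand0 <- hand_kinematics(home, ap)$pos[, 1]
  ang <- 2 * pi * (seq_len(n_targets) - 1L) / n_targets
  C <- n_targets
  x0 <- matrix(home, 4L, C)
  goal <- array(0, c(2L, C, T))
  x_star <- array(0, c(4L, C, T))
  speed <- dist / movement
  th_prev <- NULL
  for (t in seq_len(T)) {
    d <- if (t < t_move) 0 else speed * (t - t_move) * dt
    pos <- rbind(hand0[1] + d * cos(ang), hand0[2] + d * sin(ang))
    goal[, , t] <- goal_scale * (pos - hand0)
    th <- inverse_kinematics(pos, ap)
    x_star[1:2, , t] <- th[c("theta_elb", "theta_sho"), ]
    if (!is.null(th_prev)) {
      x_star[3:4, , t] <- (th[c("theta_elb", "theta_sho"), ] -
                             th_prev[c("theta_elb", "theta_sho"), ]) / dt
    }
    th_prev <- th
  }
  conditions <- tibble::tibble(condition = seq_len(C), direction = ang,
                               distance = dist)
  new_task("tracking", C, T, dt, x0, x_star, goal, NULL,
           array(0, c(2L, C, T)), rep(1, T), rep(lw$alpha, T), lw,
           list(move_on = t_move, speed = speed), conditions, ap)
}

#' Extract one trial's specification from a task
#'
#' @param task A task object from [posture_task()], [reach_task()] or
#'   [tracking_task()].
#' @param condition Condition index in `1..task$C`.
#' @return List with the per-step target trajectory, load schedule, goal
#'   input, penalty window and timing events for that condition.
#' @export
make_trial <- function(task, condition) {
  if (condition < 1 || condition > task$C) {
    stop("unknown condition index ", condition)
  }
  list(kind = task$kind, condition = condition, T = task$T, dt = task$dt,
       x0 = task$x0[, condition],
       x_star = task$x_star[, condition, , drop = TRUE],
       load = task$load[, condition, , drop = TRUE],
       goal = if (is.null(task$goal)) NULL else
         task$goal[, condition, , drop = TRUE],
       go = task$go, kin_w = task$kin_w, alpha_t = task$alpha_t,
       events = task$events,
       info = task$conditions[condition, ])
}

#' Per-trial loss
#'
#' Sum over time of the squared kinematic error (within the task's penalty
#' windows) plus the activity penalties `alpha_t |m|^2 + beta |h|^2 +
#' gamma |o|^2`. The total training cost is `J = sum_i l_i / (2 C T)`.
#'
#' @param traj List with matrices `x` (4 x T), `m` (6 x T), `h`, `o`
#'   (units x T) for one condition.
#' @param task A task object.
#' @param condition Condition index.
#' @return The scalar per-trial loss `l_i`.
#' @export
trial_loss <- function(traj, task, condition) {
  T <- ncol(traj$x)
  if (T != task$T) stop("trajectory length does not match the task")
  err <- traj$x - task$x_star[, condition, ]
  kin <- colSums(err^2) * task$kin_w
  musc <- task$alpha_t * colSums(traj$m^2)
  act <- task$lw$beta * colSums(traj$h^2) + task$lw$gamma * colSums(traj$o^2)
  sum(kin + musc + act)
}

#' Total training cost over all conditions
#'
#' @param batch A `trial_batch` from [evaluate_network()] (or any list with
#'   arrays `x`, `m`, `h`, `o` of dims signals x C x T).
#' @param task The task the batch was rolled out on.
#' @return `J = sum_i l_i / (2 C T)`.
#' @export
total_cost <- function(batch, task) {
  l <- vapply(seq_len(task$C), function(ci) {
    trial_loss(list(x = batch$x[, ci, ], m = batch$m[, ci, ],
                    h = batch$h[, ci, ], o = batch$o[, ci, ]),
               task, ci)
  }, numeric(1))
  sum(l) / (2 * task$C * task$T)
}
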