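# Forward rollout and backpropagation-through-time for the closed-loop
# controller + arm system. The rollout is vectorized across conditions:
# layer activities are n x C matrices and one R-level step advances every
# condition at once.

task_input_dim <- function(task) {
  n_goal <- if (is.null(task$goal)) 0L else dim(task$goal)[1]
  n_goal + as.integer(!is.null(task$go)) + 4L + 6L
}

# adjoint of hand_kinematics: gpos, gvel are 2 x C; returns 4 x C
hand_kin_backward <- function(state, gpos, gvel, ap) {
  s <- as_state_matrix(state)
  ths <- s[TH_S, ]; the <- s[TH_E, ]
  oms <- s[OM_S, ]; ome <- s[OM_E, ]
  s1 <- sin(ths); c1 <- cos(ths)
  s12 <- sin(ths + the); c12 <- cos(ths + the)
  l1 <- ap$l1; l2 <- ap$l2
  gx <- matrix(0, 4L, ncol(s))
  # position partials
  gx[TH_S, ] <- gpos[1, ] * (-l1 * s1 - l2 * s12) +
    gpos[2, ] * (l1 * c1 + l2 * c12)
  gx[TH_E, ] <- gpos[1, ] * (-l2 * s12) + gpos[2, ] * (l2 * c12)
  # velocity partials
  om12 <- oms + ome
  gx[TH_S, ] <- gx[TH_S, ] +
    gvel[1, ] * (-l1 * c1 * oms - l2 * c12 * om12) +
    gvel[2, ] * (-l1 * s1 * oms - l2 * s12 * om12)
  gx[TH_E, ] <- gx[TH_E, ] +
    gvel[1, ] * (-l2 * c12 * om12) + gvel[2, ] * (-l2 * s12 * om12)
  gx[OM_S, ] <- gvel[1, ] * (-l1 * s1 - l2 * s12) +
    gvel[2, ] * (l1 * c1 + l2 * c12)
  gx[OM_E, ] <- gvel[1, ] * (-l2 * s12) + gvel[2, ] * (l2 * c12)
  gx
}

feedback_live <- function(t_delayed, task, np, feedback_mode) {
  if (feedback_mode == "continuous") return(TRUE)
  if (feedback_mode == "none") return(FALSE)
  on <- task$events$load_on
  if (is.null(on)) on <- task$events$go_on
  pulse_steps <- as.integer(round(0.2 / np$dt))
  t_delayed >= on && t_delayed < on + pulse_steps
}

#' Roll out a controller on a task
#'
#' Simulates the closed loop (network, muscles, arm, delayed feedback) for
#' every condition of a task and records all trajectories. Deterministic
#' given the weights unless `motor_noise > 0`.
#'
#' @param w `controller_weights`.
#' @param task A task object.
#' @param np [network_params()].
#' @param mp [muscle_params()].
#' @param motor_noise Variance of multiplicative signal-dependent noise on
#'   the motor commands, as a fraction of the squared command (0.8 = the
#'   "80% of the motor commands" level). Applied at test time only.
#' @param feedback_mode `"continuous"` (default), `"pulse"` (sensory
#'   feedback passes only when the delayed sample falls within the first
#'   200 ms after the perturbation/GO; otherwise the channels are held at
#'   their pre-perturbation values), or `"none"` (channels held at the
#'   initial condition throughout).
#' @param noise_seed RNG seed for the motor noise.
#' @return An object of class `trial_batch`: arrays `x` (4 x C x T), `h`,
#'   `o` (n x C x T), `m` (6 x C x T), `inputs` (k x C x (T-1)), hand
#'   position `hand` (2 x C x T), plus the task and parameters.
#' @export
evaluate_network <- function(w, task, np, mp = muscle_params(),
                             motor_noise = 0,
                             feedback_mode = c("continuous", "pulse", "none"),
                             noise_seed = NULL) {
  feedback_mode <- match.arg(feedback_mode)
  fwd <- rollout_forward(w, task, np, mp, motor_noise, feedback_mode,
                         noise_seed)
  hk <- hand_kinematics(matrix(fwd$x, 4L), task$ap)
  fwd$hand <- array(hk$pos, c(2L, task$C, task$T))
  fwd$loss <- total_cost(fwd, task)
  fwd$task <- task; fwd$np <- np; fwd$mp <- mp
  class(fwd) <- "trial_batch"
  fwd
}

rollout_forward <- function(w, task, np, mp, motor_noise = 0,
                            feedback_mode = "continuous",
                            noise_seed = NULL) {
  N <- np$n; C <- task$C; T <- task$T
  delay <- np$delay_steps
  n_goal <- if (is.null(task$goal)) 0L else dim(task$goal)[1]
  has_go <- !is.null(task$go)
  k <- n_goal + as.integer(has_go) + 10L
  if (ncol(w$W_sh) != k) stop("weights expect ", ncol(w$W_sh),
                              " input channels; task provides ", k)
  x <- array(0, c(4L, C, T)); x[, , 1] <- task$x0
  h <- array(0, c(N, C, T)); o <- array(0, c(N, C, T))
  m <- array(0, c(6L, C, T))
  inputs <- array(0, c(k, C, T - 1L))
  live <- logical(T - 1L)
  if (motor_noise > 0 && !is.null(noise_seed)) set.seed(noise_seed)
  fb_rows_x <- n_goal + as.integer(has_go) + (1:4)
  fb_rows_m <- n_goal + as.integer(has_go) + (5:10)
  x0fb <- if (np$feedback == "joint") task$x0 else {
    hk0 <- hand_kinematics(task$x0, task$ap)
    rbind(hk0$pos, hk0$vel)
  }
  rec <- np$rec; l_n <- np$l_n; l_m <- np$l_m
  for (t in seq_len(T - 1L)) {
    It <- matrix(0, k, C)
    if (n_goal > 0) It[seq_len(n_goal), ] <- task$goal[, , t]
    if (has_go) It[n_goal + 1L, ] <- task$go[t]
    idx <- max(t - delay, 1L)
    live[t] <- feedback_live(idx, task, np, feedback_mode)
    if (live[t]) {
      xd <- x[, , idx]
      It[fb_rows_x, ] <- if (np$feedback == "joint") xd else {
        hk <- hand_kinematics(xd, task$ap)
        rbind(hk$pos, hk$vel)
      }
      It[fb_rows_m, ] <- m[, , idx]
    } else {
      It[fb_rows_x, ] <- x0fb
      It[fb_rows_m, ] <- 0
    }
    inputs[, , t] <- It
    ht <- h[, , t]; ot <- o[, , t]
    if (rec) {
      h[, , t + 1L] <- (1 - l_n) * ht +
        l_n * tanh(w$W_sh %*% It + w$W_hh %*% ht + w$b_h)
      o[, , t + 1L] <- (1 - l_n) * ot +
        l_n * tanh(w$W_ho %*% ht + w$W_oo %*% ot + w$b_o)
    } else {
      h[, , t + 1L] <- tanh(w$W_sh %*% It + w$b_h)
      o[, , t + 1L] <- tanh(w$W_ho %*% ht + w$b_o)
    }
    drive <- pmax(w$W_ou %*% ot, 0)
    if (motor_noise > 0) {
      eps <- matrix(stats::rnorm(6L * C), 6L, C)
      drive <- pmax(drive * (1 + sqrt(motor_noise) * eps), 0)
    }
    m[, , t + 1L] <- (1 - l_m) * m[, , t] + l_m * drive
    tau <- muscle_torques(m[, , t], x[, , t], mp)
    x[, , t + 1L] <- step_arm(x[, , t], tau, task$load[, , t], task$ap)
  }
  list(x = x, h = h, o = o, m = m, inputs = inputs, live = live)
}

# BPTT: returns gradients of the total cost J wrt all weights.
rollout_backward <- function(w, task, np, mp, fwd) {
  N <- np$n; C <- task$C; T <- task$T
  delay <- np$delay_steps
  ap <- task$ap
  n_goal <- if (is.null(task$goal)) 0L else dim(task$goal)[1]
  has_go <- !is.null(task$go)
  fb_rows_x <- n_goal + as.integer(has_go) + (1:4)
  fb_rows_m <- n_goal + as.integer(has_go) + (5:10)
  s <- 1 / (2 * C * T)
  x <- fwd$x; h <- fwd$h; o <- fwd$o; m <- fwd$m
  rec <- np$rec; l_n <- np$l_n; l_m <- np$l_m
  # direct loss adjoints
  gx <- 2 * s * (x - task$x_star) *
    rep(task$kin_w, each = 4L * C)
  gm <- 2 * s * m * rep(task$alpha_t, each = 6L * C)
  dim(gx) <- c(4L, C, T); dim(gm) <- c(6L, C, T)
  g <- list(W_sh = matrix(0, N, ncol(w$W_sh)), W_hh = matrix(0, N, N),
            W_ho = matrix(0, N, N), W_oo = matrix(0, N, N),
            W_ou = matrix(0, 6L, N), b_h = numeric(N), b_o = numeric(N))
  gh_run <- 2 * s * task$lw$beta * h[, , T]
  go_run <- 2 * s * task$lw$gamma * o[, , T]
  for (t in (T - 1L):1L) {
    ht <- h[, , t]; ot <- o[, , t]
    ghn <- gh_run; gon <- go_run
    if (rec) {
      ta <- (h[, , t + 1L] - (1 - l_n) * ht) / l_n
      tb <- (o[, , t + 1L] - (1 - l_n) * ot) / l_n
      gA <- l_n * ghn * (1 - ta^2)
      gB <- l_n * gon * (1 - tb^2)
    } else {
      gA <- ghn * (1 - h[, , t + 1L]^2)
      gB <- gon * (1 - o[, , t + 1L]^2)
    }
    drive <- (m[, , t + 1L] - (1 - l_m) * m[, , t]) / l_m
    gdrive <- l_m * gm[, , t + 1L] * (drive > 1e-12)
    It <- fwd$inputs[, , t]
    g$W_sh <- g$W_sh + tcrossprod(gA, It)
    g$b_h <- g$b_h + rowSums(gA)
    g$W_ho <- g$W_ho + tcrossprod(gB, ht)
    g$b_o <- g$b_o + rowSums(gB)
    g$W_ou <- g$W_ou + tcrossprod(gdrive, ot)
    if (rec) {
      g$W_hh <- g$W_hh + tcrossprod(gA, ht)
      g$W_oo <- g$W_oo + tcrossprod(gB, ot)
    }
    gh_run <- 2 * s * task$lw$beta * ht + crossprod(w$W_ho, gB)
    go_run <- 2 * s * task$lw$gamma * ot + crossprod(w$W_ou, gdrive)
    if (rec) {
      gh_run <- gh_run + (1 - l_n) * ghn + crossprod(w$W_hh, gA)
      go_run <- go_run + (1 - l_n) * gon + crossprod(w$W_oo, gB)
    }
    gm[, , t] <- gm[, , t] + (1 - l_m) * gm[, , t + 1L]
    pb <- plant_step_backward(x[, , t], m[, , t], gx[, , t + 1L],
                              ap, mp, task$load[, , t])
    gx[, , t] <- gx[, , t] + pb$gx
    gm[, , t] <- gm[, , t] + pb$gm
    # delayed-feedback path
    if (fwd$live[t]) {
      gI <- crossprod(w$W_sh, gA)
      idx <- max(t - delay, 1L)
      if (np$feedback == "joint") {
        gx[, , idx] <- gx[, , idx] + gI[fb_rows_x, ]
      } else {
        hkb <- hand_kin_backward(x[, , idx], gI[fb_rows_x[1:2], ],
                                 gI[fb_rows_x[3:4], ], ap)
        gx[, , idx] <- gx[, , idx] + hkb
      }
      gm[, , idx] <- gm[, , idx] + gI[fb_rows_m, ]
    }
  }
  g
}
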