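#' Training configuration
#'
#' Full-batch backpropagation through time with Adam. One epoch is one
#' gradient step over all task conditions. Training stops when the loss
#' has fallen below `loss_tol` and its 500-epoch running mean changes by
#' less than `plateau_tol`, or at `max_epochs` (with a warning flag).
#'
#' @param lr Adam step size.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param max_epochs Epoch cap.
#' @param clip Global gradient-norm clip.
#' @param loss_tol Loss level regarded as converged.
#' @param plateau_tol Running-mean loss change regarded as a plateau.
#' @param plateau_window Epochs over which the plateau is assessed.
#' @param backtrack_factor Backtracking trigger: if the loss exceeds this
#'   multiple of the best loss seen, the optimizer restores the best
#'   checkpoint, halves the learning rate and resets the Adam moments.
#'   Guards against the rectified muscle layer dying wholesale after one
#'   bad step (a collapse the plain update cannot recover from, since a
#'   fully silent readout has exactly zero gradient).
#' @param max_restarts Maximum number of backtracking events.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 3e-3, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, max_epochs = 3000L, clip = 1.0,
                         loss_tol = 5e-4, plateau_tol = 1e-6,
                         plateau_window = 500L, backtrack_factor = 1.4,
                         max_restarts = 20L) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 max_epochs = as.integer(max_epochs), clip = clip,
                 loss_tol = loss_tol, plateau_tol = plateau_tol,
                 plateau_window = as.integer(plateau_window),
                 backtrack_factor = backtrack_factor,
                 max_restarts = as.integer(max_restarts)),
            class = "train_config")
}

trainable_names <- function(np) {
  if (np$rec) c("W_sh", "W_hh", "W_ho", "W_oo", "W_ou", "b_h", "b_o")
  else c("W_sh", "W_ho", "W_ou", "b_h", "b_o")
}

#' Train a controller on a task
#'
#' Optimizes the controller weights by full-batch BPTT over all task
#' conditions, differentiating through the arm dynamics (analytic plant
#' Jacobian). NO-REC networks keep their recurrent matrices pinned at
#' exact zero throughout. Seed-reproducible.
#'
#' @param task A task object.
#' @param np [network_params()].
#' @param mp [muscle_params()].
#' @param cfg [train_config()].
#' @param seed Seed for weight initialization.
#' @param w Optional starting weights (default: fresh [init_weights()]).
#' @param feedback_mode Feedback gating used during training (see
#'   [evaluate_network()]).
#' @param verbose Print the loss every 100 epochs.
#' @return List of class `trained_controller`: `weights`, `loss_history`
#'   (tibble epoch/loss), `converged` flag, plus the task/params used.
#' @export
train_network <- function(task, np, mp = muscle_params(),
                          cfg = train_config(), seed = 1L, w = NULL,
                          feedback_mode = "continuous", verbose = FALSE) {
  if (is.null(w)) w <- init_weights(np, task_input_dim(task), seed)
  nm <- trainable_names(np)
  mom <- lapply(w[nm], function(x) x * 0)
  vel <- lapply(w[nm], function(x) x * 0)
  loss_hist <- numeric(cfg$max_epochs)
  best <- list(loss = Inf, w = w)
  converged <- FALSE
  n_epoch <- 0L
  lr_cur <- cfg$lr
  restarts <- 0L
  adam_t <- 0L
  clean <- 0L
  for (ep in seq_len(cfg$max_epochs)) {
    fwd <- rollout_forward(w, task, np, mp,
                           feedback_mode = feedback_mode)
    loss <- total_cost(fwd, task)
    if (!is.finite(loss)) {
      warning("training diverged (non-finite loss) at epoch ", ep,
              "; returning best checkpoint")
      break
    }
    loss_hist[ep] <- loss
    n_epoch <- ep
    # backtrack on collapse: restore best weights, halve lr, reset Adam;
    # after a sustained stretch of clean progress the rate recovers
    if (ep > 20L && restarts < cfg$max_restarts &&
        loss > cfg$backtrack_factor * best$loss) {
      w <- best$w
      lr_cur <- lr_cur / 2
      mom <- lapply(mom, function(x) x * 0)
      vel <- lapply(vel, function(x) x * 0)
      adam_t <- 0L
      restarts <- restarts + 1L
      clean <- 0L
      if (verbose) message(sprintf(
        "epoch %5d  backtrack #%d (loss %.3g > %.2f x best %.3g), lr -> %.3g",
        ep, restarts, loss, cfg$backtrack_factor, best$loss, lr_cur))
      next
    }
    clean <- clean + 1L
    if (clean >= 150L && lr_cur < cfg$lr) {
      lr_cur <- min(2 * lr_cur, cfg$lr)
      clean <- 0L
    }
    if (loss < best$loss) best <- list(loss = loss, w = w)
    if (verbose && ep %% 100L == 0L) {
      message(sprintf("epoch %5d  loss %.6g", ep, loss))
    }
    win <- cfg$plateau_window
    if (ep >= 2L * win && loss < cfg$loss_tol) {
      m1 <- mean(loss_hist[(ep - win + 1L):ep])
      m0 <- mean(loss_hist[(ep - 2L * win + 1L):(ep - win)])
      if (abs(m0 - m1) < cfg$plateau_tol) {
        converged <- TRUE
        break
      }
    }
    g <- rollout_backward(w, task, np, mp, fwd)
    gn <- sqrt(sum(vapply(g[nm], function(x) sum(x^2), numeric(1))))
    if (is.finite(gn) && gn > cfg$clip) {
      g[nm] <- lapply(g[nm], function(x) x * (cfg$clip / gn))
    }
    adam_t <- adam_t + 1L
    bc1 <- 1 - cfg$beta1^adam_t
    bc2 <- 1 - cfg$beta2^adam_t
    for (p in nm) {
      mom[[p]] <- cfg$beta1 * mom[[p]] + (1 - cfg$beta1) * g[[p]]
      vel[[p]] <- cfg$beta2 * vel[[p]] + (1 - cfg$beta2) * g[[p]]^2
      w[[p]] <- w[[p]] - lr_cur * (mom[[p]] / bc1) /
        (sqrt(vel[[p]] / bc2) + cfg$eps)
    }
  }
  if (!converged && best$loss > cfg$loss_tol) {
    attr(best$w, "warning") <- "not converged"
  }
  final <- if (converged) w else best$w
  structure(list(weights = final, task = task, np = np, mp = mp,
                 loss_history = tibble::tibble(
                   epoch = seq_len(n_epoch), loss = loss_hist[seq_len(n_epoch)]),
                 converged = converged, seed = seed,
                 feedback_mode = feedback_mode),
            class = "trained_controller")
}

#' @export
print.trained_controller <- function(x, ...) {
  cat("Trained controller:", x$task$kind, "task,",
      if (x$np$rec) "REC" else "NO-REC",
      sprintf("(%d units/layer)\n", x$np$n))
  cat(sprintf("  epochs: %d  final loss: %.3g  converged: %s\n",
              nrow(x$loss_history), utils::tail(x$loss_history$loss, 1),
              x$converged))
  invisible(x)
}

#' Tidy trial trajectories
#'
#' Long-format tibble of the rolled-out kinematics and muscle activity:
#' one row per condition and time step with columns `condition`, `t`,
#' `theta_sho`, `theta_elb`, `omega_sho`, `omega_elb`, `hand_x`, `hand_y`
#' and `m1`..`m6`. Suitable for writing as tidy CSV.
#'
#' @param x A `trial_batch` from [evaluate_network()].
#' @param ... Unused.
#' @method tidy trial_batch
#' @export
tidy.trial_batch <- function(x, ...) {
  C <- x$task$C; T <- x$task$T
  base <- tidyr::expand_grid(condition = seq_len(C), t = (seq_len(T) - 1) *
                               x$task$dt)
  base <- dplyr::arrange(base, .data$t, .data$condition)
  out <- tibble::tibble(
    condition = base$condition, t = base$t,
    theta_sho = as.vector(x$x[TH_S, , ]),
    theta_elb = as.vector(x$x[TH_E, , ]),
    omega_sho = as.vector(x$x[OM_S, , ]),
    omega_elb = as.vector(x$x[OM_E, , ]),
    hand_x = as.vector(x$hand[1, , ]),
    hand_y = as.vector(x$hand[2, , ]))
  for (i in 1:6) out[[paste0("m", i)]] <- as.vector(x$m[i, , ])
  dplyr::arrange(out, .data$condition, .data$t)
}

#' @export
print.trial_batch <- function(x, ...) {
  cat(sprintf("Trial batch: %s task, %d conditions x %d steps, loss %.4g\n",
              x$task$kind, x$task$C, x$task$T, x$loss))
  invisible(x)
}

#' Hand-path plot of a trial batch
#'
#' @param object A `trial_batch`.
#' @param ... Unused.
#' @return A ggplot of the endpoint paths, one line per condition.
#' @method autoplot trial_batch
#' @export
autoplot.trial_batch <- function(object, ...) {
  df <- tidy.trial_batch(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$hand_x, .data$hand_y,
                                   group = .data$condition,
                                   colour = factor(.data$condition))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "hand x (m)", y = "hand y (m)",
                  title = paste(object$task$kind, "task: hand paths"))
}
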