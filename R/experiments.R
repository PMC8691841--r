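# End-to-end experiment orchestration: trained controller -> population
# tensors in the reported analysis windows -> jPCA + TME/down-sampling ->
# report.

#' Per-condition movement onset
#'
#' First step at which the hand speed exceeds `frac` of its per-condition
#' peak.
#'
#' @param batch A `trial_batch`.
#' @param frac Fraction of peak speed.
#' @param from First step searched (defaults to the task's GO/move event,
#'   so start-of-trial transients are not mistaken for movement).
#' @return Integer vector of onset indices, one per condition.
#' @export
movement_onset <- function(batch, frac = 0.05, from = NULL) {
  task <- batch$task
  if (is.null(from)) {
    from <- task$events$go_on %||% task$events$move_on %||% 1L
  }
  hk <- hand_kinematics(matrix(batch$x, 4L), task$ap)
  speed <- matrix(sqrt(colSums(hk$vel^2)), task$C, task$T)
  apply(speed[, from:task$T, drop = FALSE], 1, function(v)
    which(v > frac * max(v))[1]) + from - 1L
}

# analysis window start (steps) for posture-type alignment: the reported
# window starts 20 ms after the sensory delay has elapsed (70 ms at the
# standard 50 ms delay); with no delay the window starts at load onset.
posture_window_start <- function(np) {
  if (np$delay_steps == 0L) 0L else np$delay_steps + 2L
}

window_indices <- function(batch, np, window_ms = NULL, dur_ms = 300) {
  task <- batch$task
  dt_ms <- task$dt * 1000
  dur <- as.integer(round(dur_ms / dt_ms))
  if (!is.null(window_ms)) {
    start <- task$events$load_on %||% task$events$go_on %||%
      task$events$move_on
    i0 <- start + as.integer(round(window_ms[1] / dt_ms))
    len <- as.integer(round((window_ms[2] - window_ms[1]) / dt_ms))
    return(matrix(rep(i0:min(i0 + len, task$T), task$C), ncol = task$C))
  }
  if (task$kind == "posture") {
    i0 <- task$events$load_on + posture_window_start(np)
    matrix(rep(i0:min(i0 + dur, task$T), task$C), ncol = task$C)
  } else if (task$kind == "reach") {
    on <- movement_onset(batch)
    on <- pmin(on, task$T - dur)
    vapply(on, function(i) i:(i + dur), integer(dur + 1L))
  } else {
    on <- as.integer(round(stats::median(movement_onset(batch))))
    matrix(rep(on:task$T, task$C), ncol = task$C)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# analysis conditions: all except a null (no-load) training condition
loaded_conditions <- function(task) {
  if ("label" %in% names(task$conditions)) {
    keep <- which(task$conditions$label != "NULL")
    if (length(keep) > 0L) return(keep)
  }
  seq_len(task$C)
}

#' Build the analysis tensors from a rolled-out batch
#'
#' Extracts output-layer, input-layer, muscle and kinematic activity over
#' the task's analysis window (posture: a 300 ms window beginning after
#' the sensory delay has elapsed; reach: the first 300 ms of movement,
#' aligned per condition; tracking: movement start to trial end) and wraps
#' each as a [population_tensor()] with its conventional
#' soft-normalization constant.
#'
#' @param batch A `trial_batch` from [evaluate_network()].
#' @param np The [network_params()] used for the rollout.
#' @param window_ms Optional explicit window (ms relative to the aligning
#'   event), length 2.
#' @return Named list of tensors: `output`, `input`, `muscle`,
#'   `kinematics`.
#' @export
analysis_tensors <- function(batch, np, window_ms = NULL) {
  task <- batch$task
  idx <- window_indices(batch, np, window_ms)
  keep <- loaded_conditions(task)
  grab <- function(a) {
    out <- array(0, c(dim(a)[1], length(keep), nrow(idx)))
    for (j in seq_along(keep)) {
      out[, j, ] <- a[, keep[j], idx[, keep[j]]]
    }
    out
  }
  kin <- if (np$feedback == "cartesian") {
    hk <- hand_kinematics(matrix(batch$x, 4L), task$ap)
    array(rbind(hk$pos, hk$vel), dim(batch$x))
  } else {
    batch$x
  }
  tt <- (idx[, 1] - idx[1, 1]) * task$dt
  list(output = population_tensor(grab(batch$o), tt, "network"),
       input = population_tensor(grab(batch$h), tt, "network"),
       muscle = population_tensor(grab(batch$m), tt, "muscle"),
       kinematics = population_tensor(grab(kin), tt, "kinematics"))
}

#' Run a full task experiment
#'
#' Trains (or reuses) a controller, rolls out every condition, builds the
#' four signal-class tensors in the reported analysis windows, and applies
#' jPCA to each: 6 components for the network layers, 4 for the muscles,
#' 2 for the kinematics. Optionally adds TME nulls for the network layers
#' and down-sampling controls for the low-dimensional signals.
#'
#' @param task A task object.
#' @param np [network_params()].
#' @param controller Optional `trained_controller` (skips training).
#' @param seed Training seed.
#' @param cfg [train_config()].
#' @param mp [muscle_params()].
#' @param n_tme Surrogates for the network-layer TME tests (0 = skip).
#' @param n_downsample Down-sampling iterations (0 = skip).
#' @param window_ms Optional explicit analysis window override.
#' @return Object of class `experiment_report`.
#' @export
run_task_experiment <- function(task, np, controller = NULL, seed = 1L,
                                cfg = train_config(), mp = muscle_params(),
                                n_tme = 0, n_downsample = 0,
                                window_ms = NULL) {
  if (is.null(controller)) {
    controller <- train_network(task, np, mp, cfg, seed = seed)
  }
  batch <- evaluate_network(controller$weights, task, np, mp)
  tensors <- analysis_tensors(batch, np, window_ms)
  fits <- list(
    output = jpca(tensors$output, ncomp = 6),
    input = jpca(tensors$input, ncomp = 6),
    muscle = jpca(tensors$muscle, ncomp = 4),
    kinematics = jpca(tensors$kinematics, ncomp = 2))
  tme <- NULL
  if (n_tme > 0) {
    tme <- list(
      output = tme_test(tensors$output, ncomp = 6, n = n_tme,
                        seed = seed + 1L),
      input = tme_test(tensors$input, ncomp = 6, n = n_tme,
                       seed = seed + 2L))
  }
  downsample <- NULL
  if (n_downsample > 0) {
    downsample <- list(
      muscle = downsample_compare(tensors$output, k = 6, ncomp = 4,
                                  n_iter = n_downsample, seed = seed + 3L),
      kinematics = downsample_compare(tensors$output, k = 4, ncomp = 2,
                                      n_iter = n_downsample,
                                      seed = seed + 4L))
  }
  structure(list(task = task, np = np, controller = controller,
                 batch = batch, tensors = tensors, fits = fits,
                 tme = tme, downsample = downsample, seed = seed),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment report: %s task, %s network (%d units)\n",
              x$task$kind, if (x$np$rec) "REC" else "NO-REC", x$np$n))
  print(tidy.experiment_report(x))
  invisible(x)
}

#' @method tidy experiment_report
#' @export
tidy.experiment_report <- function(x, ...) {
  purrr::map_dfr(names(x$fits), function(sig) {
    g <- glance.jpca(x$fits[[sig]])
    dplyr::mutate(g, signal = sig,
                  frequency1_hz = x$fits[[sig]]$frequencies[1],
                  .before = 1)
  })
}

#' @method glance experiment_report
#' @export
glance.experiment_report <- function(x, ...) {
  g <- glance.jpca(x$fits$output)
  dplyr::mutate(g,
                task = x$task$kind,
                rec = x$np$rec,
                n_units = x$np$n,
                converged = x$controller$converged,
                .before = 1)
}

#' Decode jPC-plane trajectories from sensory feedback
#'
#' Ordinary least squares from the time-aligned sensory feedback signals
#' (delayed kinematics and muscle activity, plus the GO cue and static
#' task-goal inputs where the task has them) to the output-layer jPC-plane
#' trajectories of an experiment. High decoding accuracy means the plane
#' dynamics are available in the network's inputs.
#'
#' @param report An `experiment_report`.
#' @param signal Which fitted signal class to decode (default `"output"`).
#' @param include_task_inputs Include GO cue and static goal channels.
#' @param shuffle Permute the predictors in time within each condition (a
#'   negative control that destroys the temporal alignment).
#' @param shuffle_seed Seed for the permutation.
#' @return List of class `feedback_decoding`: per-plane and overall R^2
#'   plus the fitted values.
#' @export
decode_jpc_from_feedback <- function(report, signal = "output",
                                     include_task_inputs = TRUE,
                                     shuffle = FALSE, shuffle_seed = 1L) {
  task <- report$task
  np <- report$np
  batch <- report$batch
  fit <- report$fits[[signal]]
  idx <- window_indices(batch, np)
  keep <- loaded_conditions(task)
  # predictors: what the network sees at each analyzed step
  n_goal <- if (is.null(task$goal)) 0L else dim(task$goal)[1]
  n_extra <- if (include_task_inputs)
    n_goal + as.integer(!is.null(task$go)) else 0L
  preds <- list()
  for (j in seq_along(keep)) {
    ci <- keep[j]
    cols <- vapply(idx[, ci], function(t) {
      d <- max(t - np$delay_steps, 1L)
      xd <- batch$x[, ci, d]
      fb <- if (np$feedback == "joint") xd else {
        hk <- hand_kinematics(xd, task$ap)
        c(hk$pos, hk$vel)
      }
      extra <- numeric(0)
      if (include_task_inputs) {
        if (!is.null(task$goal)) extra <- c(extra,
                                            task$goal[, ci, min(t, task$T)])
        if (!is.null(task$go)) extra <- c(extra, task$go[min(t, task$T)])
      }
      c(fb, batch$m[, ci, d], extra)
    }, numeric(10L + n_extra))
    if (shuffle) {
      set.seed(shuffle_seed + ci)
      cols <- cols[, sample.int(ncol(cols)), drop = FALSE]
    }
    preds[[j]] <- cols
  }
  P <- t(do.call(cbind, preds))                  # CT x p
  resp <- t(do.call(rbind, lapply(fit$planes, function(pl)
    crossprod(pl, fit$X_red))))                  # CT x 2K
  X <- cbind(1, P)
  beta <- qr.coef(qr(X), resp)
  beta[is.na(beta)] <- 0
  pred <- X %*% beta
  resid <- resp - pred
  center <- sweep(resp, 2, colMeans(resp))
  r2_plane <- vapply(seq_along(fit$planes), function(k) {
    cols <- (2 * k - 1):(2 * k)
    1 - sum(resid[, cols]^2) / sum(center[, cols]^2)
  }, numeric(1))
  overall <- 1 - sum(resid^2) / sum(center^2)
  structure(list(r2_plane = r2_plane, r2_overall = overall,
                 fitted = pred, observed = resp, signal = signal),
            class = "feedback_decoding")
}

#' @export
print.feedback_decoding <- function(x, ...) {
  cat(sprintf("Feedback decoding of %s-layer jPC planes: overall R2 %.3f\n",
              x$signal, x$r2_overall))
  cat("  per plane:", paste(sprintf("%.3f", x$r2_plane), collapse = ", "),
      "\n")
  invisible(x)
}

#' Intrinsic vs sensory current ratios
#'
#' For each input-layer unit of a REC network, compares the current
#' arriving through intrinsic recurrent connections (`|W_hh h|`, averaged
#' over the rollout) with the current arriving through sensory feedback
#' connections (`|W_sh I|`), alongside the bare weight-norm ratio.
#' Ratios near 0.5 mean the sensory contribution is about twice the
#' recurrent one.
#'
#' @param controller A `trained_controller`.
#' @param batch A `trial_batch` rolled out from it.
#' @return Tibble with one row per input-layer unit: `weight_ratio`
#'   (`|W_hh row| / |W_sh row|`) and `current_ratio`
#'   (mean recurrent current / mean sensory current).
#' @export
current_ratio <- function(controller, batch) {
  w <- controller$weights
  np <- controller$np
  H <- matrix(batch$h[, , seq_len(dim(batch$h)[3] - 1L)], np$n)
  K <- dim(batch$inputs)[1]
  I <- matrix(batch$inputs, K)
  rec_cur <- rowMeans(abs(w$W_hh %*% H))
  sen_cur <- rowMeans(abs(w$W_sh %*% I))
  wr <- sqrt(rowSums(w$W_hh^2)) / sqrt(rowSums(w$W_sh^2))
  if (!np$rec) {
    rec_cur <- rep(0, np$n)
    wr <- rep(0, np$n)
    warning("NO-REC network: current ratios are identically zero")
  }
  tibble::tibble(unit = seq_len(np$n), weight_ratio = wr,
                 current_ratio = rec_cur / sen_cur)
}

#' Endpoint error under motor noise
#'
#' Trains one controller per feedback mode (without noise), then tests
#' each with multiplicative signal-dependent noise on the motor commands
#' (noise variance = level x squared command) and reports the hand's
#' endpoint position error.
#'
#' @param task A task object.
#' @param np [network_params()].
#' @param modes Feedback modes to train/test (see [evaluate_network()]).
#' @param noise_levels Noise variance levels (0.8 = the 80% level).
#' @param n_rep Noisy test repetitions per level.
#' @param seed Base seed.
#' @param cfg [train_config()].
#' @param mp [muscle_params()].
#' @return Tibble: `mode`, `level`, `error` (m, mean over conditions and
#'   repetitions).
#' @export
noise_robustness <- function(task, np, modes = c("continuous", "pulse"),
                             noise_levels = c(0, 0.2, 0.4, 0.8),
                             n_rep = 5, seed = 1L, cfg = train_config(),
                             mp = muscle_params()) {
  hand_target <- function() {
    if (task$kind == "posture") {
      hand_kinematics(task$x0, task$ap)$pos
    } else {
      th <- task$x_star[, , task$T]
      hand_kinematics(rbind(th[1, ], th[2, ], 0, 0), task$ap)$pos
    }
  }
  targ <- hand_target()
  purrr::map_dfr(modes, function(md) {
    ctrl <- train_network(task, np, mp, cfg, seed = seed,
                          feedback_mode = md)
    purrr::map_dfr(noise_levels, function(lv) {
      errs <- vapply(seq_len(max(1L, n_rep * (lv > 0))), function(r) {
        b <- evaluate_network(ctrl$weights, task, np, mp,
                              motor_noise = lv, feedback_mode = md,
                              noise_seed = seed + 1000L * r)
        ep <- b$hand[, , task$T]
        mean(sqrt(colSums((ep - targ)^2)))
      }, numeric(1))
      tibble::tibble(mode = md, level = lv, error = mean(errs))
    })
  })
}

#' Sensory-delay sweep
#'
#' Trains networks at several feedback delays (several seeds each), runs
#' the task's jPCA analysis with the posture window shifted by the delay,
#' and collects fit qualities and top-plane frequencies.
#'
#' @param task_factory Zero-argument function returning the task (a fresh
#'   task per fit keeps the sweep self-contained).
#' @param delays Feedback delays (s).
#' @param n_seeds Networks per delay.
#' @param np_base [network_params()] template (its `delay` is overridden).
#' @param cfg [train_config()].
#' @param mp [muscle_params()].
#' @return Tibble: `delay`, `seed`, `r2_constrained`, `r2_unconstrained`,
#'   `frequency1_hz`, `converged`.
#' @export
delay_sweep <- function(task_factory, delays = c(0, 0.05, 0.1),
                        n_seeds = 3, np_base = network_params(),
                        cfg = train_config(), mp = muscle_params()) {
  purrr::map_dfr(delays, function(dl) {
    purrr::map_dfr(seq_len(n_seeds), function(sd_i) {
      np <- np_base
      np$delay <- dl
      np$delay_steps <- as.integer(round(dl / np$dt))
      task <- task_factory()
      rep <- run_task_experiment(task, np, seed = sd_i, cfg = cfg, mp = mp)
      tibble::tibble(delay = dl, seed = sd_i,
                     r2_constrained = rep$fits$output$r2_constrained,
                     r2_unconstrained = rep$fits$output$r2_unconstrained,
                     frequency1_hz = rep$fits$output$frequencies[1],
                     converged = rep$controller$converged)
    })
  })
}

#' Cartesian-feedback variant of a task experiment
#'
#' Identical pipeline with the kinematic feedback (and the kinematic
#' analysis tensor) expressed as hand position/velocity in cartesian
#' coordinates instead of joint angles, optionally under the
#' gaussian-gain initialization scheme.
#'
#' @param task A task object.
#' @param np [network_params()] template; feedback is set to cartesian.
#' @param init `"uniform"` or `"gaussian"`.
#' @param ... Passed to [run_task_experiment()].
#' @return An `experiment_report`.
#' @export
cartesian_variant <- function(task, np = network_params(),
                              init = c("uniform", "gaussian"), ...) {
  init <- match.arg(init)
  np$feedback <- "cartesian"
  np$init <- init
  run_task_experiment(task, np, ...)
}
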