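#' Parameters of the two-layer leaky recurrent controller
#'
#' Both layers are leaky tanh units; the muscle layer is a leaky rectified
#' linear readout. Leak fractions are `l_n = dt/tau_n` and `l_m = dt/tau_m`
#' (0.5 and 0.2 at the defaults). Sensory feedback (joint kinematics and
#' muscle activity) reaches the network after a fixed delay.
#'
#' @param n Units per layer. The full-scale setting is 500; analyses run
#'   identically at reduced sizes (100-200) for desk-scale work.
#' @param tau_n,tau_m Time constants of network and muscle units (s).
#' @param delay Sensory feedback delay (s); must be a multiple of `dt`.
#' @param dt Simulation step (s), shared with the plant.
#' @param rec Logical: intrinsic recurrent connections present? When
#'   `FALSE` (the NO-REC variant) `W_hh` and `W_oo` are pinned to zero and
#'   both layers become memoryless tanh maps of their inputs (no leak term).
#' @param init `"uniform"` for U(-1/N_inp, 1/N_inp) entries, or
#'   `"gaussian"` for N(0, (gain/sqrt(N_inp))^2).
#' @param gain Gain g of the gaussian scheme (> 1 encourages strong
#'   intrinsic dynamics).
#' @param literal_gn Use the literal sd = gain/N_inp scaling instead of
#'   gain/sqrt(N_inp) for the gaussian scheme.
#' @param feedback `"joint"` for joint angles/velocities as kinematic
#'   feedback, `"cartesian"` for hand position/velocity.
#' @return An object of class `network_params`.
#' @export
network_params <- function(n = 100, tau_n = 0.020, tau_m = 0.050,
                           delay = 0.050, dt = 0.010, rec = TRUE,
                           init = c("uniform", "gaussian"), gain = 1.5,
                           literal_gn = FALSE,
                           feedback = c("joint", "cartesian")) {
  init <- match.arg(init)
  feedback <- match.arg(feedback)
  steps <- delay / dt
  if (abs(steps - round(steps)) > 1e-9) {
    stop("`delay` must be a whole multiple of `dt`")
  }
  structure(list(n = n, tau_n = tau_n, tau_m = tau_m, delay = delay,
                 dt = dt, l_n = dt / tau_n, l_m = dt / tau_m,
                 delay_steps = as.integer(round(steps)), rec = rec,
                 init = init, gain = gain, literal_gn = literal_gn,
                 feedback = feedback),
            class = "network_params")
}

rand_weight <- function(nrow, ncol, np) {
  n_inp <- ncol
  if (np$init == "uniform") {
    matrix(stats::runif(nrow * ncol, -1 / n_inp, 1 / n_inp), nrow, ncol)
  } else {
    sd <- if (np$literal_gn) np$gain / n_inp else np$gain / sqrt(n_inp)
    matrix(stats::rnorm(nrow * ncol, 0, sd), nrow, ncol)
  }
}

#' Initialize controller weights
#'
#' Entries of each weight matrix are drawn independently with scale set by
#' that matrix's number of incoming connections (its column count); biases
#' start at zero. NO-REC networks get exact-zero recurrent matrices that
#' stay zero through training.
#'
#' @param np A [network_params()] object.
#' @param n_input Number of input channels (task goal + GO cue + delayed
#'   kinematic feedback + delayed muscle feedback).
#' @param seed Integer RNG seed, recorded in the result.
#' @return An object of class `controller_weights`: list with `W_sh`,
#'   `W_hh`, `W_ho`, `W_oo`, `W_ou`, `b_h`, `b_o`.
#' @export
init_weights <- function(np, n_input, seed = 1L) {
  set.seed(seed)
  n <- np$n
  w <- list(
    W_sh = rand_weight(n, n_input, np),
    W_hh = if (np$rec) rand_weight(n, n, np) else matrix(0, n, n),
    W_ho = rand_weight(n, n, np),
    W_oo = if (np$rec) rand_weight(n, n, np) else matrix(0, n, n),
    W_ou = rand_weight(6L, n, np),
    b_h = numeric(n),
    b_o = numeric(n))
  attr(w, "seed") <- seed
  attr(w, "n_input") <- n_input
  class(w) <- "controller_weights"
  w
}

#' One update of the network layers
#'
#' Recurrent variant:
#' `h' = (1 - l_n) h + l_n tanh(W_sh I + W_hh h + b_h)` and
#' `o' = (1 - l_n) o + l_n tanh(W_ho h + W_oo o + b_o)`.
#' NO-REC variant: memoryless `h' = tanh(W_sh I + b_h)`,
#' `o' = tanh(W_ho h + b_o)`.
#'
#' @param h,o Layer activity vectors or n x C matrices.
#' @param input Input matrix `I` (channels x C) or vector.
#' @param w A [init_weights()] object.
#' @param np A [network_params()] object.
#' @return List with updated `h` and `o`.
#' @export
step_network <- function(h, o, input, w, np) {
  h <- if (is.matrix(h)) h else matrix(h, ncol = 1L)
  o <- if (is.matrix(o)) o else matrix(o, ncol = 1L)
  input <- if (is.matrix(input)) input else matrix(input, ncol = 1L)
  if (nrow(input) != ncol(w$W_sh)) {
    stop("input dimension does not match W_sh")
  }
  if (np$rec) {
    hn <- (1 - np$l_n) * h +
      np$l_n * tanh(w$W_sh %*% input + w$W_hh %*% h + w$b_h)
    on <- (1 - np$l_n) * o +
      np$l_n * tanh(w$W_ho %*% h + w$W_oo %*% o + w$b_o)
  } else {
    hn <- tanh(w$W_sh %*% input + w$b_h)
    on <- tanh(w$W_ho %*% h + w$b_o)
  }
  list(h = hn, o = on)
}

#' One update of the muscle activations
#'
#' `m' = (1 - l_m) m + l_m max(W_ou o, 0)`, elementwise; activations stay
#' nonnegative for all time.
#'
#' @param m Muscle activation vector (length 6) or 6 x C matrix.
#' @param o Output-layer activity.
#' @param w,np Weights and parameters as in [step_network()].
#' @return Updated activations, same shape as `m`.
#' @export
step_muscle <- function(m, o, w, np) {
  m <- if (is.matrix(m)) m else matrix(m, ncol = 1L)
  o <- if (is.matrix(o)) o else matrix(o, ncol = 1L)
  (1 - np$l_m) * m + np$l_m * pmax(w$W_ou %*% o, 0)
}

#' Delayed sensory feedback from recorded histories
#'
#' Returns the plant state and muscle vector exactly `delay_steps` samples
#' in the past; before the delay has elapsed the buffer is filled with the
#' trial's initial condition (no spurious transient at t = 0).
#'
#' @param x_history,m_history Arrays with time as the last dimension
#'   (e.g. 4 x C x T and 6 x C x T), or matrices with time in columns.
#' @param t Current 1-based time index.
#' @param delay_steps Integer delay in samples.
#' @return List with `x` and `m` at the delayed index.
#' @export
delayed_feedback <- function(x_history, m_history, t, delay_steps) {
  if (delay_steps < 0 || delay_steps != round(delay_steps)) {
    stop("`delay_steps` must be a nonnegative integer")
  }
  idx <- max(t - delay_steps, 1L)
  slice_time <- function(a) {
    if (length(dim(a)) == 3L) a[, , idx, drop = TRUE] else a[, idx]
  }
  list(x = slice_time(x_history), m = slice_time(m_history))
}

#' Save / load controller weights as JSON text
#'
#' Plain-text checkpoint: weight matrices plus a metadata block (seed,
#' layer size, input dimensionality).
#'
#' @param w A `controller_weights` object.
#' @param path File path.
#' @return `read_weights()` returns the restored `controller_weights`.
#' @export
write_weights <- function(w, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write checkpoints")
  }
  payload <- list(meta = list(seed = attr(w, "seed"),
                              n_input = attr(w, "n_input"),
                              n = nrow(w$W_ho)),
                  weights = lapply(unclass(w), function(x) unname(as.matrix(x))))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  w <- lapply(payload$weights, function(x) {
    if (is.null(dim(x))) matrix(x, ncol = 1L) else as.matrix(x)
  })
  w$b_h <- drop(w$b_h); w$b_o <- drop(w$b_o)
  attr(w, "seed") <- payload$meta$seed
  attr(w, "n_input") <- payload$meta$n_input
  class(w) <- "controller_weights"
  w
}
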