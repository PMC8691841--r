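#' Population tensor
#'
#' A units x conditions x time activity array with its time base and signal
#' kind. The soft-normalization constant defaults by kind: 5e-4 for network
#' activity, 5 (spikes/s) for spike rates, 0 for muscle and kinematic
#' signals.
#'
#' @param x Numeric array, units x conditions x time (no missing values).
#' @param time Time base in seconds (defaults to a 10 ms grid from 0).
#' @param kind One of `"network"`, `"kinematics"`, `"muscle"`, `"spikes"`.
#' @param softnorm Soft-normalization constant; `NULL` picks the kind's
#'   default.
#' @return An object of class `population_tensor`.
#' @export
population_tensor <- function(x, time = NULL,
                              kind = c("network", "kinematics", "muscle",
                                       "spikes"),
                              softnorm = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.array(x), length(dim(x)) == 3L, all(is.finite(x)),
            dim(x)[3] >= 2L)
  if (is.null(softnorm)) {
    softnorm <- switch(kind, network = 5e-4, spikes = 5,
                       kinematics = 0, muscle = 0)
  }
  if (softnorm < 0) stop("softnorm constant must be nonnegative")
  if (is.null(time)) time <- (seq_len(dim(x)[3]) - 1) * 0.010
  structure(list(data = x, time = time, kind = kind, softnorm = softnorm),
            class = "population_tensor")
}

#' Soft-normalize and center a population tensor
#'
#' Each unit is divided by its activity range (over all conditions and
#' times) plus the soft-normalization constant; then the cross-condition
#' mean is subtracted at each time point, removing all condition-independent
#' signal. The result is reshaped to units x (conditions * time).
#'
#' @param tensor A [population_tensor()] (or plain 3-D array).
#' @param softnorm Override the tensor's constant.
#' @return List with the centered matrix `X` (N x CT, time fastest within
#'   condition), the normalized 3-D array `arr`, and the dimensions.
#' @export
preprocess_tensor <- function(tensor, softnorm = NULL) {
  if (!inherits(tensor, "population_tensor")) {
    tensor <- population_tensor(tensor, kind = "network",
                                softnorm = softnorm)
  }
  if (is.null(softnorm)) softnorm <- tensor$softnorm
  if (softnorm < 0) stop("softnorm constant must be nonnegative")
  a <- tensor$data
  d <- dim(a)
  rng <- apply(a, 1, function(u) max(u) - min(u))
  denom <- rng + softnorm
  # a flat signal carries no variance; leave it unscaled rather than 0/0
  denom[denom == 0] <- 1
  a <- a / denom
  cmean <- apply(a, c(1, 3), mean)              # N x T
  a <- a - aperm(array(rep(cmean, d[2]), c(d[1], d[3], d[2])), c(1, 3, 2))
  # columns condition-major: all times of condition 1, then condition 2, ...
  X <- do.call(cbind, lapply(seq_len(d[2]), function(ci)
    matrix(a[, ci, ], d[1], d[3])))
  list(X = X, arr = a, n = d[1], C = d[2], T = d[3])
}

# first-difference derivative pairs within each condition
derivative_pairs <- function(Xred, C, T, dt) {
  nc <- nrow(Xred)
  idx_t <- rep(seq_len(T - 1L), C) + rep((seq_len(C) - 1L) * T, each = T - 1L)
  Xs <- Xred[, idx_t, drop = FALSE]
  Xd <- (Xred[, idx_t + 1L, drop = FALSE] - Xs) / dt
  list(X = Xs, Xdot = Xd)
}

skew_basis <- function(d) {
  ij <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
  lapply(seq_len(nrow(ij)), function(k) {
    B <- matrix(0, d, d)
    B[ij[k, 1], ij[k, 2]] <- 1
    B[ij[k, 2], ij[k, 1]] <- -1
    B
  })
}

#' Fit linear dynamics to reduced trajectories
#'
#' Least-squares fit of `Xdot = M X`, either unconstrained or with `M`
#' restricted to the skew-symmetric subspace (solved in closed form over
#' the d(d-1)/2 basis coefficients). `R^2 = 1 - |Xdot - M X|_F^2 /
#' |Xdot - rowmean(Xdot)|_F^2`.
#'
#' @param X,Xdot d x S matrices of states and their time derivatives.
#' @param constrain Logical: restrict `M` to skew-symmetric?
#' @return List with `M` and `r2`.
#' @export
fit_dynamics <- function(X, Xdot, constrain = FALSE) {
  d <- nrow(X)
  S <- tcrossprod(X)
  G <- tcrossprod(Xdot, X)
  if (rcond(S) < 1e-12) {
    warning("X X^T nearly singular; adding a small ridge")
    S <- S + diag(1e-8 * mean(diag(S)), d)
  }
  if (constrain) {
    B <- skew_basis(d)
    K <- length(B)
    A <- matrix(0, K, K)
    b <- numeric(K)
    for (k in seq_len(K)) {
      BkS <- B[[k]] %*% S
      for (l in seq_len(K)) A[k, l] <- sum(BkS * B[[l]])
      b[k] <- sum(B[[k]] * G)
    }
    cc <- solve(A, b)
    M <- Reduce(`+`, Map(`*`, B, cc))
  } else {
    M <- G %*% solve(S)
  }
  resid <- Xdot - M %*% X
  denom <- sum((Xdot - rowMeans(Xdot))^2)
  list(M = M, r2 = 1 - sum(resid^2) / denom)
}

# planes of a skew-symmetric matrix: orthonormal 2-D bases, frequencies (Hz)
skew_planes <- function(M_skew) {
  d <- nrow(M_skew)
  e <- eigen(M_skew)
  lam <- Im(e$values)
  pos <- which(lam > 1e-12)
  # stable sort by descending eigenvalue magnitude (deterministic tie-break)
  pos <- pos[order(-lam[pos], pos)]
  n_planes <- floor(d / 2)
  planes <- list(); freqs <- numeric(0)
  for (k in seq_along(pos)) {
    v <- e$vectors[, pos[k]]
    P <- cbind(Re(v), Im(v))
    P <- qr.Q(qr(P))
    planes[[k]] <- P
    freqs[k] <- lam[pos[k]] / (2 * pi)
  }
  while (length(planes) < n_planes) {
    planes[[length(planes) + 1L]] <- matrix(0, d, 2)
    freqs <- c(freqs, 0)
  }
  list(planes = planes, frequencies = freqs)
}

#' jPCA-style rotational-dynamics analysis
#'
#' Preprocesses a population tensor (soft normalization, cross-condition
#' mean subtraction), reduces it to its top principal components,
#' differentiates within each condition, and fits both an unconstrained
#' linear dynamical system and one constrained to skew-symmetric (pure
#' rotations). The skew fit's conjugate eigenvector pairs define the jPC
#' planes, ranked by eigenvalue (rotation speed); per-plane variance
#' accounted for is measured against the total variance of the full
#' preprocessed matrix.
#'
#' @param tensor A [population_tensor()] or 3-D array (units x conditions
#'   x time).
#' @param ncomp Number of principal components retained (6 for network
#'   activity; the analyses of 4 kinematic and 6 muscle signals use 2 and
#'   4).
#' @param softnorm Override the soft-normalization constant.
#' @param dt Sample interval (s) used for the derivative.
#' @return An object of class `jpca`.
#' @export
jpca <- function(tensor, ncomp = 6, softnorm = NULL, dt = 0.010) {
  pp <- preprocess_tensor(tensor, softnorm)
  flagged <- NULL
  if (pp$n < ncomp) {
    flagged <- sprintf("only %d signals; using all of them", pp$n)
    ncomp <- pp$n
  }
  sv <- svd(pp$X)
  keep <- sum(sv$d > sv$d[1] * 1e-10)
  if (keep < ncomp) {
    flagged <- sprintf("rank %d < %d requested components", keep, ncomp)
    ncomp <- keep
  }
  U <- sv$u[, seq_len(ncomp), drop = FALSE]
  Xred <- crossprod(U, pp$X)
  var_captured <- sum(sv$d[seq_len(ncomp)]^2) / sum(sv$d^2)
  dp <- derivative_pairs(Xred, pp$C, pp$T, dt)
  fit_u <- fit_dynamics(dp$X, dp$Xdot, constrain = FALSE)
  fit_c <- fit_dynamics(dp$X, dp$Xdot, constrain = TRUE)
  sp <- skew_planes(fit_c$M)
  tot <- sum(pp$X^2)
  plane_vaf <- vapply(sp$planes, function(P) {
    sum(crossprod(P, Xred)^2) / tot
  }, numeric(1))
  structure(list(basis = U, X_red = Xred, M = fit_u$M, M_skew = fit_c$M,
                 r2_unconstrained = fit_u$r2, r2_constrained = fit_c$r2,
                 frequencies = sp$frequencies, planes = sp$planes,
                 plane_vaf = plane_vaf, var_captured = var_captured,
                 n = pp$n, C = pp$C, T = pp$T, dt = dt, ncomp = ncomp,
                 flagged = flagged),
            class = "jpca")
}

#' @export
print.jpca <- function(x, ...) {
  cat(sprintf(
    "jPCA: %d signals, %d conditions, %d steps (%d PCs)\n",
    x$n, x$C, x$T, x$ncomp))
  cat(sprintf("  R2 constrained %.3f | unconstrained %.3f | ratio %.3f\n",
              x$r2_constrained, x$r2_unconstrained,
              x$r2_constrained / x$r2_unconstrained))
  cat("  plane frequencies (Hz):",
      paste(sprintf("%.2f", x$frequencies), collapse = ", "), "\n")
  cat("  plane VAF:",
      paste(sprintf("%.1f%%", 100 * x$plane_vaf), collapse = ", "), "\n")
  if (!is.null(x$flagged)) cat("  note:", x$flagged, "\n")
  invisible(x)
}

#' @method tidy jpca
#' @export
tidy.jpca <- function(x, ...) {
  tibble::tibble(plane = seq_along(x$frequencies),
                 frequency_hz = x$frequencies,
                 vaf = x$plane_vaf)
}

#' @method glance jpca
#' @export
glance.jpca <- function(x, ...) {
  tibble::tibble(r2_constrained = x$r2_constrained,
                 r2_unconstrained = x$r2_unconstrained,
                 r2_ratio = x$r2_constrained / x$r2_unconstrained,
                 top2_vaf = sum(x$plane_vaf[1:min(2, length(x$plane_vaf))]),
                 var_captured = x$var_captured,
                 n_signals = x$n, n_conditions = x$C, n_steps = x$T)
}

#' Plane-trajectory coordinates of a jPCA fit
#'
#' @param x A `jpca` object.
#' @param planes Which planes to extract.
#' @return Tibble with columns `plane`, `condition`, `t`, `jpc1`, `jpc2`.
#' @export
plane_trajectories <- function(x, planes = seq_along(x$planes)) {
  purrr::map_dfr(planes, function(k) {
    proj <- crossprod(x$planes[[k]], x$X_red)     # 2 x CT
    tibble::tibble(plane = k,
                   condition = rep(seq_len(x$C), each = x$T),
                   t = rep((seq_len(x$T) - 1) * x$dt, x$C),
                   jpc1 = proj[1, ], jpc2 = proj[2, ])
  })
}

#' @method autoplot jpca
#' @export
autoplot.jpca <- function(object, planes = 1:2, ...) {
  df <- plane_trajectories(object, planes)
  ggplot2::ggplot(df, ggplot2::aes(.data$jpc1, .data$jpc2,
                                   group = .data$condition,
                                   colour = factor(.data$condition))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::facet_wrap(~plane, scales = "free",
                        labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "jPC 1", y = "jPC 2")
}

#' Down-sampling control for low-dimensional signals
#'
#' Muscle (6) and kinematic (4) recordings have far fewer signals than a
#' neural population, which depresses dynamical fits. This control samples
#' `k` units without replacement from the population, reruns the full jPCA
#' analysis on each subsample, and returns the distribution of fits. The
#' empirical probability that a comparison value is exceeded is the
#' fraction of iterations at or below it.
#'
#' @param tensor A [population_tensor()] (network/neural activity).
#' @param k Signals per subsample (6 to match muscles, 4 for kinematics).
#' @param ncomp Components used in the subsample jPCA (4 to match the
#'   muscle analysis, 2 for kinematics).
#' @param n_iter Number of random subsamples.
#' @param seed RNG seed.
#' @return Object of class `downsample_control` with a tibble `draws`
#'   (`r2_constrained`, `r2_unconstrained` per iteration).
#' @export
downsample_compare <- function(tensor, k, ncomp = min(k, 6), n_iter = 1000,
                               seed = 1L) {
  if (!inherits(tensor, "population_tensor")) {
    tensor <- population_tensor(tensor, kind = "network")
  }
  N <- dim(tensor$data)[1]
  if (k > N) stop("cannot sample ", k, " units from ", N)
  set.seed(seed)
  draws <- purrr::map_dfr(seq_len(n_iter), function(i) {
    idx <- sample.int(N, k)
    sub <- population_tensor(tensor$data[idx, , , drop = FALSE],
                             time = tensor$time, kind = tensor$kind,
                             softnorm = tensor$softnorm)
    j <- jpca(sub, ncomp = ncomp)
    tibble::tibble(iter = i, r2_constrained = j$r2_constrained,
                   r2_unconstrained = j$r2_unconstrained)
  })
  structure(list(draws = draws, k = k, ncomp = ncomp, seed = seed),
            class = "downsample_control")
}

#' Empirical probability from a down-sampling control
#'
#' @param ctrl A `downsample_control`.
#' @param value Observed fit (e.g. the muscle R^2).
#' @param which `"constrained"` or `"unconstrained"`.
#' @return Fraction of subsample fits at or below `value`.
#' @export
downsample_p <- function(ctrl, value, which = c("constrained",
                                                "unconstrained")) {
  which <- match.arg(which)
  col <- paste0("r2_", which)
  mean(ctrl$draws[[col]] <= value)
}
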