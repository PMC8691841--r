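# Tensor-maximum-entropy surrogates: the maximum-entropy Gaussian
# distribution over units x conditions x time tensors whose expected
# covariance along each mode matches the data's, destroying all
# higher-order (cross-mode) structure such as coherent rotations.

#' Mode-wise covariances of a population tensor
#'
#' Scatter matrices along each tensor mode after removing the grand mean:
#' the unit covariance marginalizes over conditions and time, and so on.
#' Should be computed on the same preprocessed tensor that the observed
#' statistic uses.
#'
#' @param x 3-D array (units x conditions x time) or
#'   [population_tensor()].
#' @return List of class `mode_covariances` with `unit` (N x N),
#'   `condition` (C x C), `time` (T x T) and the grand `mean`.
#' @export
mode_covariances <- function(x) {
  if (inherits(x, "population_tensor")) x <- x$data
  stopifnot(is.array(x), length(dim(x)) == 3L)
  d <- dim(x)
  mu <- mean(x)
  xc <- x - mu
  unf <- function(a, mode) {
    perm <- c(mode, setdiff(1:3, mode))
    matrix(aperm(a, perm), d[mode])
  }
  structure(list(unit = tcrossprod(unf(xc, 1)),
                 condition = tcrossprod(unf(xc, 2)),
                 time = tcrossprod(unf(xc, 3)),
                 mean = mu, dim = d),
            class = "mode_covariances")
}

# Solve for the Lagrange multipliers of the maximum-entropy energy.
# The eigenvectors of each mode covariance are eigenvectors of the joint
# covariance; its eigenvalues are 1/(lu_i + lc_j + lt_k) and the
# multipliers are chosen so each mode's marginal eigenvalues match.
tme_multipliers <- function(ev_u, ev_c, ev_t, tol = 1e-9,
                            maxit = 2000L) {
  N <- length(ev_u); C <- length(ev_c); T <- length(ev_t)
  scale <- sum(ev_u)
  # common total mass across modes (equal up to numerical error)
  target <- list(u = ev_u, c = ev_c, t = ev_t)
  # work on the N x (C*T) unfolding; column ct indexes (c, t) column-major
  mode_sums <- function(M) {
    byu <- rowSums(M)
    ct <- matrix(colSums(M), C, T)
    list(u = byu, c = rowSums(ct), t = colSums(ct))
  }
  fg <- function(par) {
    lu <- par[1:N]; lc <- par[N + (1:C)]; lt <- par[N + C + (1:T)]
    sct <- as.vector(outer(lc, lt, `+`))
    Ssum <- outer(lu, sct, `+`)
    if (any(Ssum <= 1e-14)) {
      return(list(f = 1e12 * (1 + sum(pmax(1e-14 - Ssum, 0))), g = NULL))
    }
    D <- 1 / Ssum
    ms <- mode_sums(D)
    ru <- ms$u - target$u; rc <- ms$c - target$c; rt <- ms$t - target$t
    f <- sum(ru^2) + sum(rc^2) + sum(rt^2)
    W <- (outer(ru, as.vector(outer(rc, rt, `+`)), `+`)) * D^2
    ws <- mode_sums(W)
    g <- -2 * c(ws$u, ws$c, ws$t)
    list(f = f, g = g)
  }
  init <- c(C * T / (3 * ev_u), N * T / (3 * ev_c), N * C / (3 * ev_t))
  opt <- stats::optim(init, fn = function(p) fg(p)$f,
                      gr = function(p) {
                        r <- fg(p)
                        if (is.null(r$g)) numeric(length(p)) else r$g
                      },
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  final <- fg(opt$par)
  rel <- sqrt(final$f) / scale
  if (!is.finite(rel) || rel > 1e-2) {
    stop(sprintf(
      "TME multiplier optimization did not converge (relative residual %.2g)",
      rel))
  }
  list(lu = opt$par[1:N], lc = opt$par[N + (1:C)],
       lt = opt$par[N + C + (1:T)], residual = rel)
}

mode_product <- function(a, Q, mode) {
  d <- dim(a)
  perm <- c(mode, setdiff(1:3, mode))
  m <- matrix(aperm(a, perm), d[mode])
  out <- Q %*% m
  d2 <- d; d2[mode] <- nrow(Q)
  aperm(array(out, d2[perm]), order(perm))
}

#' Sampler for tensor-maximum-entropy surrogates
#'
#' Builds the maximum-entropy Gaussian tensor distribution whose expected
#' mode-wise covariances match the given ones (eigendecompose each mode
#' covariance, numerically solve for the Lagrange multipliers of the
#' maximum-entropy energy over the Kronecker-structured eigenvalue tensor,
#' then sample by scaled mode products). Rank-deficient covariances are
#' handled by flooring eigenvalues at 1e-10.
#'
#' @param cov A [mode_covariances()] object.
#' @return A function of no arguments; each call returns one surrogate
#'   tensor (units x conditions x time). Seed the R RNG before calling for
#'   reproducibility.
#' @export
tme_sampler <- function(cov) {
  eu <- eigen(cov$unit, symmetric = TRUE)
  ec <- eigen(cov$condition, symmetric = TRUE)
  et <- eigen(cov$time, symmetric = TRUE)
  floor_ev <- function(v) pmax(v, 1e-10)
  mult <- tme_multipliers(floor_ev(eu$values), floor_ev(ec$values),
                          floor_ev(et$values))
  d <- cov$dim
  Ssum <- outer(mult$lu, as.vector(outer(mult$lc, mult$lt, `+`)), `+`)
  sqrt_d <- array(sqrt(1 / Ssum), d)
  function() {
    z <- array(stats::rnorm(prod(d)), d) * sqrt_d
    z <- mode_product(z, eu$vectors, 1)
    z <- mode_product(z, ec$vectors, 2)
    z <- mode_product(z, et$vectors, 3)
    z + cov$mean
  }
}

#' Sample TME surrogate tensors
#'
#' @param cov A [mode_covariances()] object.
#' @param n Number of surrogates.
#' @param seed RNG seed.
#' @return List of `n` surrogate arrays.
#' @export
sample_surrogates <- function(cov, n, seed = 1L) {
  set.seed(seed)
  sampler <- tme_sampler(cov)
  replicate(n, sampler(), simplify = FALSE)
}

# PCA + dynamical fits on an already-centered N x CT matrix
jpca_core <- function(X, C, T, ncomp, dt) {
  sv <- svd(X, nu = ncomp, nv = 0)
  U <- sv$u[, seq_len(ncomp), drop = FALSE]
  Xred <- crossprod(U, X)
  dp <- derivative_pairs(Xred, C, T, dt)
  c(constrained = fit_dynamics(dp$X, dp$Xdot, TRUE)$r2,
    unconstrained = fit_dynamics(dp$X, dp$Xdot, FALSE)$r2)
}

#' TME hypothesis test for rotational structure
#'
#' Compares the observed constrained/unconstrained dynamical fits to the
#' distribution over maximum-entropy surrogates that share the data's
#' mode-wise covariances (unit tuning breadth, condition covariance,
#' temporal smoothness) but none of its cross-mode interactions.
#' P-values use the add-one convention
#' `p = (1 + #{surrogate R2 >= observed}) / (n + 1)`.
#'
#' The test is unreliable for small populations; a warning is issued below
#' 30 units. Surrogates are generated from (and compared on) the
#' preprocessed tensor, matching the statistic's input.
#'
#' @param tensor A [population_tensor()] or 3-D array.
#' @param ncomp Principal components for the jPCA fits.
#' @param n Number of surrogates (1000 in the full analysis).
#' @param seed RNG seed.
#' @param softnorm Override soft-normalization of the observed tensor.
#' @param dt Sample interval (s).
#' @param cov Optional [mode_covariances()] to draw surrogates from.
#'   By default the covariances are estimated from the preprocessed
#'   observed tensor (the plug-in procedure used in practice); passing a
#'   known covariance makes observed and surrogates exactly exchangeable,
#'   which the calibration tests rely on.
#' @return Object of class `tme_null` with observed fits, the surrogate
#'   draws, and p-values.
#' @export
tme_test <- function(tensor, ncomp = 6, n = 1000, seed = 1L,
                     softnorm = NULL, dt = 0.010, cov = NULL) {
  if (!inherits(tensor, "population_tensor")) {
    tensor <- population_tensor(tensor, kind = "network",
                                softnorm = softnorm)
  }
  sn <- if (is.null(softnorm)) tensor$softnorm else softnorm
  pp <- preprocess_tensor(tensor, sn)
  if (pp$n < 30) {
    warning("TME hypothesis testing is unreliable below 30 units (have ",
            pp$n, ")")
  }
  if (n < 100) warning("fewer than 100 surrogates: p-value resolution is ",
                       signif(1 / (n + 1), 2))
  obs <- jpca_core(pp$X, pp$C, pp$T, ncomp, dt)
  if (is.null(cov)) cov <- mode_covariances(pp$arr)
  set.seed(seed)
  sampler <- tme_sampler(cov)
  draws <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    # each surrogate passes through the identical preprocessing as the
    # observed tensor, keeping the two exchangeable under the null
    pps <- preprocess_tensor(sampler(), softnorm = sn)
    draws[i, ] <- jpca_core(pps$X, pp$C, pp$T, ncomp, dt)
  }
  draws <- tibble::tibble(iter = seq_len(n),
                          r2_constrained = draws[, 1],
                          r2_unconstrained = draws[, 2])
  p_c <- (1 + sum(draws$r2_constrained >= obs["constrained"])) / (n + 1)
  p_u <- (1 + sum(draws$r2_unconstrained >= obs["unconstrained"])) / (n + 1)
  structure(list(observed = obs, draws = draws,
                 p_constrained = p_c, p_unconstrained = p_u,
                 n = n, seed = seed, n_units = pp$n),
            class = "tme_null")
}

#' @export
print.tme_null <- function(x, ...) {
  cat(sprintf(
    "TME null (%d surrogates, %d units)\n", x$n, x$n_units))
  cat(sprintf("  constrained:   observed R2 %.3f | median null %.3f | p = %.4g\n",
              x$observed["constrained"],
              stats::median(x$draws$r2_constrained), x$p_constrained))
  cat(sprintf("  unconstrained: observed R2 %.3f | median null %.3f | p = %.4g\n",
              x$observed["unconstrained"],
              stats::median(x$draws$r2_unconstrained), x$p_unconstrained))
  invisible(x)
}

#' @method tidy tme_null
#' @export
tidy.tme_null <- function(x, ...) x$draws

#' @method glance tme_null
#' @export
glance.tme_null <- function(x, ...) {
  tibble::tibble(
    r2_constrained = unname(x$observed["constrained"]),
    r2_unconstrained = unname(x$observed["unconstrained"]),
    null_median_constrained = stats::median(x$draws$r2_constrained),
    null_iqr_constrained = stats::IQR(x$draws$r2_constrained),
    null_median_unconstrained = stats::median(x$draws$r2_unconstrained),
    p_constrained = x$p_constrained,
    p_unconstrained = x$p_unconstrained,
    n_surrogates = x$n)
}

#' @method autoplot tme_null
#' @export
autoplot.tme_null <- function(object, ...) {
  df <- tidyr::pivot_longer(object$draws, -"iter",
                            names_to = "fit", values_to = "r2")
  obs <- tibble::tibble(
    fit = c("r2_constrained", "r2_unconstrained"),
    r2 = unname(object$observed))
  ggplot2::ggplot(df, ggplot2::aes(.data$r2)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$r2),
                        colour = "black", linewidth = 1) +
    ggplot2::facet_wrap(~fit, scales = "free") +
    ggplot2::labs(x = expression(R^2), y = "surrogates")
}
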