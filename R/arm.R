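#' Parameters of the planar two-link arm
#'
#' Rigid-body parameters of a shoulder+elbow arm restricted to the horizontal
#' plane (no gravity term). Defaults are the widely used planar-arm set from
#' the optimal-control literature. The arm state vector is ordered
#' `[theta_elb, theta_sho, omega_elb, omega_sho]` (radians, rad/s); torque
#' vectors are ordered `[shoulder, elbow]` (N m).
#'
#' @param l1,l2 Upper-arm and forearm lengths (m).
#' @param m1,m2 Link masses (kg).
#' @param i1,i2 Link moments of inertia (kg m^2).
#' @param d1,d2 Distances from the proximal joint to each link's center of
#'   mass (m).
#' @param viscosity Joint viscosity (N m s/rad), applied at both joints.
#' @param dt Integration time step (s); the simulation grid is 10 ms.
#' @return An object of class `arm_params`.
#' @export
arm_params <- function(l1 = 0.30, l2 = 0.33, m1 = 1.4, m2 = 1.0,
                       i1 = 0.025, i2 = 0.045, d1 = 0.11, d2 = 0.16,
                       viscosity = 0.05, dt = 0.010) {
  stopifnot(l1 > 0, l2 > 0, m1 > 0, m2 > 0, i1 > 0, i2 > 0,
            d1 > 0, d2 > 0, viscosity >= 0, dt > 0)
  p <- list(l1 = l1, l2 = l2, m1 = m1, m2 = m2, i1 = i1, i2 = i2,
            d1 = d1, d2 = d2, viscosity = viscosity, dt = dt)
  # inertia-matrix coefficients (Li & Todorov parameterization)
  p$a1 <- i1 + i2 + m2 * l1^2
  p$a2 <- m2 * l1 * d2
  p$a3 <- i2
  class(p) <- "arm_params"
  p
}

#' Parameters of the six lumped muscle actuators
#'
#' Six muscles: shoulder flexor/extensor, elbow flexor/extensor, and a
#' biarticular flexor/extensor pair. Moment arms are constant
#' (state-independent). Muscle force is
#' `activation * f_max * FL(lnorm) * FV(vnorm)` where normalized length and
#' velocity are linear in the joint state through the moment-arm matrix:
#' `lnorm = 1 - R (theta - theta_ref) / l0`, `vnorm = -R omega / l0`.
#' FL is a Gaussian bump centered at the optimal length; FV is a piecewise
#' hyperbola with `FV(0) = 1`, saturating at `fv_max` for lengthening and
#' reaching zero at shortening velocity `-v_max`.
#'
#' @param moment_arms 6 x 2 matrix (m); columns are (shoulder, elbow) joints.
#'   Monoarticular muscles have exactly one nonzero entry, biarticulars two.
#' @param f_max Maximal isometric forces (N), length 6.
#' @param l0 Optimal muscle length used for normalization (m).
#' @param theta_ref Joint angles (shoulder, elbow; rad) at which every muscle
#'   sits at its optimal length. Defaults to the workspace home posture.
#' @param fl_width Width of the Gaussian force-length curve (normalized).
#' @param fv_max Force-velocity saturation for lengthening.
#' @param v_max Maximal shortening velocity (optimal lengths per second).
#' @param fv_curv Curvature constant of the lengthening hyperbola.
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(moment_arms = NULL,
                          f_max = c(40, 40, 30, 30, 25, 25),
                          l0 = 0.10,
                          theta_ref = c(pi / 4, pi / 2),
                          fl_width = 0.3, fv_max = 1.3,
                          v_max = 10, fv_curv = 1) {
  if (is.null(moment_arms)) {
    moment_arms <- rbind(
      c( 0.020,  0.000),   # shoulder flexor
      c(-0.020,  0.000),   # shoulder extensor
      c( 0.000,  0.020),   # elbow flexor
      c( 0.000, -0.020),   # elbow extensor
      c( 0.015,  0.020),   # biarticular flexor
      c(-0.015, -0.020))   # biarticular extensor
    rownames(moment_arms) <- c("sho_flex", "sho_ext", "elb_flex",
                               "elb_ext", "bi_flex", "bi_ext")
  }
  stopifnot(nrow(moment_arms) == 6, ncol(moment_arms) == 2,
            length(f_max) == 6, all(f_max > 0), l0 > 0)
  nz <- rowSums(moment_arms != 0)
  stopifnot(all(nz[1:4] == 1), all(nz[5:6] == 2))
  structure(list(moment_arms = moment_arms, f_max = f_max, l0 = l0,
                 theta_ref = theta_ref, fl_width = fl_width,
                 fv_max = fv_max, v_max = v_max, fv_curv = fv_curv),
            class = "muscle_params")
}

# state component indices: [theta_elb, theta_sho, omega_elb, omega_sho]
TH_E <- 1L; TH_S <- 2L; OM_E <- 3L; OM_S <- 4L

#' Arm state vector(s)
#'
#' @param theta_elb,theta_sho Joint angles (rad).
#' @param omega_elb,omega_sho Joint angular velocities (rad/s).
#' @return A length-4 state vector ordered
#'   `[theta_elb, theta_sho, omega_elb, omega_sho]`.
#' @export
arm_state <- function(theta_elb, theta_sho, omega_elb = 0, omega_sho = 0) {
  s <- c(theta_elb, theta_sho, omega_elb, omega_sho)
  names(s) <- c("theta_elb", "theta_sho", "omega_elb", "omega_sho")
  s
}

as_state_matrix <- function(state) {
  if (is.matrix(state)) state else matrix(state, nrow = 4L)
}

muscle_fl <- function(lnorm, mp) exp(-((lnorm - 1) / mp$fl_width)^2)

muscle_fl_prime <- function(lnorm, mp) {
  muscle_fl(lnorm, mp) * (-2 * (lnorm - 1) / mp$fl_width^2)
}

muscle_fv <- function(vnorm, mp) {
  out <- vnorm
  pos <- vnorm >= 0
  b <- mp$fv_curv
  out[pos] <- (mp$fv_max * vnorm[pos] + b) / (vnorm[pos] + b)
  vn <- vnorm[!pos]
  out[!pos] <- pmax(0, (mp$v_max + vn) / (mp$v_max - vn / 0.3))
  out
}

muscle_fv_prime <- function(vnorm, mp) {
  out <- vnorm
  pos <- vnorm >= 0
  b <- mp$fv_curv
  out[pos] <- (mp$fv_max - 1) * b / (vnorm[pos] + b)^2
  vn <- vnorm[!pos]
  den <- mp$v_max - vn / 0.3
  g <- (den + (mp$v_max + vn) / 0.3) / den^2
  g[(mp$v_max + vn) <= 0] <- 0
  out[!pos] <- g
  out
}

muscle_kinematics <- function(state, mp) {
  s <- as_state_matrix(state)
  dtheta <- rbind(s[TH_S, ] - mp$theta_ref[1], s[TH_E, ] - mp$theta_ref[2])
  lnorm <- 1 - (mp$moment_arms %*% dtheta) / mp$l0
  vnorm <- -(mp$moment_arms %*% rbind(s[OM_S, ], s[OM_E, ])) / mp$l0
  list(lnorm = lnorm, vnorm = vnorm)
}

#' Convert muscle activations to joint torques
#'
#' Each muscle produces force `activation * f_max * FL * FV`; forces map to
#' joint torques through the transposed moment-arm matrix.
#'
#' @param m Muscle activations: length-6 vector or 6 x C matrix,
#'   nonnegative.
#' @param state Arm state vector or 4 x C matrix.
#' @param mp A [muscle_params()] object.
#' @return Torque as a 2 x C matrix with rows (shoulder, elbow), in N m
#'   (a named length-2 vector when the inputs are vectors).
#' @export
muscle_torques <- function(m, state, mp = muscle_params()) {
  vec_in <- !is.matrix(m)
  m <- if (is.matrix(m)) m else matrix(m, nrow = 6L)
  s <- as_state_matrix(state)
  if (!all(is.finite(s))) {
    stop("non-finite arm state: integration blow-up")
  }
  stopifnot(nrow(m) == 6L, all(m >= 0))
  kin <- muscle_kinematics(s, mp)
  force <- m * mp$f_max * muscle_fl(kin$lnorm, mp) * muscle_fv(kin$vnorm, mp)
  tau <- crossprod(mp$moment_arms, force)
  if (vec_in) {
    tau <- drop(tau)
    names(tau) <- c("shoulder", "elbow")
  }
  tau
}

# 2x2 per-condition inverse inertia; returns list of entry vectors
inertia_inverse <- function(theta_elb, ap) {
  c2 <- cos(theta_elb)
  m11 <- ap$a1 + 2 * ap$a2 * c2
  m12 <- ap$a3 + ap$a2 * c2
  m22 <- rep(ap$a3, length(theta_elb))
  det <- m11 * m22 - m12^2
  if (any(det <= 0)) stop("singular inertia matrix")
  list(i11 = m22 / det, i12 = -m12 / det, i22 = m11 / det,
       m11 = m11, m12 = m12, m22 = m22, det = det)
}

coriolis <- function(state, ap) {
  s <- as_state_matrix(state)
  h <- ap$a2 * sin(s[TH_E, ])
  rbind(-h * s[OM_E, ] * (2 * s[OM_S, ] + s[OM_E, ]),  # shoulder
        h * s[OM_S, ]^2)                               # elbow
}

#' One forward-Euler step of the arm dynamics
#'
#' Standard planar two-link rigid-body equations (configuration-dependent
#' inertia matrix, Coriolis/centripetal terms, joint viscosity); the
#' horizontal plane means there is no gravity term. Angles advance with the
#' current velocities and velocities with the current acceleration
#' (forward Euler, step `dt`).
#'
#' @param state Arm state vector or 4 x C matrix.
#' @param torque Muscle-generated joint torque, length-2 `(shoulder, elbow)`
#'   or 2 x C matrix (N m).
#' @param load Externally applied perturbation torque, same shape as
#'   `torque`; zero outside posture perturbations.
#' @param ap An [arm_params()] object.
#' @return The next state, same shape as `state`.
#' @export
step_arm <- function(state, torque, load = 0, ap = arm_params()) {
  vec_in <- !is.matrix(state)
  s <- as_state_matrix(state)
  tau <- if (is.matrix(torque)) torque else matrix(torque, nrow = 2L,
                                                   ncol = ncol(s))
  if (length(load) == 1L && all(load == 0)) {
    load <- matrix(0, 2L, ncol(s))
  } else if (!is.matrix(load)) {
    load <- matrix(load, nrow = 2L, ncol = ncol(s))
  }
  stopifnot(all(is.finite(s)), all(is.finite(tau)), all(is.finite(load)))
  inv <- inertia_inverse(s[TH_E, ], ap)
  u <- tau + load - coriolis(s, ap) -
    ap$viscosity * rbind(s[OM_S, ], s[OM_E, ])
  acc_s <- inv$i11 * u[1, ] + inv$i12 * u[2, ]
  acc_e <- inv$i12 * u[1, ] + inv$i22 * u[2, ]
  out <- rbind(s[TH_E, ] + ap$dt * s[OM_E, ],
               s[TH_S, ] + ap$dt * s[OM_S, ],
               s[OM_E, ] + ap$dt * acc_e,
               s[OM_S, ] + ap$dt * acc_s)
  if (vec_in) {
    out <- drop(out)
    names(out) <- c("theta_elb", "theta_sho", "omega_elb", "omega_sho")
  }
  out
}

#' Hand position and velocity by forward kinematics
#'
#' @param state Arm state vector or 4 x C matrix.
#' @param ap An [arm_params()] object.
#' @return List with `pos` (2 x C; m) and `vel` (2 x C; m/s) of the
#'   endpoint in cartesian workspace coordinates (shoulder at the origin).
#' @export
hand_kinematics <- function(state, ap = arm_params()) {
  s <- as_state_matrix(state)
  ths <- s[TH_S, ]; the <- s[TH_E, ]
  oms <- s[OM_S, ]; ome <- s[OM_E, ]
  x <- ap$l1 * cos(ths) + ap$l2 * cos(ths + the)
  y <- ap$l1 * sin(ths) + ap$l2 * sin(ths + the)
  vx <- -ap$l1 * sin(ths) * oms - ap$l2 * sin(ths + the) * (oms + ome)
  vy <- ap$l1 * cos(ths) * oms + ap$l2 * cos(ths + the) * (oms + ome)
  list(pos = rbind(x, y), vel = rbind(vx, vy))
}

#' Joint angles reaching a hand position (inverse kinematics)
#'
#' Closed-form two-link inverse kinematics, elbow-flexed branch
#' (positive elbow angle, matching the home posture).
#'
#' @param xy Hand position, length-2 vector or 2 x K matrix (m).
#' @param ap An [arm_params()] object.
#' @return 2 x K matrix with rows (theta_sho, theta_elb) in rad.
#' @export
inverse_kinematics <- function(xy, ap = arm_params()) {
  xy <- if (is.matrix(xy)) xy else matrix(xy, nrow = 2L)
  r2 <- colSums(xy^2)
  ce <- (r2 - ap$l1^2 - ap$l2^2) / (2 * ap$l1 * ap$l2)
  if (any(abs(ce) > 1)) stop("hand target outside the reachable workspace")
  the <- acos(ce)
  ths <- atan2(xy[2, ], xy[1, ]) -
    atan2(ap$l2 * sin(the), ap$l1 + ap$l2 * cos(the))
  rbind(theta_sho = ths, theta_elb = the)
}

# Backward pass through one composite plant step
#   x' = step_arm(x, muscle_torques(m, x) + load)
# Given the adjoint of x' (4 x C), returns adjoints of x and m.
# Used by the BPTT training loop; kept in the plant module because it
# encodes the analytic Jacobian of the arm dynamics.
plant_step_backward <- function(state, m, gnext, ap, mp, load = 0) {
  s <- as_state_matrix(state)
  C <- ncol(s)
  the <- s[TH_E, ]
  inv <- inertia_inverse(the, ap)
  kin <- muscle_kinematics(s, mp)
  fl <- muscle_fl(kin$lnorm, mp); flp <- muscle_fl_prime(kin$lnorm, mp)
  fv <- muscle_fv(kin$vnorm, mp); fvp <- muscle_fv_prime(kin$vnorm, mp)
  force <- m * mp$f_max * fl * fv
  tau <- crossprod(mp$moment_arms, force)
  cc <- coriolis(s, ap)
  if (length(load) == 1L) load <- matrix(load, 2L, C)
  # load is additive and state-independent: it shifts u (and so the
  # accelerations entering the inertia-derivative term) but has no partials
  u <- tau + load - cc - ap$viscosity * rbind(s[OM_S, ], s[OM_E, ])
  ga_e <- gnext[OM_E, ]; ga_s <- gnext[OM_S, ]     # adjoints of accelerations
  # accel = Minv %*% u, accel adjoint -> u adjoint through Minv (symmetric)
  gu_s <- ap$dt * (inv$i11 * ga_s + inv$i12 * ga_e)
  gu_e <- ap$dt * (inv$i12 * ga_s + inv$i22 * ga_e)
  gu <- rbind(gu_s, gu_e)
  # direct state pass-through
  gx <- gnext
  gx[OM_E, ] <- gx[OM_E, ] + ap$dt * gnext[TH_E, ]
  gx[OM_S, ] <- gx[OM_S, ] + ap$dt * gnext[TH_S, ]
  # u = tau(m, x) - coriolis(x) - B omega  (+ load, constant)
  # (1) viscosity
  gx[OM_S, ] <- gx[OM_S, ] - ap$viscosity * gu_s
  gx[OM_E, ] <- gx[OM_E, ] - ap$viscosity * gu_e
  # (2) coriolis partials
  h <- ap$a2 * sin(the); dh <- ap$a2 * cos(the)
  om_s <- s[OM_S, ]; om_e <- s[OM_E, ]
  gx[OM_S, ] <- gx[OM_S, ] - gu_s * (-2 * h * om_e) - gu_e * (2 * h * om_s)
  gx[OM_E, ] <- gx[OM_E, ] - gu_s * (-h * (2 * om_s + 2 * om_e))
  gx[TH_E, ] <- gx[TH_E, ] -
    (gu_s * (-dh * om_e * (2 * om_s + om_e)) + gu_e * (dh * om_s^2))
  # (3) inertia dependence: accel = Minv(the) u_tot; need d(Minv u)/d the.
  # d(Minv)/dthe = -Minv dM Minv, dM = -a2 sin(the) [[2,1],[1,0]]
  acc_s <- inv$i11 * u[1, ] + inv$i12 * u[2, ]
  acc_e <- inv$i12 * u[1, ] + inv$i22 * u[2, ]
  dM_acc_s <- -h * (2 * acc_s + acc_e)
  dM_acc_e <- -h * acc_s
  # gnext_omega %*% (-Minv dM acc) * dt
  tmp_s <- inv$i11 * dM_acc_s + inv$i12 * dM_acc_e
  tmp_e <- inv$i12 * dM_acc_s + inv$i22 * dM_acc_e
  gx[TH_E, ] <- gx[TH_E, ] - ap$dt * (ga_s * tmp_s + ga_e * tmp_e)
  # (4) muscle torque partials: tau = R^T (m fmax fl fv)
  q <- mp$moment_arms %*% gu                      # 6 x C
  gm <- q * (mp$f_max * fl * fv)
  gth <- crossprod(mp$moment_arms, q * m * mp$f_max * fv * flp) *
    (-1 / mp$l0)                                  # rows (sho, elb)
  gom <- crossprod(mp$moment_arms, q * m * mp$f_max * fl * fvp) *
    (-1 / mp$l0)
  gx[TH_S, ] <- gx[TH_S, ] + gth[1, ]
  gx[TH_E, ] <- gx[TH_E, ] + gth[2, ]
  gx[OM_S, ] <- gx[OM_S, ] + gom[1, ]
  gx[OM_E, ] <- gx[OM_E, ] + gom[2, ]
  list(gx = gx, gm = gm)
}
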