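#' Forward kinematics of the two-link arm
#'
#' Maps joint angles to the endpoint (hand) position in a Cartesian frame with
#' origin at the shoulder joint. Accepts a single configuration (length-2
#' vector) or a matrix with one configuration per row; returns the same shape.
#'
#' @param q Joint angles `(q1, q2)` \[rad\] (shoulder, elbow); vector or n x 2
#'   matrix.
#' @param arm An [arm_params()] object.
#' @return Endpoint position(s) \[m\], same shape as `q`.
#' @export
forward_kinematics <- function(q, arm) {
  q <- as_config_matrix(q)
  x <- cbind(arm$l1 * cos(q[, 1]) + arm$l2 * cos(q[, 1] + q[, 2]),
             arm$l1 * sin(q[, 1]) + arm$l2 * sin(q[, 1] + q[, 2]))
  drop_config(x, q)
}

#' Inverse kinematics of the two-link arm
#'
#' Recovers joint angles from an endpoint position, selecting the elbow-flexed
#' branch `q2 in (0, pi)` (the principal arccos branch). The mirrored
#' elbow-extended solution is rejected by convention. Positions must lie
#' strictly inside the workspace annulus `|l1 - l2| < ||x|| < l1 + l2`.
#'
#' @param x Endpoint position(s) \[m\]; vector or n x 2 matrix.
#' @param arm An [arm_params()] object.
#' @return Joint angles, same shape as `x`.
#' @export
inverse_kinematics <- function(x, arm) {
  xm <- as_config_matrix(x)
  r2 <- xm[, 1]^2 + xm[, 2]^2
  r <- sqrt(r2)
  lo <- abs(arm$l1 - arm$l2)
  hi <- arm$l1 + arm$l2
  if (any(r <= lo)) {
    stop(sprintf("inverse_kinematics: ||x|| = %.4f m not above inner workspace bound |l1 - l2| = %.4f m",
                 min(r), lo))
  }
  if (any(r >= hi)) {
    stop(sprintf("inverse_kinematics: ||x|| = %.4f m not below outer workspace bound l1 + l2 = %.4f m",
                 max(r), hi))
  }
  c2 <- (r2 - arm$l1^2 - arm$l2^2) / (2 * arm$l1 * arm$l2)
  c2 <- pmin(1, pmax(-1, c2))
  q2 <- acos(c2)
  q1 <- atan2(xm[, 2], xm[, 1]) -
    atan2(arm$l2 * sin(q2), arm$l1 + arm$l2 * cos(q2))
  drop_config(cbind(q1, q2), xm)
}

#' Endpoint Jacobian of the two-link arm
#'
#' Partial derivative of the forward kinematics with respect to the joint
#' angles. `t(J) %*% u_ext` maps external endpoint forces to joint torques.
#' Singular configurations (full extension) are returned as-is; downstream
#' consumers are responsible for conditioning checks.
#'
#' @param q Joint angles (length-2 vector).
#' @param arm An [arm_params()] object.
#' @return 2 x 2 Jacobian matrix \[m\].
#' @export
jacobian <- function(q, arm) {
  s1 <- sin(q[1]); c1 <- cos(q[1])
  s12 <- sin(q[1] + q[2]); c12 <- cos(q[1] + q[2])
  matrix(c(-arm$l1 * s1 - arm$l2 * s12, -arm$l2 * s12,
           arm$l1 * c1 + arm$l2 * c12,  arm$l2 * c12),
         nrow = 2, byrow = TRUE)
}

#' Time derivative of the endpoint Jacobian
#'
#' @param q Joint angles (length-2 vector).
#' @param qd Joint angular velocities (length-2 vector).
#' @param arm An [arm_params()] object.
#' @return 2 x 2 matrix \[m/s\].
#' @export
jacobian_dot <- function(q, qd, arm) {
  s1 <- sin(q[1]); c1 <- cos(q[1])
  s12 <- sin(q[1] + q[2]); c12 <- cos(q[1] + q[2])
  w1 <- qd[1]; w12 <- qd[1] + qd[2]
  matrix(c(-arm$l1 * c1 * w1 - arm$l2 * c12 * w12, -arm$l2 * c12 * w12,
           -arm$l1 * s1 * w1 - arm$l2 * s12 * w12, -arm$l2 * s12 * w12),
         nrow = 2, byrow = TRUE)
}

#' Convert Cartesian endpoint kinematics to joint-space kinematics
#'
#' Applies the inverse kinematics sample-wise and propagates velocities and
#' accelerations through the Jacobian:
#' `qd = J^-1 xd`, `qdd = J^-1 (xdd - Jdot qd)`.
#'
#' @param x,xd,xdd n x 2 matrices of endpoint position, velocity and
#'   acceleration.
#' @param arm An [arm_params()] object.
#' @return List with n x 2 matrices `q`, `qd`, `qdd`.
#' @export
cartesian_to_joint <- function(x, xd, xdd, arm) {
  q <- as_config_matrix(inverse_kinematics(x, arm))
  n <- nrow(q)
  qd <- matrix(0, n, 2)
  qdd <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    J <- jacobian(q[i, ], arm)
    qd[i, ] <- solve(J, xd[i, ])
    Jd <- jacobian_dot(q[i, ], qd[i, ], arm)
    qdd[i, ] <- solve(J, xdd[i, ] - Jd %*% qd[i, ])
  }
  list(q = q, qd = qd, qdd = qdd)
}

#' Map endpoint forces to joint torques sample-wise
#'
#' @param q n x 2 matrix of joint angles.
#' @param u n x 2 matrix of endpoint forces \[N\].
#' @param arm An [arm_params()] object.
#' @return n x 2 matrix of joint torques \[N m\].
#' @export
endpoint_force_to_torque <- function(q, u, arm) {
  q <- as_config_matrix(q)
  u <- as_config_matrix(u)
  tau <- matrix(0, nrow(q), 2)
  for (i in seq_len(nrow(q))) {
    tau[i, ] <- crossprod(jacobian(q[i, ], arm), u[i, ])
  }
  drop_config(tau, u)
}

as_config_matrix <- function(q) {
  if (is.matrix(q)) {
    stopifnot(ncol(q) == 2)
    q
  } else {
    stopifnot(length(q) == 2)
    matrix(q, nrow = 1)
  }
}

drop_config <- function(out, template) {
  dimnames(out) <- NULL
  if (is.matrix(template) && nrow(template) > 1) out else drop(out)
}
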