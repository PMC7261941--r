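#' Minimum-jerk point-to-point reference trajectory
#'
#' Fifth-order minimum-jerk polynomial between two workspace points with zero
#' boundary velocity and acceleration; after `T_mov` the reference holds the
#' goal. The peak speed of the minimum-jerk profile is
#' `1.875 * ||x_goal - x_start|| / T_mov` at the midpoint.
#'
#' @param x_start,x_goal Endpoint positions \[m\] (length-2).
#' @param T_mov Movement duration \[s\].
#' @param fs Sample rate \[Hz\].
#' @param arm An [arm_params()] object (for the joint-space image; endpoints
#'   must lie in the workspace).
#' @param T_total Total reference duration \[s\] (>= `T_mov`); defaults to
#'   `T_mov`.
#' @return List with time `t`, Cartesian series `x`, `xd`, `xdd` and
#'   joint-space series `q`, `qd`, `qdd` (all n x 2), plus `fs`.
#' @export
min_jerk_reference <- function(x_start, x_goal, T_mov, fs, arm,
                               T_total = T_mov) {
  if (T_mov <= 0) stop("min_jerk_reference: T_mov must be positive")
  # workspace check (errors if unreachable)
  inverse_kinematics(rbind(x_start, x_goal), arm)
  n <- round(T_total * fs) + 1
  t <- seq(0, by = 1 / fs, length.out = n)
  s <- pmin(t / T_mov, 1)
  pos <- 10 * s^3 - 15 * s^4 + 6 * s^5
  vel <- (30 * s^2 - 60 * s^3 + 30 * s^4) / T_mov
  acc <- (60 * s - 180 * s^2 + 120 * s^3) / T_mov^2
  vel[s >= 1] <- 0
  acc[s >= 1] <- 0
  dx <- x_goal - x_start
  x <- cbind(x_start[1] + dx[1] * pos, x_start[2] + dx[2] * pos)
  xd <- cbind(dx[1] * vel, dx[2] * vel)
  xdd <- cbind(dx[1] * acc, dx[2] * acc)
  js <- cartesian_to_joint_vec(x, xd, xdd, arm)
  list(t = t, x = x, xd = xd, xdd = xdd,
       q = js$q, qd = js$qd, qdd = js$qdd, fs = fs)
}

# Vectorized closed-form kinematic maps ------------------------------------

#' Vectorized Cartesian-to-joint conversion
#'
#' Closed-form per-sample inversion of the 2 x 2 Jacobian (no loops), for
#' long series.
#'
#' @inheritParams cartesian_to_joint
#' @return List with n x 2 matrices `q`, `qd`, `qdd`.
#' @export
cartesian_to_joint_vec <- function(x, xd, xdd, arm) {
  q <- as_config_matrix(inverse_kinematics(x, arm))
  l1 <- arm$l1; l2 <- arm$l2
  s1 <- sin(q[, 1]); c1 <- cos(q[, 1])
  s12 <- sin(q[, 1] + q[, 2]); c12 <- cos(q[, 1] + q[, 2])
  J11 <- -l1 * s1 - l2 * s12; J12 <- -l2 * s12
  J21 <- l1 * c1 + l2 * c12;  J22 <- l2 * c12
  det <- J11 * J22 - J12 * J21
  qd1 <- (J22 * xd[, 1] - J12 * xd[, 2]) / det
  qd2 <- (-J21 * xd[, 1] + J11 * xd[, 2]) / det
  w1 <- qd1; w12 <- qd1 + qd2
  Jd11 <- -l1 * c1 * w1 - l2 * c12 * w12; Jd12 <- -l2 * c12 * w12
  Jd21 <- -l1 * s1 * w1 - l2 * s12 * w12; Jd22 <- -l2 * s12 * w12
  r1 <- xdd[, 1] - (Jd11 * qd1 + Jd12 * qd2)
  r2 <- xdd[, 2] - (Jd21 * qd1 + Jd22 * qd2)
  qdd1 <- (J22 * r1 - J12 * r2) / det
  qdd2 <- (-J21 * r1 + J11 * r2) / det
  list(q = q, qd = unname(cbind(qd1, qd2)), qdd = unname(cbind(qdd1, qdd2)))
}

#' Vectorized joint-to-Cartesian conversion
#'
#' @param q,qd,qdd n x 2 joint series.
#' @param arm An [arm_params()] object.
#' @return List with n x 2 matrices `x`, `xd`, `xdd`.
#' @export
joint_to_cartesian_vec <- function(q, qd, qdd, arm) {
  l1 <- arm$l1; l2 <- arm$l2
  s1 <- sin(q[, 1]); c1 <- cos(q[, 1])
  s12 <- sin(q[, 1] + q[, 2]); c12 <- cos(q[, 1] + q[, 2])
  x <- cbind(l1 * c1 + l2 * c12, l1 * s1 + l2 * s12)
  J11 <- -l1 * s1 - l2 * s12; J12 <- -l2 * s12
  J21 <- l1 * c1 + l2 * c12;  J22 <- l2 * c12
  xd <- cbind(J11 * qd[, 1] + J12 * qd[, 2],
              J21 * qd[, 1] + J22 * qd[, 2])
  w1 <- qd[, 1]; w12 <- qd[, 1] + qd[, 2]
  Jd11 <- -l1 * c1 * w1 - l2 * c12 * w12; Jd12 <- -l2 * c12 * w12
  Jd21 <- -l1 * s1 * w1 - l2 * s12 * w12; Jd22 <- -l2 * s12 * w12
  xdd <- cbind(J11 * qdd[, 1] + J12 * qdd[, 2] + Jd11 * qd[, 1] + Jd12 * qd[, 2],
               J21 * qdd[, 1] + J22 * qdd[, 2] + Jd21 * qd[, 1] + Jd22 * qd[, 2])
  list(x = x, xd = xd, xdd = xdd)
}

#' Vectorized endpoint-force-to-torque map
#'
#' @param q n x 2 joint angles.
#' @param u n x 2 endpoint forces.
#' @param arm An [arm_params()] object.
#' @return n x 2 joint torques `t(J(q)) u`.
#' @export
force_to_torque_vec <- function(q, u, arm) {
  l1 <- arm$l1; l2 <- arm$l2
  s1 <- sin(q[, 1]); c1 <- cos(q[, 1])
  s12 <- sin(q[, 1] + q[, 2]); c12 <- cos(q[, 1] + q[, 2])
  J11 <- -l1 * s1 - l2 * s12; J12 <- -l2 * s12
  J21 <- l1 * c1 + l2 * c12;  J22 <- l2 * c12
  cbind(J11 * u[, 1] + J21 * u[, 2],
        J12 * u[, 1] + J22 * u[, 2])
}

#' Vectorized torque-to-endpoint-force map (inverse transpose Jacobian)
#'
#' @param q n x 2 joint angles.
#' @param tau n x 2 joint torques.
#' @param arm An [arm_params()] object.
#' @return n x 2 endpoint forces `solve(t(J(q))) tau`.
#' @export
torque_to_force_vec <- function(q, tau, arm) {
  l1 <- arm$l1; l2 <- arm$l2
  s1 <- sin(q[, 1]); c1 <- cos(q[, 1])
  s12 <- sin(q[, 1] + q[, 2]); c12 <- cos(q[, 1] + q[, 2])
  J11 <- -l1 * s1 - l2 * s12; J12 <- -l2 * s12
  J21 <- l1 * c1 + l2 * c12;  J22 <- l2 * c12
  det <- J11 * J22 - J12 * J21
  # solve J' u = tau: u = J^-T tau
  cbind((J22 * tau[, 1] - J21 * tau[, 2]) / det,
        (-J12 * tau[, 1] + J11 * tau[, 2]) / det)
}
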