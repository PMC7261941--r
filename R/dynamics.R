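#' Mass and Coriolis matrices of the planar two-link arm
#'
#' Gravity-free Lagrangian dynamics of the arm constrained to the horizontal
#' plane, parameterized by the base inertial parameters
#' `pi = (pi1, pi2, pi3)`:
#' \deqn{M(q) = \begin{pmatrix} \pi_1 + \pi_2 + 2\pi_3\cos q_2 &
#'   \pi_2 + \pi_3 \cos q_2 \\ \pi_2 + \pi_3\cos q_2 & \pi_2 \end{pmatrix}}
#' and the Coriolis/centrifugal matrix `C` such that
#' `tau = M %*% qdd + C %*% qd`.
#'
#' @param q Joint angles (length-2 vector).
#' @param qd Joint angular velocities (length-2 vector).
#' @param arm An [arm_params()] object, or a length-3 base-inertial-parameter
#'   vector.
#' @return List with 2 x 2 matrices `M` \[kg m^2\] and `C` \[kg m^2 / s\].
#' @export
mass_coriolis <- function(q, qd, arm) {
  pb <- if (inherits(arm, "arm_params")) bip_from_standard(arm) else as.numeric(arm)
  stopifnot(length(pb) == 3)
  c2 <- cos(q[2]); s2 <- sin(q[2])
  M <- matrix(c(pb[1] + pb[2] + 2 * pb[3] * c2, pb[2] + pb[3] * c2,
                pb[2] + pb[3] * c2,             pb[2]),
              nrow = 2, byrow = TRUE)
  C <- matrix(c(-pb[3] * s2 * qd[2], -pb[3] * s2 * (qd[1] + qd[2]),
                 pb[3] * s2 * qd[1], 0),
              nrow = 2, byrow = TRUE)
  list(M = M, C = C)
}

#' Base regressor matrix of the planar two-link arm
#'
#' The rigid-body torque is linear in the base inertial parameters:
#' `Y %*% pi == M %*% qdd + C %*% qd` for every state. The 2 x 3 base
#' regressor is
#' \deqn{\bar Y = \begin{pmatrix}
#'   \ddot q_1 & \ddot q_1 + \ddot q_2 & \bar y_{13} \\
#'   0 & \ddot q_1 + \ddot q_2 & \bar y_{23} \end{pmatrix}}
#' with
#' \eqn{\bar y_{13} = (2\ddot q_1 + \ddot q_2)\cos q_2 -
#'   (2 \dot q_1 \dot q_2 + \dot q_2^2)\sin q_2} and
#' \eqn{\bar y_{23} = \ddot q_1 \cos q_2 + \dot q_1^2 \sin q_2}.
#'
#' @param q,qd,qdd Joint angles, velocities, accelerations (length-2 vectors).
#' @return 2 x 3 regressor matrix.
#' @export
base_regressor <- function(q, qd, qdd) {
  c2 <- cos(q[2]); s2 <- sin(q[2])
  y13 <- (2 * qdd[1] + qdd[2]) * c2 - (2 * qd[1] * qd[2] + qd[2]^2) * s2
  y23 <- qdd[1] * c2 + qd[1]^2 * s2
  matrix(c(qdd[1], qdd[1] + qdd[2], y13,
           0,      qdd[1] + qdd[2], y23),
         nrow = 2, byrow = TRUE)
}

#' Vectorized base regressor over a trajectory
#'
#' Stacks the 2 x 3 base regressor rows for every sample of a joint-space
#' trajectory into a `(2n) x 3` matrix (sample-major: rows `2i-1`, `2i`
#' belong to sample `i`).
#'
#' @param q,qd,qdd n x 2 matrices.
#' @return `(2n) x 3` matrix.
#' @export
base_regressor_series <- function(q, qd, qdd) {
  c2 <- cos(q[, 2]); s2 <- sin(q[, 2])
  y13 <- (2 * qdd[, 1] + qdd[, 2]) * c2 -
    (2 * qd[, 1] * qd[, 2] + qd[, 2]^2) * s2
  y23 <- qdd[, 1] * c2 + qd[, 1]^2 * s2
  n <- nrow(q)
  out <- matrix(0, 2 * n, 3)
  odd <- seq(1, 2 * n, by = 2)
  out[odd, 1] <- qdd[, 1]
  out[odd, 2] <- qdd[, 1] + qdd[, 2]
  out[odd, 3] <- y13
  out[odd + 1, 2] <- qdd[, 1] + qdd[, 2]
  out[odd + 1, 3] <- y23
  out
}

#' Rigid-body inverse dynamics (joint torques from a joint trajectory)
#'
#' @param q,qd,qdd n x 2 matrices of joint kinematics.
#' @param arm An [arm_params()] object or base-inertial-parameter vector.
#' @return n x 2 matrix of torques `M qdd + C qd` \[N m\].
#' @export
inverse_dynamics <- function(q, qd, qdd, arm) {
  pb <- if (inherits(arm, "arm_params")) bip_from_standard(arm) else as.numeric(arm)
  Y <- base_regressor_series(as_config_matrix(q), as_config_matrix(qd),
                             as_config_matrix(qdd))
  tv <- Y %*% pb
  matrix(tv, ncol = 2, byrow = TRUE)
}
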