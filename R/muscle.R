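#' Six-muscle model of the two-link arm
#'
#' Lumped muscle model with a constant 6 x 2 moment-arm matrix: one
#' mono-articular antagonist pair at the shoulder, one at the elbow, and one
#' bi-articular pair, each pair with exactly opposite moment arms so that
#' uniform co-contraction of a pair is torque-free. Muscle tension is
#' `m = a + D_m ed + K_m e` with muscle stiffness `K_m = K0 + K1 a`
#' (elementwise) and damping `D_m = K_m / 12`; `e`, `ed` are the
#' muscle-level tracking errors with respect to the reference movement.
#' The delayed reflexive feedback is proportional-derivative on those errors.
#'
#' Default magnitudes are calibrated so the window-averaged intrinsic joint
#' stiffness is of the order of published simulated values for transversal
#' reaching (roughly 15-30 N m/rad diagonal); they are simulator defaults,
#' not physiological authority. The baseline co-contraction `a0` is set high
#' enough that no muscle goes slack under the largest designed perturbation
#' (slack muscles would violate the linear tension model the estimators
#' assume; the simulator still clamps tensions at zero defensively).
#'
#' @param Jm 6 x 2 moment-arm matrix \[m\].
#' @param K0 Baseline muscle stiffness, 6-vector \[N/m per muscle\].
#' @param K1 Activation-dependent stiffness gain, 6-vector \[1/m\].
#' @param gp,gd Reflex proportional \[N/m\] and derivative \[N s/m\] gains.
#' @param delta_s Simulated feedback delay \[s\]; defaults to 115 ms, the
#'   voluntary-feedback delay, so that no feedback response to a perturbation
#'   can occur within a 115 ms estimation window.
#' @param a0 Baseline co-contraction tension \[N\].
#' @param dm_ratio Muscle damping / stiffness ratio (default 1/12).
#' @return A `muscle_model` object.
#' @export
muscle_model <- function(Jm = default_moment_arms(),
                         K0 = c(4000, 4000, 2000, 2000, 8500, 8500),
                         K1 = rep(15, 6),
                         gp = 400, gd = 40,
                         delta_s = 0.115,
                         a0 = 20,
                         dm_ratio = 1 / 12) {
  Jm <- as.matrix(Jm)
  stopifnot(nrow(Jm) == 6, ncol(Jm) == 2)
  if (any(K0 < 0) || any(K1 < 0)) stop("muscle_model: K0, K1 must be non-negative")
  if (delta_s < 0) stop("muscle_model: delta_s must be non-negative")
  structure(list(Jm = Jm, K0 = as.numeric(K0), K1 = as.numeric(K1),
                 gp = gp, gd = gd, delta_s = delta_s, a0 = a0,
                 dm_ratio = dm_ratio),
            class = "muscle_model")
}

#' @rdname muscle_model
#' @export
default_moment_arms <- function() {
  rbind(c(0.040, 0), c(-0.040, 0),          # shoulder flexor / extensor
        c(0, 0.025), c(0, -0.025),          # elbow flexor / extensor
        c(0.028, 0.028), c(-0.028, -0.028)) # bi-articular pair
}

#' Intrinsic joint impedance of the muscle model at given activations
#'
#' The intrinsic (instantaneous, delay-free) joint stiffness is the
#' congruence map of the diagonal muscle stiffness through the moment arms,
#' `K_q = t(Jm) diag(K0 + K1 a) Jm`, and the damping is `K_q * dm_ratio`.
#' `K_q` is symmetric positive definite whenever all muscle stiffnesses are
#' positive.
#'
#' @param muscle A [muscle_model()] object.
#' @param a Muscle activations: 6-vector or n x 6 matrix (then averaged over
#'   rows first; the map is linear in `a`, so averaging commutes).
#' @return List with 2 x 2 matrices `K_q` \[N m/rad\] and `D_q`
#'   \[N m s/rad\].
#' @export
intrinsic_joint_impedance <- function(muscle, a) {
  if (is.matrix(a)) a <- colMeans(a)
  Km <- muscle$K0 + muscle$K1 * pmax(a, 0)
  Kq <- crossprod(muscle$Jm, muscle$Jm * Km)
  list(K_q = Kq, D_q = Kq * muscle$dm_ratio)
}

#' Feedforward muscle activations for a reference movement
#'
#' Computes the inverse-dynamics joint torque of the reference (including the
#' admittance load the hand must drive), distributes it across the six
#' muscles by the minimum-norm solution of `t(Jm) a = tau`, and adds the
#' minimal uniform per-pair co-contraction offset that keeps every activation
#' at or above the baseline `a0` (muscles only pull; pair offsets are
#' torque-free by construction of the moment arms).
#'
#' @param ref Reference as returned by [min_jerk_reference()] (fields `q`,
#'   `qd`, `qdd`, `xd`, `xdd`).
#' @param arm An [arm_params()] object.
#' @param muscle A [muscle_model()] object.
#' @param manip A [manipulandum()] object, or `NULL` for an unloaded arm.
#' @return n x 6 matrix of feedforward activations \[N\].
#' @export
feedforward_activation <- function(ref, arm, muscle, manip = NULL) {
  tau <- inverse_dynamics(ref$q, ref$qd, ref$qdd, arm)
  if (!is.null(manip)) {
    load <- ref$xdd %*% diag(diag(manip$M_adm) + diag(manip$M_handle)) +
      ref$xd %*% diag(diag(manip$D_adm))
    tau <- tau + endpoint_force_to_torque(ref$q, load, arm)
  }
  # minimum-norm distribution: a = Jm (Jm' Jm)^-1 tau
  Jm <- muscle$Jm
  Mi <- solve(crossprod(Jm))
  a <- tau %*% Mi %*% t(Jm)
  for (p in list(c(1, 2), c(3, 4), c(5, 6))) {
    off <- max(0, muscle$a0 - min(a[, p]))
    a[, p] <- a[, p] + off
  }
  if (any(a < 0)) warning("feedforward_activation: torque demand exceeds co-contraction budget; activations clipped downstream")
  a
}
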