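#' Single sinusoidal acceleration block
#'
#' Evaluates the biphasic acceleration block
#' \deqn{\xi(t) = \tfrac12 A_p(\sin(4\pi t/T_p + 3\pi/2) + 1)}
#' on `[0, Tp/2]` and its negation on `[Tp/2, Tp]`. The block starts and ends
#' at zero with zero slope, integrates to zero net velocity, and produces a
#' net displacement of `Ap * Tp^2 / 8`.
#'
#' @param Ap Peak acceleration amplitude.
#' @param Tp Block duration \[s\].
#' @param fs Sample rate \[Hz\].
#' @return List with `t` (time grid from 0 to `Tp`) and `a` (acceleration).
#' @export
sin_block <- function(Ap, Tp, fs) {
  if (!is.finite(Ap)) stop("sin_block: Ap must be finite")
  if (!is.finite(Tp) || Tp <= 0) stop("sin_block: Tp must be positive")
  if (fs * Tp < 8) stop("sin_block: fs too low to resolve the block (need fs*Tp >= 8)")
  t <- seq(0, Tp, by = 1 / fs)
  list(t = t, a = sin_block_eval(t, Ap, Tp)$a)
}

# analytic acceleration/velocity/position/jerk of one block, from rest
sin_block_eval <- function(t, Ap, Tp) {
  w <- 4 * pi / Tp
  half <- Tp / 2
  sgn <- ifelse(t <= half, 1, -1)
  base <- 0.5 * Ap * (1 - cos(w * t))      # sin(x + 3pi/2) = -cos(x)
  a <- sgn * base
  j <- sgn * 0.5 * Ap * w * sin(w * t)
  # first half integrals from 0
  v1 <- 0.5 * Ap * (t - sin(w * t) / w)
  p1 <- 0.5 * Ap * (t^2 / 2 + (cos(w * t) - 1) / w^2)
  # values at the half-way point
  vh <- 0.5 * Ap * half
  ph <- 0.5 * Ap * (half^2 / 2)
  # second half: v(t) = vh - int_{half}^{t} base  (sin(w*half) = 0, cos = 1)
  v2 <- vh - 0.5 * Ap * (t - half) + 0.5 * Ap * sin(w * t) / w
  p2 <- ph + vh * (t - half) - 0.25 * Ap * (t - half)^2 +
    0.5 * Ap * (1 - cos(w * t)) / w^2
  v <- ifelse(t <= half, v1, v2)
  p <- ifelse(t <= half, p1, p2)
  list(a = a, v = v, p = p, j = j)
}

#' Build the full two-block perturbation profile
#'
#' Concatenates a deviating block of duration `T_p1` and an oppositely
#' directed retracting block of duration `T_p2 = (3/2) T_p1`. The second
#' amplitude is set to `A_p2 = A_p1 (T_p1/T_p2)^2` so that position and
#' velocity return to zero at the end of the perturbation
#' (`T_pert = T_p1 + T_p2`); each block contributes zero net velocity and a
#' displacement proportional to `Ap * Tp^2`, so this choice cancels the
#' displacements exactly. The force profile is the admittance image
#' `u = M_adm * a + D_adm * v`, normalized so that the maximum absolute force
#' within the first block equals `A_pert`. All kinematic profiles are scaled
#' by the same factor so force and kinematics stay admittance-consistent.
#'
#' @param A_pert First-peak force amplitude \[N\].
#' @param T_p1 Duration of the first block \[s\].
#' @param M_adm Scalar admittance inertia \[kg\] (per axis).
#' @param D_adm Scalar admittance damping \[N s/m\] (per axis).
#' @param fs Sample rate \[Hz\].
#' @return A `perturbation_profile` object with fields `t`, `a_prof`,
#'   `v_prof`, `p_prof`, `j_prof`, `u_prof` (scalar profiles along the
#'   perturbation direction), `A_pert`, `T_p1`, `T_p2`, `T_pert`, `fs`.
#' @export
build_perturbation <- function(A_pert, T_p1, M_adm = 5, D_adm = 20, fs = 2000) {
  if (!is.finite(A_pert) || A_pert <= 0) stop("build_perturbation: A_pert must be positive")
  if (!is.finite(T_p1) || T_p1 <= 0) stop("build_perturbation: T_p1 must be positive")
  if (fs * T_p1 < 8) stop("build_perturbation: fs too low to resolve the first block")
  T_p2 <- 1.5 * T_p1
  T_pert <- T_p1 + T_p2
  Ap1 <- 1
  Ap2 <- Ap1 * (T_p1 / T_p2)^2
  n <- round(T_pert * fs)
  t <- seq(0, by = 1 / fs, length.out = n + 1)
  in1 <- t <= T_p1
  b1 <- sin_block_eval(pmin(t, T_p1), Ap1, T_p1)
  # end state of block 1 (v ends at 0, displacement Ap1*T_p1^2/8)
  p1_end <- Ap1 * T_p1^2 / 8
  t2 <- pmax(t - T_p1, 0)
  b2 <- sin_block_eval(pmin(t2, T_p2), -Ap2, T_p2)
  a <- ifelse(in1, b1$a, b2$a)
  v <- ifelse(in1, b1$v, b2$v)
  p <- ifelse(in1, b1$p, p1_end + b2$p)
  j <- ifelse(in1, b1$j, b2$j)
  u <- M_adm * a + D_adm * v
  peak1 <- max(abs(u[t <= T_p1]))
  s <- A_pert / peak1
  structure(list(t = t,
                 a_prof = s * a, v_prof = s * v, p_prof = s * p,
                 j_prof = s * j, u_prof = s * u,
                 A_pert = A_pert, T_p1 = T_p1, T_p2 = T_p2, T_pert = T_pert,
                 M_adm = M_adm, D_adm = D_adm, fs = fs),
            class = "perturbation_profile")
}

#' @export
print.perturbation_profile <- function(x, ...) {
  cat(sprintf("Perturbation profile: A_pert = %.1f N, T_p1 = %.0f ms, T_p2 = %.0f ms, T_pert = %.0f ms @ %g Hz\n",
              x$A_pert, 1e3 * x$T_p1, 1e3 * x$T_p2, 1e3 * x$T_pert, x$fs))
  cat(sprintf("  peak |p| = %.2f mm, terminal |p| = %.2e of peak\n",
              1e3 * max(abs(x$p_prof)),
              abs(x$p_prof[length(x$p_prof)]) / max(abs(x$p_prof))))
  invisible(x)
}

#' The standard set of perturbation directions
#'
#' Twenty directions `phi = (pi/12) k` for `k = 1..24` with the four cardinal
#' multiples of `pi/2` (`k = 6, 12, 18, 24`) excluded, so no perturbation is
#' aligned with a Cartesian axis.
#'
#' @return Sorted numeric vector of 20 angles \[rad\].
#' @export
pert_angle_set <- function() {
  k <- setdiff(1:24, c(6, 12, 18, 24))
  sort((pi / 12) * k)
}

#' Perturbation force vector at given times
#'
#' Evaluates the two-dimensional perturbation force
#' `u_pert(t) = A_pert * u_norm(t) * (cos(phi), sin(phi))`, where `u_norm` is
#' the normalized force profile of `profile`; zero outside `[0, T_pert]`.
#'
#' @param profile A [build_perturbation()] object.
#' @param phi Perturbation direction \[rad\].
#' @param t Times after perturbation onset \[s\].
#' @return `length(t)` x 2 matrix of forces \[N\].
#' @export
pert_force <- function(profile, phi, t) {
  u <- approx(profile$t, profile$u_prof, xout = t, yleft = 0, yright = 0,
              rule = 2)$y
  u[t > profile$T_pert | t < 0] <- 0
  cbind(u * cos(phi), u * sin(phi))
}
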