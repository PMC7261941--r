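#' @useDynLib armfji, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rnorm sd
#' @importFrom utils head read.csv tail write.csv
NULL

new_trial <- function(t, x, xd, xdd, u_ext, q, qd, qdd, a, fs,
                      perturbed, phi, onset_index, seed, kind,
                      twin = NULL, extra = list()) {
  structure(c(list(t = t, x = x, xd = xd, xdd = xdd, u_ext = u_ext,
                   q = q, qd = qd, qdd = qdd, a = a, fs = fs,
                   perturbed = perturbed, phi = phi,
                   onset_index = onset_index, seed = seed, kind = kind,
                   twin = twin), extra),
            class = "fji_trial")
}

#' @export
print.fji_trial <- function(x, ...) {
  cat(sprintf("%s trial: %d samples @ %g Hz, %s%s\n",
              x$kind, length(x$t), x$fs,
              if (x$perturbed) sprintf("perturbed (phi = %.3f rad, onset sample %d)",
                                       x$phi, x$onset_index) else "unperturbed",
              if (!is.null(x$twin)) ", with unperturbed twin" else ""))
  invisible(x)
}

per_trial_seed <- function(master, k) {
  # counter-based so earlier trials are unaffected by the trial count
  as.integer((as.numeric(master) + 7919 * as.numeric(k)) %% 2147483647L)
}

#' Simulate one dynamic-task trial
#'
#' Integrates the coupled arm + admittance dynamics for one point-to-point
#' movement. When a perturbation profile is supplied, the movement is first
#' simulated unperturbed (the twin) to locate the onset -- the first sample
#' at which the hand crosses `onset_x2` along the movement axis -- and then
#' re-simulated with the perturbation force injected from that sample on.
#' Both simulations share the same noise realization, so twin and perturbed
#' trials are identical before onset.
#'
#' @param arm,muscle,noise,manip Model components ([arm_params()],
#'   [muscle_model()], [noise_model()], [manipulandum()]).
#' @param profile A [build_perturbation()] profile, or `NULL` for an
#'   unperturbed trial.
#' @param phi Perturbation direction \[rad\].
#' @param seed Integer seed for the trial's noise stream.
#' @param x_start,x_goal Movement endpoints \[m\].
#' @param T_mov Movement duration \[s\].
#' @param onset_x2 Perturbation trigger: first crossing of this `x2`
#'   coordinate \[m\].
#' @param fs Sample rate \[Hz\].
#' @param T_tail Extra simulated time after `T_mov` \[s\].
#' @return An `fji_trial`; perturbed trials carry the unperturbed twin in
#'   `$twin`.
#' @export
simulate_dynamic_trial <- function(arm, muscle, noise, manip,
                                   profile = NULL, phi = 0, seed = 1,
                                   x_start = c(0, 0.30), x_goal = c(0, 0.55),
                                   T_mov = 2, onset_x2 = 0.4,
                                   fs = 2000, T_tail = 0.5) {
  ref <- min_jerk_reference(x_start, x_goal, T_mov, fs, arm,
                            T_total = T_mov + T_tail)
  n <- nrow(ref$x)
  aFF <- feedforward_activation(ref, arm, muscle, manip)
  set.seed(seed)
  aN <- neural_noise(n, noise, fs)
  zero_u <- matrix(0, n, 2)
  twin_raw <- run_sim_core(ref, aFF, aN, zero_u, arm, muscle, manip, fs)
  twin <- assemble_trial(twin_raw, ref$t, zero_u, arm, manip, fs,
                         perturbed = FALSE, phi = NA_real_,
                         onset_index = NA_integer_, seed = seed,
                         kind = "dynamic")
  if (is.null(profile)) return(twin)
  onset <- which(twin$x[, 2] >= onset_x2)[1]
  if (is.na(onset)) {
    stop(sprintf("simulate_dynamic_trial: trial rejected, hand never reached x2 = %.2f m (max %.3f m)",
                 onset_x2, max(twin$x[, 2])))
  }
  tp <- ref$t - ref$t[onset]
  u_pert <- pert_force(profile, phi, tp)
  pert_raw <- run_sim_core(ref, aFF, aN, u_pert, arm, muscle, manip, fs)
  assemble_trial(pert_raw, ref$t, u_pert, arm, manip, fs,
                 perturbed = TRUE, phi = phi, onset_index = onset,
                 seed = seed, kind = "dynamic", twin = twin,
                 extra = list(muscle = muscle))
}

run_sim_core <- function(ref, aFF, aN, u_pert, arm, muscle, manip, fs) {
  q0 <- ref$q[1, ]
  qd0 <- ref$qd[1, ]
  sim_core_cpp(ref$q, ref$qd, aFF, aN, u_pert,
               muscle$Jm, muscle$K0, muscle$K1, muscle$dm_ratio,
               muscle$gp, muscle$gd, round(muscle$delta_s * fs), TRUE,
               bip_from_standard(arm),
               diag(manip$M_adm) + diag(manip$M_handle), diag(manip$D_adm),
               arm$l1, arm$l2, 1 / fs, q0, qd0)
}

assemble_trial <- function(raw, t, u_pert, arm, manip, fs, perturbed, phi,
                           onset_index, seed, kind, twin = NULL,
                           extra = list()) {
  cart <- joint_to_cartesian_vec(raw$q, raw$qd, raw$qdd, arm)
  u_ext <- admittance_force(manip, cart$xd, cart$xdd, u_pert)
  new_trial(t, cart$x, cart$xd, cart$xdd, u_ext,
            raw$q, raw$qd, raw$qdd, raw$a, fs,
            perturbed, phi, onset_index, seed, kind, twin, extra)
}

#' Simulate one static-task trial (open-loop position perturbation)
#'
#' In the static task the interaction is open loop: the cart position is
#' commanded directly (applied forces do not move the manipulandum), so the
#' endpoint follows the posture plus, for perturbed trials, the scaled
#' perturbation position profile along `phi`. The arm's muscle state is
#' driven by the commanded kinematics and the measured external force is the
#' arm's reaction force, recovered algebraically from the rigid-body balance
#' `u_ext = J^-T (M qdd + C qd - tau_int)`. No ODE integration is needed.
#'
#' @inheritParams simulate_dynamic_trial
#' @param posture Held endpoint position \[m\].
#' @param profile Perturbation profile (its position profile is rescaled to
#'   `p_amp` peak displacement), or `NULL` for an unperturbed trial.
#' @param p_amp Peak displacement of the position perturbation \[m\].
#' @param T_pre Hold time before perturbation onset \[s\].
#' @param T_post Hold time after the end of the perturbation \[s\].
#' @return An `fji_trial`; perturbed trials carry the unperturbed twin.
#' @export
simulate_static_trial <- function(arm, muscle, noise, manip,
                                  profile = NULL, phi = 0, seed = 1,
                                  posture = c(0, 0.45), p_amp = 0.008,
                                  T_pre = 0.3, T_post = 0.3, fs = 2000,
                                  reflex_on = TRUE) {
  T_pert <- if (is.null(profile)) 0.4 else profile$T_pert
  n <- round((T_pre + T_pert + T_post) * fs) + 1
  t <- seq(0, by = 1 / fs, length.out = n)
  onset <- round(T_pre * fs) + 1
  # commanded endpoint kinematics
  p <- v <- a <- j <- numeric(n)
  if (!is.null(profile)) {
    s <- p_amp / max(abs(profile$p_prof))
    tp <- t - t[onset]
    idx <- tp >= 0 & tp <= profile$T_pert
    gi <- function(y) approx(profile$t, y, xout = tp[idx])$y * s
    p[idx] <- gi(profile$p_prof)
    v[idx] <- gi(profile$v_prof)
    a[idx] <- gi(profile$a_prof)
    j[idx] <- gi(profile$j_prof)
  }
  dir <- c(cos(phi), sin(phi))
  x <- cbind(posture[1] + dir[1] * p, posture[2] + dir[2] * p)
  xd <- cbind(dir[1] * v, dir[2] * v)
  xdd <- cbind(dir[1] * a, dir[2] * a)
  js <- cartesian_to_joint_vec(x, xd, xdd, arm)
  q_ref <- matrix(inverse_kinematics(posture, arm), n, 2, byrow = TRUE)
  qd_ref <- matrix(0, n, 2)

  set.seed(seed)
  aN <- neural_noise(n, noise, fs)
  aFF <- matrix(muscle$a0, n, 6)
  e <- (q_ref - js$q) %*% t(muscle$Jm)
  ed <- (qd_ref - js$qd) %*% t(muscle$Jm)
  nd <- round(muscle$delta_s * fs)
  aFB <- matrix(0, n, 6)
  if (reflex_on && nd < n) {
    src <- c(rep(1, nd), seq_len(n - nd))
    aFB <- pmax(muscle$gp * e[src, , drop = FALSE] +
                  muscle$gd * ed[src, , drop = FALSE], 0)
  }
  a_tot <- pmax(aFF + aFB + aN, 0)
  Km <- sweep(a_tot, 2, muscle$K1, `*`)
  Km <- sweep(Km, 2, muscle$K0, `+`)
  m <- pmax(a_tot + muscle$dm_ratio * Km * ed + Km * e, 0)
  tau_int <- m %*% muscle$Jm
  tau_rb <- inverse_dynamics(js$q, js$qd, js$qdd, arm)
  u_ext <- torque_to_force_vec(js$q, tau_rb - tau_int, arm)

  trial <- new_trial(t, x, xd, xdd, u_ext, js$q, js$qd, js$qdd, a_tot, fs,
                     perturbed = !is.null(profile), phi = if (is.null(profile)) NA_real_ else phi,
                     onset_index = if (is.null(profile)) NA_integer_ else onset,
                     seed = seed, kind = "static",
                     extra = list(muscle = muscle, posture = posture,
                                  pert_kinematics = list(p = p, v = v, a = a, j = j, dir = dir)))
  if (!is.null(profile)) {
    trial$twin <- simulate_static_trial(arm, muscle, noise, manip,
                                        profile = NULL, phi = phi, seed = seed,
                                        posture = posture, p_amp = p_amp,
                                        T_pre = T_pre,
                                        T_post = T_pert + T_post - 0.4,
                                        fs = fs, reflex_on = reflex_on)
  }
  trial
}

#' Run the static posture-maintenance task
#'
#' Five postures x twenty perturbation directions = 100 trials, each an 8 mm
#' open-loop position perturbation with first-block duration `T_p1 = 160` ms
#' (total perturbation duration 400 ms), in randomized order. Every trial
#' carries its unperturbed twin.
#'
#' @param arm,muscle,noise,manip Model components; defaults are the package
#'   defaults.
#' @param seed Master seed; per-trial seeds are derived counter-based.
#' @param fs Sample rate \[Hz\].
#' @param postures 5 x 2 matrix of held endpoint positions \[m\].
#' @param T_p1 First-block duration \[s\].
#' @param p_amp Position perturbation amplitude \[m\].
#' @param reflex_on Keep the delayed reflex loop active in the static task.
#' @return A `trial_set` with 100 trials.
#' @export
run_static_task <- function(arm = arm_params(), muscle = muscle_model(),
                            noise = noise_model(), manip = manipulandum(),
                            seed = 1, fs = 2000,
                            postures = static_postures(),
                            T_p1 = 0.160, p_amp = 0.008, reflex_on = TRUE) {
  profile <- build_perturbation(A_pert = 1, T_p1 = T_p1,
                                M_adm = manip$M_adm[1, 1],
                                D_adm = manip$D_adm[1, 1], fs = fs)
  angles <- pert_angle_set()
  grid <- expand.grid(pos = seq_len(nrow(postures)), phi = angles)
  set.seed(seed)
  ord <- sample.int(nrow(grid))
  grid <- grid[ord, ]
  trials <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    trials[[k]] <- simulate_static_trial(
      arm, muscle, noise, manip, profile = profile, phi = grid$phi[k],
      seed = per_trial_seed(seed, k), posture = postures[grid$pos[k], ],
      p_amp = p_amp, fs = fs, reflex_on = reflex_on)
  }
  structure(list(trials = trials, kind = "static", seed = seed, fs = fs,
                 arm = arm, muscle = muscle, noise = noise, manip = manip,
                 schedule = grid),
            class = "trial_set")
}

#' Default static-task postures
#'
#' Five endpoint positions distributed over the workspace (shoulder-centred
#' coordinates, metres).
#' @return 5 x 2 matrix.
#' @export
static_postures <- function() {
  rbind(c(0, 0.35), c(-0.10, 0.45), c(0, 0.55), c(0.10, 0.45), c(0, 0.45))
}

#' Run the dynamic movement task
#'
#' Twenty perturbation directions x `reps` repetitions (default 3) = 60
#' trials of sagittal point-to-point reaching from (0, 0.30) m to
#' (0, 0.55) m over 2 s, each trial consisting of a matched unperturbed and
#' perturbed simulation with a 40 N, 175 ms force perturbation triggered at
#' the `x2 = 0.4` m crossing; trial order is randomized.
#'
#' @inheritParams run_static_task
#' @param reps Repetitions per angle.
#' @param A_pert Perturbation force amplitude \[N\].
#' @param T_p1 First-block duration \[s\].
#' @param T_mov Movement duration \[s\].
#' @param x_start,x_goal Movement endpoints \[m\].
#' @param onset_x2 Trigger coordinate \[m\].
#' @return A `trial_set` with `20 * reps` perturbed trials (twins attached).
#' @export
run_dynamic_task <- function(arm = arm_params(), muscle = muscle_model(),
                             noise = noise_model(), manip = manipulandum(),
                             seed = 1, fs = 2000, reps = 3,
                             A_pert = 40, T_p1 = 0.070, T_mov = 2,
                             x_start = c(0, 0.30), x_goal = c(0, 0.55),
                             onset_x2 = 0.4) {
  profile <- build_perturbation(A_pert = A_pert, T_p1 = T_p1,
                                M_adm = manip$M_adm[1, 1],
                                D_adm = manip$D_adm[1, 1], fs = fs)
  angles <- pert_angle_set()
  grid <- expand.grid(rep = seq_len(reps), phi = angles)
  set.seed(seed)
  ord <- sample.int(nrow(grid))
  grid <- grid[ord, ]
  trials <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    trials[[k]] <- simulate_dynamic_trial(
      arm, muscle, noise, manip, profile = profile, phi = grid$phi[k],
      seed = per_trial_seed(seed, k), x_start = x_start, x_goal = x_goal,
      T_mov = T_mov, onset_x2 = onset_x2, fs = fs)
  }
  structure(list(trials = trials, kind = "dynamic", seed = seed, fs = fs,
                 arm = arm, muscle = muscle, noise = noise, manip = manip,
                 schedule = grid, profile = profile),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("trial_set: %d %s trials @ %g Hz (master seed %d)\n",
              length(x$trials), x$kind, x$fs, x$seed))
  invisible(x)
}

#' Window-averaged ground-truth involuntary joint impedance of a trial
#'
#' Evaluates the simulator's intrinsic joint damping and stiffness
#' analytically from the recorded activation history,
#' `K_q(t) = t(Jm) diag(K0 + K1 a(t)) Jm`, `D_q(t) = K_q(t) / 12`, and
#' averages over the estimation window. This is the reference value for
#' normalized-absolute-error validation.
#'
#' @param trial An `fji_trial` carrying its muscle model and activation
#'   history.
#' @param window Length-2 numeric `(t0, t1)` \[s\] relative to perturbation
#'   onset, or `NULL` for the whole trial.
#' @return List with 2 x 2 matrices `D_q`, `K_q`.
#' @export
ground_truth_impedance <- function(trial, window = NULL) {
  if (is.null(trial$a) || is.null(trial$muscle)) {
    stop("ground_truth_impedance: trial carries no muscle-state history")
  }
  idx <- seq_len(nrow(trial$a))
  if (!is.null(window)) {
    if (is.na(trial$onset_index)) stop("ground_truth_impedance: trial has no onset")
    i0 <- trial$onset_index + round(window[1] * trial$fs)
    i1 <- trial$onset_index + round(window[2] * trial$fs)
    if (i0 < 1 || i1 > nrow(trial$a)) stop("ground_truth_impedance: window outside trial")
    idx <- i0:i1
  }
  intrinsic_joint_impedance(trial$muscle, trial$a[idx, , drop = FALSE])[c("D_q", "K_q")]
}
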