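test_that("minimum-jerk reference satisfies its closed forms", {
  ref <- min_jerk_reference(c(0, 0.30), c(0, 0.55), 2, 2000, default_arm)
  speed <- sqrt(rowSums(ref$xd^2))
  # peak speed = 1.875 * ||dx|| / T at the midpoint
  expect_equal(max(speed), 1.875 * 0.25 / 2, tolerance = 1e-6)
  expect_equal(which.max(speed), round(nrow(ref$x) / 2), tolerance = 2)
  n <- nrow(ref$x)
  expect_equal(ref$xd[c(1, n), ], matrix(0, 2, 2))
  expect_equal(ref$xdd[c(1, n), ], matrix(0, 2, 2))
  expect_equal(ref$x[n, ], c(0, 0.55), tolerance = 1e-12)
  expect_error(min_jerk_reference(c(0, 0.3), c(0, 2), 2, 2000, default_arm),
               "workspace")
})

test_that("feedforward activations reproduce the demanded torque and stay >= a0", {
  ref <- min_jerk_reference(c(0, 0.30), c(0, 0.55), 2, 500, default_arm)
  a <- feedforward_activation(ref, default_arm, default_muscle, default_manip)
  expect_true(all(a >= default_muscle$a0 - 1e-9))
  tau_demand <- inverse_dynamics(ref$q, ref$qd, ref$qdd, default_arm) +
    endpoint_force_to_torque(ref$q,
      ref$xdd %*% default_manip$M_adm + ref$xd %*% default_manip$D_adm,
      default_arm)
  expect_lt(max(abs(a %*% default_muscle$Jm - tau_demand)), 1e-8)
  # static reference -> constant activations
  refs <- min_jerk_reference(c(0, 0.45), c(0, 0.45), 1, 500, default_arm)
  as <- feedforward_activation(refs, default_arm, default_muscle, NULL)
  expect_equal(as, matrix(default_muscle$a0, nrow(as), 6), tolerance = 1e-12)
})

test_that("neural noise has the designed gain, mean and spectrum", {
  fs <- 2000
  expect_equal(neural_noise(500, noise_model(alpha_N = 0), fs),
               matrix(0, 500, 6))
  set.seed(10)
  x <- neural_noise(8000, noise_model(), fs)
  expect_equal(dim(x), c(8000, 6))
  # spectral roll-off: power above 2*f_cN down >= 30 dB from the passband
  e <- esd(x[, 1], fs)
  pass <- mean(e$psi[e$f > 0.2 & e$f < 1])
  stopb <- mean(e$psi[e$f > 4 & e$f < 8])
  expect_gt(10 * log10(pass / stopb), 30)
  # reproducibility under seed
  set.seed(77); a1 <- neural_noise(1000, noise_model(), fs)
  set.seed(77); a2 <- neural_noise(1000, noise_model(), fs)
  expect_identical(a1, a2)
  # zero-mean Monte-Carlo check over seeds
  m <- sapply(1:40, function(s) { set.seed(s); mean(neural_noise(2000, noise_model(), fs)[, 1]) })
  expect_lt(abs(mean(m)), 3 * stats::sd(m) / sqrt(length(m)) + 0.05)
})

test_that("noise-free closed loop tracks the reference to sub-millimetre", {
  tr <- simulate_dynamic_trial(default_arm, default_muscle,
                               noise_model(alpha_N = 0), default_manip,
                               profile = NULL, seed = 1)
  n <- nrow(tr$x)
  expect_lt(sqrt(sum((tr$x[n, ] - c(0, 0.55))^2)), 1e-3)
  expect_lt(max(abs(tr$xd[n, ])), 1e-3)
})

test_that("perturbed and twin trials are identical before onset and diverge after", {
  tr <- lite_dynamic_trial()
  on <- tr$onset_index
  expect_identical(tr$x[1:on, ], tr$twin$x[1:on, ])
  expect_identical(tr$a[1:on, ], tr$twin$a[1:on, ])
  after <- on + round(0.06 * tr$fs)
  expect_gt(max(abs(tr$x[after, ] - tr$twin$x[after, ])), 1e-4)
  # onset is the first crossing of x2 = 0.4 m
  expect_gte(tr$x[on, 2], 0.4)
  expect_lt(tr$x[on - 1, 2], 0.4)
})

test_that("simulation is deterministic under a fixed seed", {
  prof <- build_perturbation(40, 0.07)
  t1 <- simulate_dynamic_trial(default_arm, default_muscle, noise_model(),
                               default_manip, prof, phi = 2, seed = 9,
                               T_tail = 0.2)
  t2 <- simulate_dynamic_trial(default_arm, default_muscle, noise_model(),
                               default_manip, prof, phi = 2, seed = 9,
                               T_tail = 0.2)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$u_ext, t2$u_ext)
})

test_that("ground-truth impedance is SPD with damping = stiffness/12", {
  tr <- lite_dynamic_trial()
  gt <- ground_truth_impedance(tr, c(0, 0.115))
  expect_true(isSymmetric(gt$K_q))
  expect_true(all(eigen(gt$K_q, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_equal(gt$D_q, gt$K_q / 12)
  # activation-independent case: K1 = 0 gives the congruence of K0 exactly
  mus0 <- muscle_model(K1 = rep(0, 6))
  imp <- intrinsic_joint_impedance(mus0, rep(1, 6))
  expect_equal(imp$K_q, crossprod(mus0$Jm, mus0$Jm * mus0$K0))
  expect_error(ground_truth_impedance(tr, c(0, 10)), "window")
})

test_that("task runners produce the designed trial schedules", {
  # scaled-down static run: check structure via a 1-posture x 20-angle variant
  st <- run_static_task(seed = 2, postures = static_postures()[5, , drop = FALSE])
  expect_length(st$trials, 20)
  expect_true(all(vapply(st$trials, function(tr) tr$perturbed, TRUE)))
  amp <- vapply(st$trials, function(tr) max(abs(tr$pert_kinematics$p)), 0)
  expect_equal(amp, rep(0.008, 20), tolerance = 1e-9)
  # randomized order reproducible under the seed
  st2 <- run_static_task(seed = 2, postures = static_postures()[5, , drop = FALSE])
  expect_identical(st$schedule, st2$schedule)
  expect_identical(vapply(st$trials, `[[`, 0, "phi"),
                   vapply(st2$trials, `[[`, 0, "phi"))
})

test_that("static open-loop trial balances forces algebraically", {
  prof <- build_perturbation(1, 0.160)
  tr <- simulate_static_trial(default_arm, default_muscle,
                              noise_model(alpha_N = 0), default_manip,
                              profile = prof, phi = 0.3, seed = 3,
                              reflex_on = FALSE)
  # noise-free unperturbed reaction force is exactly zero (co-contraction cancels)
  expect_lt(max(abs(tr$twin$u_ext)), 1e-10)
  # measured force reproduces rigid-body minus muscle torques at every sample
  tau_ext <- force_to_torque_vec(tr$q, tr$u_ext, default_arm)
  tau_rb <- inverse_dynamics(tr$q, tr$qd, tr$qdd, default_arm)
  gt <- intrinsic_joint_impedance(tr$muscle, tr$a[1, ])
  q_ref <- matrix(inverse_kinematics(tr$posture, default_arm), nrow(tr$q), 2,
                  byrow = TRUE)
  tau_int <- (q_ref - tr$q) %*% t(gt$K_q) - tr$qd %*% t(gt$D_q)
  expect_lt(max(abs(tau_rb - tau_int - tau_ext)), 1e-9)
})
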