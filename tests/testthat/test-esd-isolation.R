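test_that("ESD satisfies Parseval and locates spectral peaks", {
  fs <- 2000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- 3 * sin(2 * pi * 25 * t)
  e <- esd(x, fs)
  df <- e$f[2] - e$f[1]
  energy_time <- sum(x^2) / fs
  expect_equal(sum(e$psi) * df, energy_time, tolerance = 0.01)
  expect_equal(e$f[which.max(e$psi)], 25, tolerance = df * 1.5)
  expect_equal(esd(rep(0, 1000), fs)$psi, rep(0, length(esd(rep(0, 1000), fs)$psi)))
})

test_that("crossing rule finds a constructed crossing and respects persistence", {
  f <- seq(0, 20, by = 0.25)
  # unperturbed spectrum decays; feedback spectrum overtakes at exactly 3 Hz
  psi_up <- 100 * exp(-f)
  psi_fb <- 100 * exp(-3) * (f / 3)^2
  expect_equal(crossing_frequency(f, psi_up, psi_fb), 3, tolerance = 0.26)
  # a single-bin spike below the true crossing must be rejected
  psi_fb2 <- psi_fb
  psi_fb2[f == 1] <- 2 * psi_up[f == 1]
  expect_equal(crossing_frequency(f, psi_up, psi_fb2, persist = 3), 3,
               tolerance = 0.26)
  expect_equal(crossing_frequency(f, psi_up, psi_fb2, persist = 1), 1)
  # degenerate dominance: feedback above everywhere -> first non-DC bin
  expect_equal(crossing_frequency(f, rep(0, length(f)), rep(1, length(f))), 0.25)
  # no crossing -> NA, and select_cutoffs escalates it to an error
  expect_true(is.na(crossing_frequency(f, psi_up + 1e9, psi_fb)))
  expect_error(select_cutoffs(list(), fs = 100), "at least one")
})

test_that("cutoff selection separates constructed low and high bands end to end", {
  # unperturbed movements: pure sub-2 Hz content; perturbations add strong
  # high-band content; every crossing must land between the bands
  fs <- 200
  n <- 20 * fs
  t <- seq_len(n) / fs
  hif <- function(seed) {
    set.seed(seed + 100)
    0.5 * sin(2 * pi * 5 * t + runif(1, 0, 6)) + 0.3 * sin(2 * pi * 9 * t)
  }
  lowf <- function(seed) {
    set.seed(seed)
    0.02 * sin(2 * pi * 0.8 * t + runif(1, 0, 6))
  }
  trials <- lapply(1:4, function(s) {
    tw <- new_trial_for_test(cbind(lowf(s), lowf(s + 50)), fs)
    new_trial_for_test(cbind(lowf(s) + hif(s), lowf(s + 50) + hif(s + 7)), fs,
                       perturbed = TRUE, twin = tw)
  })
  es <- select_cutoffs(trials, fs = fs)
  expect_s3_class(es, "esd_set")
  expect_true(all(es$f_c_HP < 5.2))
  expect_true(all(es$psi_UP >= 0) && all(es$psi_P >= 0))
  expect_equal(es$psi_FB, es$psi_P - es$psi_UP)
})

test_that("decomposition identity holds exactly and unperturbed input yields ~zero", {
  tr <- lite_dynamic_trial()
  vd <- reconstruct_variational(tr, c(1.7, 1.9), 0.115, default_manip, default_arm)
  expect_equal(vd$dx + tr$x[vd$window, ], vd$x_star)
  expect_equal(vd$du_ext + tr$u_ext[vd$window, ], vd$u_ext_star)
  expect_equal(vd$dq + vd$q, vd$q_star)
  expect_equal(vd$dtau_ext,
               force_to_torque_vec(vd$q_star, vd$u_ext_star, default_arm) -
                 force_to_torque_vec(vd$q, tr$u_ext[vd$window, ], default_arm),
               tolerance = 1e-12)
  # variational position starts at zero and stays millimetre-scale
  expect_lt(max(abs(vd$dx[1, ])), 1e-4)
  expect_lt(max(abs(vd$dx)), 0.02)
  # feeding the unperturbed twin through the filter gives near-zero variation
  tw <- tr$twin
  tw$perturbed <- TRUE
  tw$onset_index <- tr$onset_index
  vd0 <- reconstruct_variational(tw, c(1.7, 1.9), 0.115, default_manip, default_arm)
  expect_lt(max(abs(vd0$dx)), 0.1 * max(abs(vd$dx)))
})

test_that("twin-referenced variational series start at zero at onset", {
  tr <- lite_dynamic_trial()
  tv <- twin_variational(tr, 0.115, default_manip)
  expect_equal(tv$dx[1, ], c(0, 0), tolerance = 1e-12)
  raw <- twin_variational(tr, 0.115, default_manip, processed = FALSE)
  expect_equal(raw$dxd[1, ], c(0, 0), tolerance = 1e-12)
  expect_equal(dim(tv$du_ext), c(231, 2))
})

test_that("static variational dynamics are the commanded profile, negated", {
  prof <- build_perturbation(1, 0.160)
  tr <- simulate_static_trial(default_arm, default_muscle, noise_model(),
                              default_manip, profile = prof, phi = pi / 3,
                              seed = 5)
  vd <- static_variational(tr, 0.4, default_arm)
  expect_equal(max(sqrt(rowSums(vd$dx^2))), 0.008, tolerance = 1e-9)
  expect_equal(vd$dx,
               -cbind(cos(pi / 3) * tr$pert_kinematics$p[vd$window],
                      sin(pi / 3) * tr$pert_kinematics$p[vd$window]),
               tolerance = 1e-9)
  expect_equal(vd$dx + tr$x[vd$window, ], vd$x_star, tolerance = 1e-12)
  # filtered regression blocks appear when cutoffs are supplied
  vdf <- static_variational(tr, 0.4, default_arm, f_c = c(1.5, 1.5))
  expect_equal(dim(vdf$A), c(2 * 801, 11))
  expect_length(vdf$b, 2 * 801)
})
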