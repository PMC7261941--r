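make_pert_set <- function(n = 4, seed = 500) {
  prof <- build_perturbation(40, 0.07)
  angles <- pert_angle_set()[c(1, 11, 5, 15, 3, 13)][seq_len(n)]
  trials <- lapply(seq_len(n), function(k) {
    simulate_dynamic_trial(default_arm, default_muscle, noise_model(),
                           default_manip, prof, phi = angles[k],
                           seed = seed + k, T_tail = 0.3)
  })
  structure(list(trials = trials, kind = "dynamic", fs = 2000, seed = seed,
                 arm = default_arm, muscle = default_muscle,
                 noise = noise_model(), manip = default_manip),
            class = "trial_set")
}

pert_set <- make_pert_set()

test_that("GOM unbiased trajectories are zero at onset and identical trials give zero variation", {
  gv <- gom_variational(pert_set, 0.115, default_arm)
  expect_length(gv, 4)
  for (vd in gv) expect_equal(vd$dx[1, ] + vd$x[1, ] - vd$x_star[1, ], c(0, 0),
                              tolerance = 1e-12)
  # identical trials: reference equals each trial, variational is zero
  same <- pert_set
  same$trials <- rep(pert_set$trials[1], 3)
  gv0 <- gom_variational(same, 0.115, default_arm)
  expect_lt(max(abs(gv0[[1]]$dx)), 1e-12)
  expect_lt(max(abs(gv0[[1]]$du_ext)), 1e-12)
  expect_error(gom_variational(pert_set$trials[1], 0.115, default_arm),
               "at least two")
})

test_that("GOM estimate is an unconstrained linear solve (stiffness may be asymmetric)", {
  gv <- gom_variational(pert_set, 0.115, default_arm)
  ge <- gom_estimate(gv, bip_from_standard(default_arm))
  expect_s3_class(ge, "baseline_estimate")
  expect_false(isTRUE(all.equal(ge$K_q, t(ge$K_q), tolerance = 1e-12)))
  expect_true(is.finite(ge$residual))
})

test_that("GOM and the main estimator coincide on true variational data", {
  vs <- synthetic_varsets(n_trials = 4, seed = 77)
  pi_true <- c(0.18, 0.06, 0.07)
  ge <- gom_estimate(vs, pi_true)
  fe <- dynamic_impedance_estimate(vs, pi_true)
  expect_equal(ge$D_q, fe$D_q, tolerance = 1e-4)
  expect_equal((ge$K_q + t(ge$K_q)) / 2, fe$K_q, tolerance = 1e-4)
})

test_that("ERD produces diagonal matrices and exact statics", {
  ee <- erd_estimate(pert_set, 0.115)
  expect_true(all(ee$M_x[row(ee$M_x) != col(ee$M_x)] == 0))
  expect_true(all(ee$D_x[row(ee$D_x) != col(ee$D_x)] == 0))
  expect_true(all(ee$K_x[row(ee$K_x) != col(ee$K_x)] == 0))
  # for a constant underlying movement the onset offset IS the unperturbed state
  prof <- build_perturbation(1, 0.160)
  strial <- simulate_static_trial(default_arm, default_muscle,
                                  noise_model(alpha_N = 0), default_manip,
                                  profile = prof, phi = 0.5, seed = 1,
                                  reflex_on = FALSE)
  ss <- structure(list(trials = list(strial), kind = "static", fs = 2000),
                  class = "trial_set")
  es <- erd_estimate(ss, 0.4)
  vd <- es$varsets[[1]]
  tv <- static_variational(strial, 0.4, default_arm)
  expect_equal(vd$dx, unname(tv$dx), tolerance = 1e-9)
})

test_that("baseline ordering on shared data: FJI beats GOM beats ERD on position", {
  iso <- lapply(pert_set$trials, reconstruct_variational, f_c = c(1.7, 1.9),
                T_est = 0.115, manip = default_manip, arm = default_arm)
  gv <- gom_variational(pert_set, 0.115, default_arm)
  ee <- erd_estimate(pert_set, 0.115)
  score <- function(vsets) {
    mean(sapply(seq_along(pert_set$trials), function(i) {
      tv <- twin_variational(pert_set$trials[[i]], 0.115, default_manip)
      nrmse(tv$dx, vsets[[i]]$dx)
    }))
  }
  s_fji <- score(iso)
  s_gom <- score(gv)
  s_erd <- score(ee$varsets)
  expect_lt(s_fji, s_gom)
  expect_lt(s_gom, s_erd)
})
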