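pi_true <- c(0.18, 0.06, 0.07)
D_true <- matrix(c(2.4, 1.2, 1.1, 1.5), 2, 2, byrow = TRUE)
K_true <- matrix(c(29, 14, 14, 17), 2, 2, byrow = TRUE)

test_that("static stage recovers all parameters exactly from model data", {
  vs <- synthetic_varsets(pi_true = pi_true, D_true = D_true, K_true = K_true)
  fit <- static_bip_estimate(vs)
  expect_equal(fit$pi_hat, pi_true, tolerance = 1e-6)
  expect_equal(matrix(fit$zeta[4:7], 2, 2, byrow = TRUE), D_true, tolerance = 1e-6)
  expect_equal(matrix(fit$zeta[8:11], 2, 2, byrow = TRUE), K_true, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  # duplicating every observation leaves the solution unchanged
  fit2 <- static_bip_estimate(c(vs, vs))
  expect_equal(fit2$pi_hat, fit$pi_hat, tolerance = 1e-9)
})

test_that("static stage reports rank deficiency", {
  vs <- synthetic_varsets(n_trials = 1, N = 40)
  vs[[1]]$dq[] <- 0
  vs[[1]]$dqd[] <- 0
  expect_error(static_bip_estimate(vs), "rank deficient")
})

test_that("dynamic stage recovers symmetric-PD stiffness and free damping exactly", {
  vs <- synthetic_varsets(pi_true = pi_true, D_true = D_true, K_true = K_true)
  est <- dynamic_impedance_estimate(vs, pi_true)
  expect_equal(est$D_q, D_true, tolerance = 1e-4)
  expect_equal(est$K_q, K_true, tolerance = 1e-4)
  # Cholesky construction: exact symmetry, PSD, and K = L L'
  expect_identical(est$K_q, est$L_q %*% t(est$L_q))
  expect_identical(est$K_q - t(est$K_q), matrix(0, 2, 2))
  expect_true(all(diag(est$L_q) >= 0))
  # asymmetric damping is representable
  Dasym <- matrix(c(2.4, 1.9, 0.4, 1.5), 2, 2, byrow = TRUE)
  vs2 <- synthetic_varsets(D_true = Dasym, K_true = K_true, seed = 13)
  est2 <- dynamic_impedance_estimate(vs2, pi_true)
  expect_equal(est2$D_q, Dasym, tolerance = 1e-4)
})

test_that("wrong a-priori inertial parameters bias the fit but keep K symmetric PSD", {
  vs <- synthetic_varsets(pi_true = pi_true, D_true = D_true, K_true = K_true,
                          seed = 5)
  est <- dynamic_impedance_estimate(vs, pi_true * 1.2)
  expect_gt(est$residual, 1e-6)
  ev <- eigen(est$K_q, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10))
})

test_that("sliding windows enumerate n - width + 1 contiguous windows", {
  w <- sliding_windows(60, 20)
  expect_length(w, 41)
  expect_equal(w[[1]], 1:20)
  expect_equal(w[[41]], 41:60)
  expect_length(sliding_windows(20, 20), 1)
  expect_equal(sliding_windows(5, 2), list(1:2, 2:3, 3:4, 4:5))
  expect_error(sliding_windows(5, 6), "exceeds")
})

test_that("interval sweep reproduces the default at matching T_est and flags short windows", {
  vs <- synthetic_varsets(n_trials = 6, N = 240, pi_true = pi_true,
                          D_true = D_true, K_true = K_true)
  T_full <- vs[[1]]$T_est
  sw <- interval_sweep(vs, pi_true, T_values = c(T_full / 2, T_full), width = 6)
  expect_equal(nrow(sw), 2)
  ref <- dynamic_impedance_estimate(vs, pi_true)
  row_full <- sw[sw$T_est == T_full, ]
  expect_equal(unlist(row_full[c("K11", "K12", "K21", "K22")], use.names = FALSE),
               as.numeric(t(ref$K_q)), tolerance = 1e-6)
  # residual non-decreasing with window length at fixed parameters
  expect_lte(sw$residual[sw$T_est == T_full / 2], sw$residual[sw$T_est == T_full] + 1e-9)
  expect_true(all(is.finite(sw$cond)))
})

test_that("truncate_window shortens every series consistently", {
  vs <- synthetic_varsets(n_trials = 1, N = 200)
  vd <- truncate_window(vs[[1]], vs[[1]]$T_est / 2)
  expect_lte(max(vd$tp), vs[[1]]$T_est / 2 + 1e-9)
  expect_equal(nrow(vd$dq), length(vd$tp))
  expect_equal(nrow(vd$dtau_ext), length(vd$tp))
})

test_that("pooled estimates are invariant to trial relabeling", {
  vs <- synthetic_varsets(n_trials = 5, seed = 31)
  est1 <- dynamic_impedance_estimate(vs, pi_true)
  est2 <- dynamic_impedance_estimate(vs[c(3, 1, 5, 2, 4)], pi_true)
  expect_equal(est1$K_q, est2$K_q, tolerance = 1e-8)
  expect_equal(est1$D_q, est2$D_q, tolerance = 1e-8)
})
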