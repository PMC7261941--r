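test_that("forward kinematics matches closed-form anchor points", {
  arm <- arm_params(l1 = 0.3, l2 = 0.3)
  expect_equal(forward_kinematics(c(pi / 2, 0), arm), c(0, 0.6), tolerance = 1e-12)
  expect_equal(forward_kinematics(c(0, pi / 2), arm), c(0.3, 0.3), tolerance = 1e-12)
})

test_that("kinematic round trip is identity on the open workspace annulus", {
  arm <- default_arm
  set.seed(7)
  q <- cbind(runif(50, -1.2, 1.8), runif(50, 0.15, 2.9))
  x <- forward_kinematics(q, arm)
  q2 <- inverse_kinematics(x, arm)
  wrapped <- (q - q2 + pi) %% (2 * pi) - pi      # q1 is only defined mod 2*pi
  expect_lt(max(abs(wrapped)), 1e-10)
  x2 <- forward_kinematics(q2, arm)
  expect_lt(max(abs(x - x2)), 1e-10)
})

test_that("inverse kinematics enforces workspace bounds and elbow branch", {
  arm <- default_arm
  expect_error(inverse_kinematics(c(0, arm$l1 + arm$l2 + 0.01), arm), "outer workspace")
  expect_error(inverse_kinematics(c(0, 0.01), arm), "inner workspace")
  # right-angle elbow from the cosine law
  q <- inverse_kinematics(c(0, sqrt(arm$l1^2 + arm$l2^2)), arm)
  expect_equal(q[2], pi / 2, tolerance = 1e-12)
  # just inside the extension limit
  qex <- inverse_kinematics(c(0, (arm$l1 + arm$l2) * (1 - 1e-12)), arm)
  expect_equal(qex[1], pi / 2, tolerance = 1e-4)
  expect_lt(qex[2], 1e-4)
  # elbow always on the flexed branch
  set.seed(8)
  qs <- cbind(runif(20, -1, 1), runif(20, 0.2, 2.8))
  qr <- inverse_kinematics(forward_kinematics(qs, arm), arm)
  expect_true(all(qr[, 2] > 0 & qr[, 2] < pi))
})

test_that("jacobian matches finite differences of forward kinematics", {
  arm <- default_arm
  st <- random_states(10, seed = 21)
  h <- 1e-7
  for (i in 1:10) {
    q <- st$q[i, ]
    J <- jacobian(q, arm)
    Jfd <- sapply(1:2, function(j) {
      dq <- c(0, 0); dq[j] <- h
      (forward_kinematics(q + dq, arm) - forward_kinematics(q - dq, arm)) / (2 * h)
    })
    expect_lt(max(abs(J - Jfd)), 1e-6)
  }
  # singular at full extension
  expect_equal(det(jacobian(c(pi / 2, 0), arm)), 0, tolerance = 1e-12)
})

test_that("Jacobian-transpose force map preserves mechanical power", {
  arm <- default_arm
  st <- random_states(25, seed = 3)
  set.seed(4)
  u <- cbind(rnorm(25, sd = 10), rnorm(25, sd = 10))
  for (i in 1:25) {
    J <- jacobian(st$q[i, ], arm)
    tau <- crossprod(J, u[i, ])
    xd <- J %*% st$qd[i, ]
    expect_equal(sum(u[i, ] * xd), sum(tau * st$qd[i, ]), tolerance = 1e-10)
  }
  expect_equal(endpoint_force_to_torque(c(0.5, 1), cbind(0, 0), arm),
               c(0, 0))
})

test_that("regressor-Lagrangian equivalence holds at 100 random states", {
  arm <- default_arm
  pb <- bip_from_standard(arm)
  st <- random_states(100, seed = 42)
  worst <- 0
  for (i in 1:100) {
    mc <- mass_coriolis(st$q[i, ], st$qd[i, ], arm)
    tau_lagr <- mc$M %*% st$qdd[i, ] + mc$C %*% st$qd[i, ]
    tau_regr <- base_regressor(st$q[i, ], st$qd[i, ], st$qdd[i, ]) %*% pb
    worst <- max(worst, max(abs(tau_lagr - tau_regr)))
    expect_true(isSymmetric(mc$M))
    expect_true(all(eigen(mc$M, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
  expect_lt(worst, 1e-9)
})

test_that("base regressor anchor values and statics", {
  expect_equal(base_regressor(c(0.3, 0.8), c(0, 0), c(0, 0)),
               matrix(0, 2, 3))
  expect_equal(base_regressor(c(0.1, 0), c(0, 0), c(1, 0)),
               matrix(c(1, 1, 2, 0, 1, 1), 2, 3, byrow = TRUE))
  # no Coriolis torque at rest
  mc <- mass_coriolis(c(0.4, 1.1), c(0, 0), default_arm)
  expect_equal(mc$C %*% c(0, 0), matrix(0, 2, 1))
})

test_that("base inertial parameters follow the parallel-axis reduction", {
  arm <- default_arm
  pb <- bip_from_standard(arm)
  I1 <- arm$I1_cg + arm$m1 * arm$lc1^2
  I2 <- arm$I2_cg + arm$m2 * arm$lc2^2
  expect_equal(pb, c(I1 + arm$m2 * arm$l1^2, I2, arm$m2 * arm$lc2 * arm$l1))
  expect_true(all(pb > 0))
  # doubling l1 quadruples the m2 l1^2 contribution
  arm2 <- arm_params(l1 = 2 * arm$l1, l2 = arm$l2, lc1 = arm$lc1,
                     lc2 = arm$lc2, m1 = arm$m1, m2 = arm$m2,
                     I1_cg = arm$I1_cg, I2_cg = arm$I2_cg)
  expect_equal(bip_from_standard(arm2)[1] - I1,
               4 * (pb[1] - I1), tolerance = 1e-12)
  expect_error(arm_params(m1 = -1), "strictly positive")
})

test_that("vectorized kinematic maps agree with the scalar versions", {
  arm <- default_arm
  st <- random_states(30, seed = 11)
  jc <- joint_to_cartesian_vec(st$q, st$qd, st$qdd, arm)
  back <- cartesian_to_joint_vec(jc$x, jc$xd, jc$xdd, arm)
  expect_lt(max(abs(back$q - st$q)), 1e-9)
  expect_lt(max(abs(back$qd - st$qd)), 1e-8)
  expect_lt(max(abs(back$qdd - st$qdd)), 1e-7)
  loop <- cartesian_to_joint(jc$x, jc$xd, jc$xdd, arm)
  expect_equal(loop$qdd, back$qdd, tolerance = 1e-9)
  set.seed(12)
  u <- cbind(rnorm(30), rnorm(30))
  tau <- force_to_torque_vec(st$q, u, arm)
  expect_equal(tau, as_config <- endpoint_force_to_torque(st$q, u, arm),
               tolerance = 1e-12)
  expect_lt(max(abs(torque_to_force_vec(st$q, tau, arm) - u)), 1e-10)
})
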