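test_that("sin_block endpoints, quarter-period peaks, zero net velocity", {
  b <- sin_block(2, 0.1, 2000)
  expect_equal(b$a[1], 0)
  expect_equal(b$a[length(b$a)], 0, tolerance = 1e-12)
  expect_equal(b$a[b$t == 0.025], 2)
  expect_equal(b$a[b$t == 0.075], -2)
  # numeric quadrature oracle: net velocity is zero
  expect_lt(abs(sum((b$a[-1] + b$a[-length(b$a)]) / 2) / 2000), 1e-10)
  expect_error(sin_block(1, -0.1, 2000), "positive")
  expect_error(sin_block(NaN, 0.1, 2000), "finite")
  expect_error(sin_block(1, 0.001, 2000), "fs too low")
})

test_that("perturbation durations follow the 3/2 rule", {
  p70 <- build_perturbation(40, 0.070)
  expect_equal(p70$T_pert, 0.175)
  p160 <- build_perturbation(40, 0.160)
  expect_equal(p160$T_pert, 0.400)
  expect_equal(p70$T_p2, 1.5 * p70$T_p1)
})

test_that("terminal position and velocity vanish to 1e-9 of peak", {
  for (Tp1 in c(0.070, 0.160)) {
    p <- build_perturbation(40, Tp1)
    n <- length(p$t)
    expect_lt(abs(p$v_prof[n]) / max(abs(p$v_prof)), 1e-9)
    expect_lt(abs(p$p_prof[n]) / max(abs(p$p_prof)), 1e-9)
    expect_lt(abs(p$a_prof[n]) / max(abs(p$a_prof)), 1e-9)
    expect_lt(abs(p$u_prof[n]) / max(abs(p$u_prof)), 1e-9)
    # analytic integrals agree with cumulative trapezoid oracle
    vn <- cumtrapz(p$a_prof, 1 / p$fs)
    pn <- cumtrapz(vn, 1 / p$fs)
    expect_lt(max(abs(vn - p$v_prof)) / max(abs(p$v_prof)), 1e-3)
    expect_lt(max(abs(pn - p$p_prof)) / max(abs(p$p_prof)), 2e-3)
  }
})

test_that("first-peak force normalization and amplitude linearity", {
  p <- build_perturbation(40, 0.070)
  expect_equal(max(abs(p$u_prof[p$t <= p$T_p1])), 40, tolerance = 1e-10)
  p2 <- build_perturbation(80, 0.070)
  expect_equal(p2$u_prof, 2 * p$u_prof, tolerance = 1e-10)
  expect_equal(p2$p_prof, 2 * p$p_prof, tolerance = 1e-10)
})

test_that("acceleration profile is continuous at the block junction", {
  p <- build_perturbation(40, 0.070)
  i <- which.min(abs(p$t - p$T_p1))
  expect_lt(abs(p$a_prof[i]), 1e-9 * max(abs(p$a_prof)))
  expect_lt(max(abs(diff(p$a_prof))), 1.2 * max(abs(p$a_prof)) *
              (4 * pi / p$T_p1) / p$fs)
})

test_that("the perturbation angle set has 20 non-cardinal angles", {
  a <- pert_angle_set()
  expect_length(a, 20)
  expect_false(any(sapply(a, function(x) isTRUE(all.equal(x %% (pi / 2), 0)))))
  # enumeration oracle: k = 1..24 minus multiples of 6
  expect_equal(a, (pi / 12) * setdiff(1:24, c(6, 12, 18, 24)))
  expect_true(all(diff(a) > 0) && a[1] > 0 && a[20] < 2 * pi)
})

test_that("pert_force direction, peak, antisymmetry and support", {
  p <- build_perturbation(40, 0.070)
  t <- seq(0, 0.3, by = 5e-4)
  u0 <- pert_force(p, 0, t)
  expect_true(all(u0[, 2] == 0))
  expect_equal(max(sqrt(rowSums(pert_force(p, 1.1, t)^2))), 40, tolerance = 1e-9)
  expect_equal(pert_force(p, 1.1 + pi, t), -pert_force(p, 1.1, t), tolerance = 1e-12)
  expect_true(all(u0[t > p$T_pert, ] == 0))
})
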