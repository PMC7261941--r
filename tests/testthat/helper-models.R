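# shared fixtures: all synthetic, generated in code

default_arm <- arm_params()
default_muscle <- muscle_model()
default_manip <- manipulandum()

# deterministic "random" joint states away from singularity
random_states <- function(n, seed = 123) {
  set.seed(seed)
  list(q = cbind(runif(n, -1, 1.5), runif(n, 0.3, 2.6)),
       qd = cbind(rnorm(n), rnorm(n)),
       qdd = cbind(rnorm(n, sd = 5), rnorm(n, sd = 5)))
}

# small dynamic trial pair cache (noise on), built once per test run
lite_dynamic_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prof <- build_perturbation(40, 0.07)
      cache <<- simulate_dynamic_trial(default_arm, default_muscle,
                                       noise_model(), default_manip,
                                       profile = prof, phi = pi / 12, seed = 401)
    }
    cache
  }
})

# bare-bones trial wrapper for spectral tests (only x/u_ext/flags used)
new_trial_for_test <- function(x, fs, perturbed = FALSE, twin = NULL,
                               u_ext = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  structure(list(t = seq_len(n) / fs, x = x,
                 xd = matrix(0, n, 2), xdd = matrix(0, n, 2),
                 u_ext = if (is.null(u_ext)) matrix(0, n, 2) else u_ext,
                 q = matrix(0, n, 2), qd = matrix(0, n, 2),
                 qdd = matrix(0, n, 2), a = NULL, fs = fs,
                 perturbed = perturbed, phi = NA_real_,
                 onset_index = NA_integer_, seed = 0, kind = "synthetic",
                 twin = twin),
            class = "fji_trial")
}

# exact synthetic variational windows drawn from a model world: joint series
# are smooth analytic functions; dtau generated exactly from (pi, D, K)
synthetic_varsets <- function(n_trials = 4, N = 120, fs = 2000,
                              pi_true = c(0.18, 0.06, 0.07),
                              D_true = matrix(c(2.4, 1.2, 1.1, 1.5), 2, 2, byrow = TRUE),
                              K_true = matrix(c(29, 14, 14, 17), 2, 2, byrow = TRUE),
                              seed = 99) {
  set.seed(seed)
  lapply(seq_len(n_trials), function(k) {
    t <- seq(0, by = 1 / fs, length.out = N)
    ph <- runif(4, 0, 2 * pi)
    q_star <- cbind(0.6 + 0.02 * sin(2 * pi * 3 * t + ph[1]),
                    1.4 + 0.03 * sin(2 * pi * 4 * t + ph[2]))
    qd_star <- cbind(0.02 * 2 * pi * 3 * cos(2 * pi * 3 * t + ph[1]),
                     0.03 * 2 * pi * 4 * cos(2 * pi * 4 * t + ph[2]))
    qdd_star <- cbind(-0.02 * (2 * pi * 3)^2 * sin(2 * pi * 3 * t + ph[1]),
                      -0.03 * (2 * pi * 4)^2 * sin(2 * pi * 4 * t + ph[2]))
    dq <- cbind(0.004 * sin(2 * pi * 8 * t + ph[3]) * t / t[N],
                0.006 * sin(2 * pi * 6 * t + ph[4]) * t / t[N])
    dqd <- cbind(c(0, diff(dq[, 1])) * fs, c(0, diff(dq[, 2])) * fs)
    dqdd <- cbind(c(0, diff(dqd[, 1])) * fs, c(0, diff(dqd[, 2])) * fs)
    q <- q_star - dq
    qd <- qd_star - dqd
    qdd <- qdd_star - dqdd
    dY <- base_regressor_series(q_star, qd_star, qdd_star) -
      base_regressor_series(q, qd, qdd)
    dtau <- matrix(dY %*% pi_true, ncol = 2, byrow = TRUE) +
      dqd %*% t(D_true) + dq %*% t(K_true)
    structure(list(tp = t, window = seq_len(N), onset_index = 1,
                   T_est = t[N], fs = fs, f_c = c(0, 0), phi = 0,
                   q_star = q_star, qd_star = qd_star, qdd_star = qdd_star,
                   q = q, qd = qd, qdd = qdd,
                   dq = dq, dqd = dqd, dqdd = dqdd, dtau_ext = dtau),
              class = "variational_dynamics")
  })
}
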