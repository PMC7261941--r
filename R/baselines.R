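#' Variational dynamics via averaged unbiased perturbed movements (GOM)
#'
#' Reference estimator in the style of Gomi & Kawato: every perturbed trial
#' is unbiased by subtracting its state at perturbation onset (position,
#' velocity, acceleration and force offsets), the unbiased trajectories are
#' averaged across all perturbed trials to form the unperturbed reference,
#' and each trial's variational dynamics are the reference minus its own
#' unbiased trajectory (`Delta chi = chi* - chi` convention). The estimated
#' unperturbed trajectory per trial is its own onset offset plus the common
#' reference. Unperturbed trials are not used.
#'
#' @param trials A `trial_set` or list of perturbed `fji_trial`s.
#' @param T_est Estimation window duration \[s\].
#' @param arm An [arm_params()] object (joint-space conversion).
#' @return List of `variational_dynamics` objects, one per perturbed trial.
#' @export
gom_variational <- function(trials, T_est, arm) {
  tl <- if (inherits(trials, "trial_set")) trials$trials else trials
  tl <- Filter(function(tr) isTRUE(tr$perturbed), tl)
  if (length(tl) < 2) stop("gom_variational: need at least two perturbed trials")
  fs <- tl[[1]]$fs
  nw <- round(T_est * fs)
  chans <- c("x", "xd", "xdd", "u_ext")
  unb <- lapply(tl, function(tr) {
    widx <- tr$onset_index:(tr$onset_index + nw)
    lapply(stats::setNames(chans, chans), function(ch) {
      s <- tr[[ch]][widx, , drop = FALSE]
      sweep(s, 2, s[1, ], `-`)
    })
  })
  ref <- lapply(stats::setNames(chans, chans), function(ch) {
    Reduce(`+`, lapply(unb, `[[`, ch)) / length(unb)
  })
  lapply(seq_along(tl), function(i) {
    tr <- tl[[i]]
    widx <- tr$onset_index:(tr$onset_index + nw)
    star <- lapply(stats::setNames(chans, chans), function(ch) {
      sweep(ref[[ch]], 2, tr[[ch]][widx[1], ], `+`)
    })
    js_star <- cartesian_to_joint_vec(star$x, star$xd, star$xdd, arm)
    tau_star <- force_to_torque_vec(js_star$q, star$u_ext, arm)
    q_p <- tr$q[widx, ]
    tau_p <- force_to_torque_vec(q_p, tr$u_ext[widx, ], arm)
    structure(list(tp = (widx - tr$onset_index) / fs,
                   window = widx, onset_index = tr$onset_index,
                   T_est = T_est, fs = fs, f_c = c(NA, NA), phi = tr$phi,
                   dx = star$x - tr$x[widx, ],
                   dxd = star$xd - tr$xd[widx, ],
                   dxdd = star$xdd - tr$xdd[widx, ],
                   dxddd = NULL,
                   du_ext = star$u_ext - tr$u_ext[widx, ],
                   x_star = star$x, xd_star = star$xd, xdd_star = star$xdd,
                   u_ext_star = star$u_ext,
                   q_star = js_star$q, qd_star = js_star$qd,
                   qdd_star = js_star$qdd, tau_ext_star = tau_star,
                   dq = js_star$q - q_p,
                   dqd = js_star$qd - tr$qd[widx, ],
                   dqdd = js_star$qdd - tr$qdd[widx, ],
                   dtau_ext = tau_star - tau_p,
                   q = q_p, qd = tr$qd[widx, ], qdd = tr$qdd[widx, ],
                   x = tr$x[widx, ], u_ext = tr$u_ext[widx, ]),
              class = "variational_dynamics")
  })
}

#' GOM-style joint-space impedance estimate
#'
#' Linear least squares for the damping and stiffness matrices on GOM
#' variational data with the base inertial parameters fixed a priori
#' (linearized rigid-body terms via the regressor difference). Stiffness
#' symmetry is not enforced, matching the unconstrained linear formulation.
#'
#' @param varsets List of `variational_dynamics` from [gom_variational()].
#' @param pi_hat A-priori base inertial parameters (length 3).
#' @param T_est Optional truncation of the windows \[s\].
#' @param window_id Identifier stored in the result.
#' @return A `baseline_estimate` with `method = "GOM"`, `D_q`, `K_q`,
#'   `residual`.
#' @export
gom_estimate <- function(varsets, pi_hat, T_est = NULL, window_id = NA) {
  if (!is.null(T_est)) varsets <- lapply(varsets, truncate_window, T_est = T_est)
  blocks <- lapply(varsets, regression_blocks)
  A <- do.call(rbind, lapply(blocks, `[[`, "A"))
  b <- unlist(lapply(blocks, `[[`, "b"))
  bbar <- b - A[, 1:3] %*% pi_hat
  th <- qr.coef(qr(A[, 4:11]), bbar)
  res <- bbar - A[, 4:11] %*% th
  structure(list(method = "GOM",
                 pi_hat = as.numeric(pi_hat),
                 D_q = matrix(th[1:4], 2, 2, byrow = TRUE),
                 K_q = matrix(th[5:8], 2, 2, byrow = TRUE),
                 residual = sum(res^2), window_id = window_id),
            class = "baseline_estimate")
}

#' ERD-style Cartesian impedance estimate
#'
#' Reference estimator in the style of Erden & Billard: variational
#' positions and forces are the onset values minus the measured series (the
#' unperturbed state is assumed constant over the window), variational
#' velocities and accelerations follow by Savitzky-Golay differentiation of
#' the variational position, and diagonal Cartesian inertia, damping and
#' stiffness matrices are estimated simultaneously per axis by linear least
#' squares on `Delta u = M_x Delta xdd + D_x Delta xd + K_x Delta x`.
#'
#' @param trials A `trial_set` or list of perturbed `fji_trial`s.
#' @param T_est Estimation window duration \[s\].
#' @param window_id Identifier stored in the result.
#' @return A `baseline_estimate` with `method = "ERD"`, diagonal 2 x 2
#'   `M_x`, `D_x`, `K_x`, `residual`, and the per-trial variational series
#'   in `$varsets` (fields `dx`, `dxd`, `dxdd`, `du_ext`).
#' @export
erd_estimate <- function(trials, T_est, window_id = NA) {
  tl <- if (inherits(trials, "trial_set")) trials$trials else trials
  tl <- Filter(function(tr) isTRUE(tr$perturbed), tl)
  if (length(tl) < 1) stop("erd_estimate: need perturbed trials with onsets")
  fs <- tl[[1]]$fs
  nw <- round(T_est * fs)
  varsets <- lapply(tl, function(tr) {
    widx <- tr$onset_index:(tr$onset_index + nw)
    dx <- sweep(-tr$x[widx, , drop = FALSE], 2, tr$x[widx[1], ], `+`)
    du <- sweep(-tr$u_ext[widx, , drop = FALSE], 2, tr$u_ext[widx[1], ], `+`)
    dxd <- apply(dx, 2, sg_filter, fs = fs, window = sg_window_cached(fs, 50, 7),
                 poly_order = 7, deriv = 1)
    dxdd <- apply(dx, 2, sg_filter, fs = fs, window = sg_window_cached(fs, 50, 7),
                  poly_order = 7, deriv = 2)
    list(tp = (widx - tr$onset_index) / fs, dx = dx, dxd = dxd, dxdd = dxdd,
         du_ext = du, phi = tr$phi)
  })
  fit_axis <- function(ax) {
    X <- do.call(rbind, lapply(varsets, function(v) {
      cbind(v$dxdd[, ax], v$dxd[, ax], v$dx[, ax])
    }))
    y <- unlist(lapply(varsets, function(v) v$du_ext[, ax]))
    th <- qr.coef(qr(X), y)
    list(th = th, rss = sum((y - X %*% th)^2))
  }
  f1 <- fit_axis(1)
  f2 <- fit_axis(2)
  structure(list(method = "ERD",
                 M_x = diag(c(f1$th[1], f2$th[1])),
                 D_x = diag(c(f1$th[2], f2$th[2])),
                 K_x = diag(c(f1$th[3], f2$th[3])),
                 residual = f1$rss + f2$rss,
                 varsets = varsets, window_id = window_id),
            class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf("%s baseline estimate (residual %.4g)\n", x$method, x$residual))
  invisible(x)
}
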