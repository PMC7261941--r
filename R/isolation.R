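#' Endpoint jerk by Savitzky-Golay differentiation
#'
#' Third derivative of each position channel with a seventh-order
#' Savitzky-Golay smoothing differentiator whose window is sized to realize
#' approximately the requested cutoff frequency at the given sample rate.
#'
#' @param x n x 2 (or vector) position series \[m\].
#' @param fs Sample rate \[Hz\].
#' @param fc_sg Smoothing cutoff \[Hz\].
#' @param poly_order Polynomial order.
#' @return Jerk series \[m/s^3\], same shape as `x`.
#' @export
compute_jerk <- function(x, fs, fc_sg = 50, poly_order = 7) {
  w <- sg_window_cached(fs, fc_sg, poly_order)
  if (is.matrix(x)) {
    apply(x, 2, sg_filter, fs = fs, window = w, poly_order = poly_order,
          deriv = 3)
  } else {
    sg_filter(x, fs, w, poly_order, deriv = 3)
  }
}

.sg_cache <- new.env(parent = emptyenv())
sg_window_cached <- function(fs, fc, poly_order) {
  key <- paste(fs, fc, poly_order, sep = "_")
  if (is.null(.sg_cache[[key]])) {
    .sg_cache[[key]] <- sg_window_for_cutoff(fs, fc, poly_order)
  }
  .sg_cache[[key]]
}

#' Energy spectral density of a finite signal
#'
#' One-sided Riemann approximation of the continuous-time energy spectral
#' density `psi(f) = |integral exp(-2 pi i f t) x(t) dt|^2`, computed as
#' `|dt * DFT(x)|^2` on a zero-padded grid, with interior bins doubled so
#' that `sum(psi) * df` equals the total signal energy `integral x(t)^2 dt`
#' (Parseval).
#'
#' @param x Numeric signal (one channel).
#' @param fs Sample rate \[Hz\].
#' @param nfft FFT length; defaults to the next power of two at least four
#'   times the signal length (zero-padding refines the frequency grid).
#' @return List with frequency grid `f` \[Hz\] and `psi`
#'   \[signal-units^2 s^2\].
#' @export
esd <- function(x, fs, nfft = NULL) {
  n <- length(x)
  if (is.null(nfft)) nfft <- 2^ceiling(log2(max(4 * n, 8)))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  dt <- 1 / fs
  half <- nfft %/% 2
  psi <- (dt * Mod(X[1:(half + 1)]))^2
  # fold negative frequencies so that sum(psi) * df = energy
  psi[2:half] <- 2 * psi[2:half]
  f <- (0:half) * fs / nfft
  list(f = f, psi = psi)
}

#' Select high-pass cutoff frequencies from a trial set
#'
#' For each Cartesian axis, averages the jerk energy spectral densities of
#' all unperturbed movements (`psi_UP`, taken from the trials' unperturbed
#' twins) and of all perturbed movements (`psi_P`); the feedback spectrum is
#' `psi_FB = psi_P - psi_UP`. The cutoff is the lowest frequency above which
#' `psi_FB` exceeds `psi_UP` for at least `persist` consecutive bins (the
#' persistence requirement rejects single-bin noise crossings).
#'
#' @param trials A `trial_set` (perturbed trials with twins) or list of
#'   trials.
#' @param fs Sample rate \[Hz\]; defaults to the set's rate.
#' @param persist Number of consecutive bins the crossing must hold.
#' @param nfft FFT length passed to [esd()].
#' @param signal Which series carries the separation: `"jerk"` (endpoint
#'   jerk, the default, used for the dynamic task) or `"force"` (measured
#'   external force, used for the open-loop static task where the commanded
#'   kinematics carry no noise and the noise-vs-perturbation separation
#'   lives in the force channel).
#' @return An `esd_set`: list with `f`, 2-column matrices `psi_UP`, `psi_P`,
#'   `psi_FB`, and per-axis cutoffs `f_c_HP` \[Hz\].
#' @export
select_cutoffs <- function(trials, fs = NULL, persist = 3, nfft = NULL,
                           signal = c("jerk", "force")) {
  signal <- match.arg(signal)
  tl <- if (inherits(trials, "trial_set")) trials$trials else trials
  if (is.null(fs)) fs <- tl[[1]]$fs
  pert <- Filter(function(tr) isTRUE(tr$perturbed), tl)
  unpert <- c(Filter(function(tr) !isTRUE(tr$perturbed), tl),
              lapply(pert, `[[`, "twin"))
  unpert <- Filter(Negate(is.null), unpert)
  if (length(pert) == 0 || length(unpert) == 0) {
    stop("select_cutoffs: need at least one perturbed and one unperturbed trial")
  }
  avg_psi <- function(set) {
    acc <- NULL
    f <- NULL
    for (tr in set) {
      jj <- if (signal == "jerk") compute_jerk(tr$x, fs) else tr$u_ext
      e1 <- esd(jj[, 1], fs, nfft)
      e2 <- esd(jj[, 2], fs, nfft)
      if (is.null(acc)) {
        acc <- cbind(e1$psi, e2$psi)
        f <- e1$f
      } else {
        acc <- acc + cbind(e1$psi, e2$psi)
      }
    }
    list(f = f, psi = acc / length(set))
  }
  up <- avg_psi(unpert)
  pp <- avg_psi(pert)
  psi_fb <- pp$psi - up$psi
  f_c <- vapply(1:2, function(ax) {
    fc <- crossing_frequency(up$f, up$psi[, ax], psi_fb[, ax], persist)
    if (is.na(fc)) {
      stop(sprintf("select_cutoffs: no persistent psi_FB > psi_UP crossing below Nyquist on axis %d", ax))
    }
    fc
  }, 0)
  structure(list(f = up$f, psi_UP = up$psi, psi_P = pp$psi, psi_FB = psi_fb,
                 f_c_HP = f_c, n_UP = length(unpert), n_P = length(pert)),
            class = "esd_set")
}

#' Lowest persistent spectral crossing
#'
#' Returns the lowest frequency from which `psi_FB > psi_UP` holds for at
#' least `persist` consecutive bins (the DC bin is ignored), or `NA` if no
#' such run exists.
#'
#' @param f Frequency grid \[Hz\].
#' @param psi_UP,psi_FB Spectra on `f`.
#' @param persist Required run length \[bins\].
#' @return Scalar frequency \[Hz\] or `NA`.
#' @export
crossing_frequency <- function(f, psi_UP, psi_FB, persist = 3) {
  above <- psi_FB > psi_UP
  above[1] <- FALSE
  run <- stats::filter(as.numeric(above), rep(1, persist), sides = 1)
  i <- which(run == persist)[1]
  if (is.na(i)) NA_real_ else f[i - persist + 1]
}

#' @export
print.esd_set <- function(x, ...) {
  cat(sprintf("ESD set: %d unperturbed / %d perturbed trials, cutoffs f_c_HP = [%.2f, %.2f] Hz\n",
              x$n_UP, x$n_P, x$f_c_HP[1], x$f_c_HP[2]))
  invisible(x)
}

#' Zero-phase high-pass filtering of a jerk series
#'
#' Order-10 Butterworth high-pass realized as a biquad cascade, applied
#' forward and backward for zero phase distortion.
#'
#' @param jerk Numeric jerk series (one channel).
#' @param f_c Cutoff \[Hz\].
#' @param fs Sample rate \[Hz\].
#' @param order Filter order.
#' @return Filtered series, same length, zero phase lag.
#' @export
highpass_jerk <- function(jerk, f_c, fs, order = 10) {
  filtfilt_sos(butter_sos(order, f_c, fs, "high"), jerk)
}

#' Reconstruct variational and unperturbed dynamics from a perturbed trial
#'
#' The feedback-jerk-isolation pipeline: the jerk content of the perturbed
#' movement above the per-axis cutoff `f_c` is attributed to the evoked
#' feedback; integrating it with zero initial conditions imposed half a
#' Savitzky-Golay window before perturbation onset (where the acausal
#' measurement chain is still untouched by post-onset data) yields the
#' variational acceleration, velocity and position.
#' The first integral is evaluated in commuted form -- the zero-phase
#' high-pass filter applied to the Savitzky-Golay acceleration, zeroed at
#' onset -- which is equivalent for linear time-invariant filtering and
#' keeps every kinematic order on the measurement chain's own operator; all
#' perturbed-trial derivatives are taken from the position series with the
#' same Savitzky-Golay configuration. Unperturbed estimates are perturbed
#' plus variational contributions (`chi* = Delta chi + chi` channel-wise,
#' exactly). The estimated unperturbed external force follows from the
#' admittance relation applied to the estimated unperturbed kinematics, and
#' joint-space counterparts from the inverse kinematics and the Jacobian
#' transpose map.
#'
#' All variational quantities use the convention `Delta chi = chi* - chi`
#' (unperturbed minus perturbed).
#'
#' @param trial A perturbed `fji_trial`.
#' @param f_c Per-axis high-pass cutoffs \[Hz\] (length 2, or scalar).
#' @param T_est Estimation interval duration \[s\].
#' @param manip A [manipulandum()] object.
#' @param arm An [arm_params()] object.
#' @return A `variational_dynamics` object over the window
#'   `[onset, onset + T_est]`: time-from-onset `tp`, Cartesian `dx`, `dxd`,
#'   `dxdd`, `dxddd`, `du_ext`, `x_star`, `xd_star`, `xdd_star`,
#'   `u_ext_star`, joint-space `q_star`, `qd_star`, `qdd_star`,
#'   `tau_ext_star`, `dq`, `dqd`, `dqdd`, `dtau_ext`, plus perturbed-window
#'   copies and metadata.
#' @param fc_sg,poly_order Savitzky-Golay configuration of the measurement
#'   chain (all perturbed-trial derivatives are taken with the same
#'   operators).
#' @export
reconstruct_variational <- function(trial, f_c, T_est, manip, arm,
                                    fc_sg = 50, poly_order = 7) {
  if (!isTRUE(trial$perturbed) || is.na(trial$onset_index)) {
    stop("reconstruct_variational: trial must be perturbed with a valid onset")
  }
  fs <- trial$fs
  n <- nrow(trial$x)
  onset <- trial$onset_index
  nw <- round(T_est * fs)
  if (onset + nw > n) stop("reconstruct_variational: onset + T_est exceeds the trial")
  f_c <- rep(f_c, length.out = 2)

  # measurement-chain kinematics of the perturbed movement: all derivatives
  # come from the same Savitzky-Golay operators (in an experiment only the
  # position series is observed)
  w_sg <- sg_window_cached(fs, fc_sg, poly_order)
  sgd <- function(x, d) apply(x, 2, sg_filter, fs = fs, window = w_sg,
                              poly_order = poly_order, deriv = d)
  xd_p <- sgd(trial$x, 1)
  xdd_p <- sgd(trial$x, 2)

  jerk <- compute_jerk(trial$x, fs, fc_sg, poly_order)
  djerk <- -vapply(1:2, function(ax) highpass_jerk(jerk[, ax], f_c[ax], fs),
                   numeric(n))
  # Variational acceleration: high-pass the measured acceleration and zero it
  # at the integration reference. For linear time-invariant filtering this is
  # the commuted form of "high-pass the jerk, then integrate once" and keeps
  # the estimate on the same Savitzky-Golay operator as the acceleration it
  # is subtracted from. The zero initial conditions are imposed half a
  # Savitzky-Golay window BEFORE onset: at the onset sample itself the
  # acausal differentiation window already straddles post-onset data, so the
  # measured-chain variational quantities are not yet zero there; one
  # half-window earlier they are (twins are identical pre-onset).
  hw <- (w_sg - 1) / 2
  i0 <- max(1, onset - hw)
  dacc_full <- vapply(1:2, function(ax) {
    ha <- filtfilt_sos(butter_sos(10, f_c[ax], fs, "high"), xdd_p[, ax])
    -(ha - ha[i0])
  }, numeric(n))
  tail_idx <- i0:n
  dt <- 1 / fs
  dxd_t <- apply(dacc_full[tail_idx, , drop = FALSE], 2, cumtrapz, dt = dt)
  dx_t <- apply(dxd_t, 2, cumtrapz, dt = dt)

  keep <- (onset - i0 + 1):(onset - i0 + 1 + nw)   # window rows in tail_idx
  widx <- onset:(onset + nw)
  dx <- dx_t[keep, , drop = FALSE]
  dxd <- dxd_t[keep, , drop = FALSE]
  dxdd <- dacc_full[widx, , drop = FALSE]
  dxddd <- djerk[widx, , drop = FALSE]

  x_star <- trial$x[widx, ] + dx
  xd_star <- xd_p[widx, ] + dxd
  xdd_star <- xdd_p[widx, ] + dxdd
  u_star <- admittance_force(manip, xd_star, xdd_star)
  du <- u_star - trial$u_ext[widx, ]

  js_star <- cartesian_to_joint_vec(x_star, xd_star, xdd_star, arm)
  js_p <- cartesian_to_joint_vec(trial$x[widx, ], xd_p[widx, ], xdd_p[widx, ], arm)
  tau_star <- force_to_torque_vec(js_star$q, u_star, arm)
  q_p <- js_p$q
  tau_p <- force_to_torque_vec(q_p, trial$u_ext[widx, ], arm)

  structure(list(tp = (widx - onset) / fs,
                 window = widx, onset_index = onset, T_est = T_est, fs = fs,
                 f_c = f_c, phi = trial$phi,
                 dx = dx, dxd = dxd, dxdd = dxdd, dxddd = dxddd, du_ext = du,
                 x_star = x_star, xd_star = xd_star, xdd_star = xdd_star,
                 u_ext_star = u_star,
                 q_star = js_star$q, qd_star = js_star$qd,
                 qdd_star = js_star$qdd, tau_ext_star = tau_star,
                 dq = js_star$q - q_p,
                 dqd = js_star$qd - js_p$qd,
                 dqdd = js_star$qdd - js_p$qdd,
                 dtau_ext = tau_star - tau_p,
                 q = q_p, qd = js_p$qd, qdd = js_p$qdd,
                 x = trial$x[widx, ], u_ext = trial$u_ext[widx, ]),
            class = "variational_dynamics")
}

#' Variational dynamics of an open-loop static-task trial
#'
#' For open-loop position perturbations the variational kinematics are known
#' a priori (the commanded perturbation displacement), which is the exact
#' limit of the jerk-isolation pipeline when the unperturbed movement has no
#' jerk content: the unperturbed position is the held posture and the
#' unperturbed force is estimated by the pre-onset baseline mean of the
#' measured external force.
#'
#' When per-axis cutoffs `f_c` are supplied (selected from the force-channel
#' energy spectral densities, see [select_cutoffs()] with
#' `signal = "force"`), the full-length regression series of the
#' identification model -- every column of the independent-variable blocks
#' and the torque output -- are additionally passed through the same
#' zero-phase high-pass filter before windowing. Filtering both sides of a
#' linear time-invariant model with one filter preserves the model exactly
#' while suppressing the slow noise-driven wander of the unperturbed
#' reaction force that a constant baseline cannot capture. The stored
#' band-limited blocks (`$A`, `$b`) are used by [static_bip_estimate()].
#'
#' @param trial A perturbed static `fji_trial`.
#' @param T_est Estimation interval duration \[s\].
#' @param arm An [arm_params()] object.
#' @param T_baseline Pre-onset averaging time for the unperturbed force
#'   \[s\].
#' @param f_c Optional per-axis high-pass cutoffs \[Hz\] for the
#'   state-variable filtering of the regression series.
#' @return A `variational_dynamics` object (same contract as
#'   [reconstruct_variational()]); with `f_c` it additionally carries
#'   filtered regression blocks `A` (`(2N) x 11`) and `b`.
#' @export
static_variational <- function(trial, T_est, arm, T_baseline = 0.2,
                               f_c = NULL) {
  if (!isTRUE(trial$perturbed)) stop("static_variational: trial must be perturbed")
  fs <- trial$fs
  onset <- trial$onset_index
  nw <- round(T_est * fs)
  n <- nrow(trial$x)
  if (onset + nw > n) stop("static_variational: onset + T_est exceeds the trial")
  widx <- onset:(onset + nw)
  nb <- max(1, onset - round(T_baseline * fs))
  u_star_const <- colMeans(trial$u_ext[nb:onset, , drop = FALSE])

  # full-length series (needed for edge-safe zero-phase filtering)
  u_star_f <- matrix(u_star_const, n, 2, byrow = TRUE)
  q_star0 <- inverse_kinematics(trial$posture, arm)
  q_star_f <- matrix(q_star0, n, 2, byrow = TRUE)
  zero_f <- matrix(0, n, 2)
  tau_star_f <- force_to_torque_vec(q_star_f, u_star_f, arm)
  tau_p_f <- force_to_torque_vec(trial$q, trial$u_ext, arm)
  dq_f <- q_star_f - trial$q
  dqd_f <- -trial$qd
  dtau_f <- tau_star_f - tau_p_f
  dY_f <- base_regressor_series(q_star_f, zero_f, zero_f) -
    base_regressor_series(trial$q, trial$qd, trial$qdd)

  Ab <- NULL
  if (!is.null(f_c)) {
    fcmax <- max(f_c)
    sos <- butter_sos(10, fcmax, fs, "high")
    hp <- function(v) filtfilt_sos(sos, v)
    odd <- seq(1, 2 * n, by = 2)
    Af <- matrix(0, 2 * n, 11)
    Af[, 1:3] <- apply(dY_f, 2, function(col) {
      out <- numeric(2 * n)
      out[odd] <- hp(col[odd]); out[odd + 1] <- hp(col[odd + 1]); out
    })
    dqd_h <- apply(dqd_f, 2, hp)
    dq_h <- apply(dq_f, 2, hp)
    Af[odd, 4] <- dqd_h[, 1]; Af[odd, 5] <- dqd_h[, 2]
    Af[odd + 1, 6] <- dqd_h[, 1]; Af[odd + 1, 7] <- dqd_h[, 2]
    Af[odd, 8] <- dq_h[, 1]; Af[odd, 9] <- dq_h[, 2]
    Af[odd + 1, 10] <- dq_h[, 1]; Af[odd + 1, 11] <- dq_h[, 2]
    dtau_h <- apply(dtau_f, 2, hp)
    rows <- as.numeric(t(cbind(2 * widx - 1, 2 * widx)))
    Ab <- list(A = Af[rows, , drop = FALSE],
               b = as.numeric(t(dtau_h[widx, , drop = FALSE])))
  }

  u_star <- u_star_f[widx, ]
  pk <- trial$pert_kinematics
  dirmat <- function(s) cbind(pk$dir[1] * s[widx], pk$dir[2] * s[widx])
  q_p <- trial$q[widx, ]
  zero <- matrix(0, length(widx), 2)

  structure(list(tp = (widx - onset) / fs,
                 window = widx, onset_index = onset, T_est = T_est, fs = fs,
                 f_c = if (is.null(f_c)) c(0, 0) else rep(f_c, length.out = 2),
                 phi = trial$phi,
                 dx = -dirmat(pk$p), dxd = -dirmat(pk$v),
                 dxdd = -dirmat(pk$a), dxddd = -dirmat(pk$j),
                 du_ext = u_star - trial$u_ext[widx, ],
                 x_star = matrix(trial$posture, length(widx), 2, byrow = TRUE),
                 xd_star = zero, xdd_star = zero,
                 u_ext_star = u_star,
                 q_star = q_star_f[widx, ], qd_star = zero, qdd_star = zero,
                 tau_ext_star = tau_star_f[widx, ],
                 dq = dq_f[widx, ],
                 dqd = dqd_f[widx, ],
                 dqdd = -trial$qdd[widx, ],
                 dtau_ext = dtau_f[widx, ],
                 q = q_p, qd = trial$qd[widx, ], qdd = trial$qdd[widx, ],
                 x = trial$x[widx, ], u_ext = trial$u_ext[widx, ],
                 A = Ab$A, b = Ab$b),
            class = "variational_dynamics")
}

#' True variational dynamics from a simulator twin
#'
#' Ground-truth counterpart of [reconstruct_variational()], computed as the
#' difference between the unperturbed twin and the perturbed trial over the
#' estimation window (convention `Delta chi = chi* - chi`).
#'
#' By default the twin references are measurement-equivalent: velocities and
#' accelerations of both trials are obtained with the same Savitzky-Golay
#' operators used throughout the processing pipeline, and the forces via the
#' admittance relation applied to those processed kinematics (this is how the
#' signals of an unperturbed twin would present themselves through the
#' apparatus' signal-conditioning chain). The references then score the
#' isolation step itself rather than the band limit of the common
#' differentiation chain. Set `processed = FALSE` to compare against the raw
#' simulator states instead.
#'
#' @param trial A perturbed `fji_trial` with `$twin`.
#' @param T_est Estimation interval duration \[s\].
#' @param manip A [manipulandum()] object (needed for processed force
#'   references; defaults to the standard apparatus).
#' @param processed Use measurement-equivalent references (default) or raw
#'   simulator states.
#' @param fc_sg,poly_order Savitzky-Golay configuration of the measurement
#'   chain.
#' @return List with `tp`, `dx`, `dxd`, `dxdd`, `du_ext` over the window.
#' @export
twin_variational <- function(trial, T_est, manip = manipulandum(),
                             processed = TRUE, fc_sg = 50, poly_order = 7) {
  if (is.null(trial$twin)) stop("twin_variational: trial has no unperturbed twin")
  fs <- trial$fs
  widx <- trial$onset_index:(trial$onset_index + round(T_est * fs))
  tw <- trial$twin
  if (!processed) {
    return(list(tp = (widx - trial$onset_index) / fs,
                dx = tw$x[widx, ] - trial$x[widx, ],
                dxd = tw$xd[widx, ] - trial$xd[widx, ],
                dxdd = tw$xdd[widx, ] - trial$xdd[widx, ],
                du_ext = tw$u_ext[widx, ] - trial$u_ext[widx, ]))
  }
  w <- sg_window_cached(fs, fc_sg, poly_order)
  sgd <- function(x, d) apply(x, 2, sg_filter, fs = fs, window = w,
                              poly_order = poly_order, deriv = d)
  xd_t <- sgd(tw$x, 1); xdd_t <- sgd(tw$x, 2)
  xd_p <- sgd(trial$x, 1); xdd_p <- sgd(trial$x, 2)
  # unperturbed force reference through the same chain as the estimator:
  # admittance relation on the processed twin kinematics, minus the measured
  # perturbed force
  u_t <- admittance_force(manip, xd_t, xdd_t)
  list(tp = (widx - trial$onset_index) / fs,
       dx = tw$x[widx, ] - trial$x[widx, ],
       dxd = xd_t[widx, ] - xd_p[widx, ],
       dxdd = xdd_t[widx, ] - xdd_p[widx, ],
       du_ext = u_t[widx, ] - trial$u_ext[widx, ])
}
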