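#' Regression blocks of the involuntary impedance model
#'
#' For each sample of a variational-dynamics window, the linear identification
#' model reads `Delta tau_ext = Delta Ybar pibar + D_q Delta qd + K_q
#' Delta q`, where `Delta Ybar` is the difference of the base regressor at
#' the estimated unperturbed and the perturbed state. This helper stacks the
#' per-sample 2 x 11 independent-variable matrices and the output vector for
#' the full 11-parameter vector
#' `zeta = (pi1, pi2, pi3, D11, D12, D21, D22, K11, K12, K21, K22)`.
#'
#' @param vd A `variational_dynamics` object.
#' @return List with `(2N) x 11` matrix `A` and length-`2N` vector `b`.
#' @export
regression_blocks <- function(vd) {
  dY <- base_regressor_series(vd$q_star, vd$qd_star, vd$qdd_star) -
    base_regressor_series(vd$q, vd$qd, vd$qdd)
  N <- nrow(vd$dq)
  A <- matrix(0, 2 * N, 11)
  odd <- seq(1, 2 * N, by = 2)
  A[, 1:3] <- dY
  A[odd, 4] <- vd$dqd[, 1]; A[odd, 5] <- vd$dqd[, 2]
  A[odd + 1, 6] <- vd$dqd[, 1]; A[odd + 1, 7] <- vd$dqd[, 2]
  A[odd, 8] <- vd$dq[, 1]; A[odd, 9] <- vd$dq[, 2]
  A[odd + 1, 10] <- vd$dq[, 1]; A[odd + 1, 11] <- vd$dq[, 2]
  b <- as.numeric(t(vd$dtau_ext))
  list(A = A, b = b)
}

#' Static-stage estimation of the base inertial parameters
#'
#' Pools the regression blocks of all static-task windows and solves the
#' full 11-parameter linear model by least squares (orthogonal
#' factorization). The damping and stiffness entries act as nuisance
#' parameters absorbing the feedback evoked by the position perturbation;
#' only the three base inertial parameters are retained.
#'
#' @param varsets List of `variational_dynamics` objects (typically all 100
#'   static trials).
#' @param T_est Estimation window duration used to build the windows \[s\]
#'   (metadata only; windows are taken as supplied).
#' @return List with `pi_hat` (length 3), the full `zeta` (length 11), the
#'   residual sum of squares `rss`, and the condition number `cond` of the
#'   observation matrix.
#' @export
static_bip_estimate <- function(varsets, T_est = 0.4) {
  blocks <- lapply(varsets, function(vd) {
    if (!is.null(vd$A)) list(A = vd$A, b = vd$b) else regression_blocks(vd)
  })
  A <- do.call(rbind, lapply(blocks, `[[`, "A"))
  b <- unlist(lapply(blocks, `[[`, "b"))
  if (nrow(A) < ncol(A)) stop("static_bip_estimate: fewer samples than parameters")
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= .Machine$double.eps * max(dim(A)) * sv[1]) {
    stop(sprintf("static_bip_estimate: observation matrix is rank deficient (singular values %s)",
                 paste(signif(sv, 3), collapse = ", ")))
  }
  qr_fit <- qr(A)
  zeta <- qr.coef(qr_fit, b)
  res <- b - A %*% zeta
  list(pi_hat = as.numeric(zeta[1:3]), zeta = as.numeric(zeta),
       rss = sum(res^2), cond = sv[1] / sv[length(sv)], n = nrow(A) / 2)
}

#' Dynamic-stage estimation of involuntary damping and stiffness
#'
#' With the base inertial parameters fixed a priori, the output becomes
#' `bbar = Delta tau_ext - Delta Ybar pibar_hat` and the model
#' `f(zetabar) = D_q Delta qd + L_q t(L_q) Delta q - bbar` is minimized in
#' the seven parameters `(D11, D12, D21, D22, L11, L21, L22)` by a
#' Levenberg-Marquardt scheme with analytic Jacobian. The Cholesky
#' parameterization enforces symmetry and positive semidefiniteness of the
#' stiffness by construction; damping is unconstrained. The deterministic
#' start is the unconstrained linear solution with its stiffness block
#' symmetrized and eigenvalue-clipped to the positive cone.
#'
#' @param varsets List of `variational_dynamics` objects (one estimation
#'   window per trial; typically the 20 trials of a sliding window).
#' @param pi_hat Length-3 base-inertial-parameter vector from the static
#'   stage.
#' @param T_est Truncate each window to this duration \[s\] (`NULL` keeps
#'   the windows as supplied).
#' @param max_iter,gtol Solver limits: maximum iterations and gradient-norm
#'   tolerance.
#' @param window_id Identifier stored in the result.
#' @return An `impedance_estimate`: `pi_hat`, 2 x 2 `D_q`, `K_q`, lower
#'   triangular `L_q`, `residual` (sum of squared residuals), `iterations`,
#'   `gradient_norm`, `window_id`.
#' @export
dynamic_impedance_estimate <- function(varsets, pi_hat, T_est = NULL,
                                       max_iter = 200, gtol = 1e-10,
                                       window_id = NA) {
  if (!is.null(T_est)) varsets <- lapply(varsets, truncate_window, T_est = T_est)
  blocks <- lapply(varsets, regression_blocks)
  A <- do.call(rbind, lapply(blocks, `[[`, "A"))
  b <- unlist(lapply(blocks, `[[`, "b"))
  bbar <- b - A[, 1:3] %*% pi_hat
  Ad <- A[, 4:7]                       # damping block (linear)
  dq <- do.call(rbind, lapply(varsets, `[[`, "dq"))
  N <- nrow(dq)
  odd <- seq(1, 2 * N, by = 2)

  # deterministic initialization: unconstrained linear solve, PSD-clipped
  lin <- qr.coef(qr(A[, 4:11]), bbar)
  K0m <- matrix(lin[5:8], 2, 2, byrow = TRUE)
  K0s <- (K0m + t(K0m)) / 2
  eg <- eigen(K0s, symmetric = TRUE)
  lam <- pmax(eg$values, 1e-8)
  L <- t(chol(eg$vectors %*% diag(lam) %*% t(eg$vectors)))
  theta <- c(lin[1:4], L[1, 1], L[2, 1], L[2, 2])

  resid_jac <- function(th) {
    L11 <- th[5]; L21 <- th[6]; L22 <- th[7]
    K <- matrix(c(L11^2, L11 * L21, L11 * L21, L21^2 + L22^2), 2, 2)
    r <- as.numeric(Ad %*% th[1:4])
    r[odd] <- r[odd] + K[1, 1] * dq[, 1] + K[1, 2] * dq[, 2]
    r[odd + 1] <- r[odd + 1] + K[2, 1] * dq[, 1] + K[2, 2] * dq[, 2]
    r <- r - bbar
    J <- cbind(Ad, 0, 0, 0)
    J[odd, 5] <- 2 * L11 * dq[, 1] + L21 * dq[, 2]
    J[odd, 6] <- L11 * dq[, 2]
    J[odd + 1, 5] <- L21 * dq[, 1]
    J[odd + 1, 6] <- L11 * dq[, 1] + 2 * L21 * dq[, 2]
    J[odd + 1, 7] <- 2 * L22 * dq[, 2]
    list(r = r, J = J)
  }

  lambda <- 1e-6
  rj <- resid_jac(theta)
  cost <- sum(rj$r^2)
  it <- 0
  gnorm <- Inf
  while (it < max_iter) {
    it <- it + 1
    g <- crossprod(rj$J, rj$r)
    gnorm <- sqrt(sum(g^2))
    if (gnorm < gtol * (1 + cost)) break
    H <- crossprod(rj$J)
    step_ok <- FALSE
    for (k in 1:30) {
      delta <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12), -g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        rj_new <- resid_jac(cand)
        if (sum(rj_new$r^2) < cost) {
          theta <- cand
          rj <- rj_new
          cost <- sum(rj$r^2)
          lambda <- max(lambda / 3, 1e-12)
          step_ok <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!step_ok) break                  # no further improvement possible
  }
  if (it >= max_iter && gnorm >= gtol * (1 + cost)) {
    stop(sprintf("dynamic_impedance_estimate: no convergence after %d iterations (gradient norm %.3e)",
                 max_iter, gnorm))
  }
  # sign convention: non-negative Cholesky diagonal (mirror solutions)
  if (theta[5] < 0) theta[5:6] <- -theta[5:6]
  if (theta[7] < 0) theta[7] <- -theta[7]
  L <- matrix(c(theta[5], 0, theta[6], theta[7]), 2, 2, byrow = TRUE)
  structure(list(pi_hat = as.numeric(pi_hat),
                 D_q = matrix(theta[1:4], 2, 2, byrow = TRUE),
                 K_q = L %*% t(L), L_q = L,
                 residual = cost, iterations = it, gradient_norm = gnorm,
                 window_id = window_id, n = N),
            class = "impedance_estimate")
}

#' @export
print.impedance_estimate <- function(x, ...) {
  cat("Involuntary impedance estimate\n")
  cat(sprintf("  pi_hat = [%.4f, %.4f, %.4f] kg m^2\n",
              x$pi_hat[1], x$pi_hat[2], x$pi_hat[3]))
  cat(sprintf("  D_q = [%.2f %.2f; %.2f %.2f] N m s/rad\n",
              x$D_q[1, 1], x$D_q[1, 2], x$D_q[2, 1], x$D_q[2, 2]))
  cat(sprintf("  K_q = [%.2f %.2f; %.2f %.2f] N m/rad  (SPD: %s)\n",
              x$K_q[1, 1], x$K_q[1, 2], x$K_q[2, 1], x$K_q[2, 2],
              all(diag(x$L_q) > 0)))
  cat(sprintf("  residual = %.4g, %d iterations\n", x$residual, x$iterations))
  invisible(x)
}

truncate_window <- function(vd, T_est) {
  keep <- vd$tp <= T_est + 1e-12
  series <- c("tp", "dx", "dxd", "dxdd", "dxddd", "du_ext",
              "x_star", "xd_star", "xdd_star", "u_ext_star",
              "q_star", "qd_star", "qdd_star", "tau_ext_star",
              "dq", "dqd", "dqdd", "dtau_ext", "q", "qd", "qdd", "x", "u_ext")
  for (s in series) {
    if (is.matrix(vd[[s]])) vd[[s]] <- vd[[s]][keep, , drop = FALSE]
    else vd[[s]] <- vd[[s]][keep]
  }
  vd$window <- vd$window[keep]
  vd$T_est <- T_est
  vd
}

#' Sliding trial windows
#'
#' Contiguous windows of `width` trials moved along trial by trial:
#' `n - width + 1` windows in total (41 for 60 trials of width 20).
#'
#' @param trials Number of trials, or a list/`trial_set` whose length is
#'   used.
#' @param width Window width \[trials\].
#' @return List of integer index vectors.
#' @export
sliding_windows <- function(trials, width = 20) {
  n <- if (is.numeric(trials) && length(trials) == 1) trials
       else length(if (inherits(trials, "trial_set")) trials$trials else trials)
  if (width > n) stop(sprintf("sliding_windows: width %d exceeds %d trials", width, n))
  lapply(seq_len(n - width + 1), function(i) i:(i + width - 1))
}

#' Estimation-interval sweep
#'
#' Re-runs the dynamic-stage estimator for several estimation-interval
#' durations on every sliding window and reports per-duration summaries.
#'
#' @param varsets List of `variational_dynamics` windows (one per trial,
#'   built with the longest duration in `T_values`).
#' @param pi_hat Static-stage base inertial parameters.
#' @param T_values Durations to evaluate \[s\].
#' @param width Sliding-window width \[trials\].
#' @param cond_limit Condition number of the linearized problem above which
#'   a duration is flagged ill-conditioned.
#' @return Data frame with one row per (T_est, window): estimates of all
#'   D/K elements, residual, and an `ill_conditioned` flag.
#' @export
interval_sweep <- function(varsets, pi_hat, T_values, width = 20,
                           cond_limit = 1e8) {
  wins <- sliding_windows(length(varsets), width)
  out <- list()
  for (T_est in T_values) {
    for (wi in seq_along(wins)) {
      vs <- lapply(varsets[wins[[wi]]], truncate_window, T_est = T_est)
      Afull <- do.call(rbind, lapply(lapply(vs, regression_blocks), `[[`, "A"))
      sv <- svd(Afull[, 4:11], nu = 0, nv = 0)$d
      cond <- sv[1] / sv[length(sv)]
      est <- dynamic_impedance_estimate(vs, pi_hat, window_id = wi)
      out[[length(out) + 1]] <- data.frame(
        T_est = T_est, window = wi,
        D11 = est$D_q[1, 1], D12 = est$D_q[1, 2],
        D21 = est$D_q[2, 1], D22 = est$D_q[2, 2],
        K11 = est$K_q[1, 1], K12 = est$K_q[1, 2],
        K21 = est$K_q[2, 1], K22 = est$K_q[2, 2],
        residual = est$residual, cond = cond,
        ill_conditioned = cond > cond_limit)
    }
  }
  do.call(rbind, out)
}
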