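#' Isolate variational dynamics for every perturbed trial of a set
#'
#' Dynamic-task sets go through the full feedback-jerk-isolation pipeline
#' (ESD-based cutoff selection once per set, then per-trial zero-phase
#' high-pass reconstruction); static-task sets use the a-priori open-loop
#' variational kinematics with baseline force subtraction.
#'
#' @param ts A `trial_set` from [run_dynamic_task()] or [run_static_task()].
#' @param T_est Estimation window duration \[s\]; defaults to 115 ms
#'   (dynamic) or 400 ms (static).
#' @return List with `varsets` (one `variational_dynamics` per perturbed
#'   trial, in trial order) and, for dynamic sets, the `esd_set` used.
#' @export
isolate_trials <- function(ts, T_est = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  if (ts$kind == "static") {
    if (is.null(T_est)) T_est <- 0.4
    es <- select_cutoffs(ts, signal = "force")
    vs <- lapply(ts$trials, static_variational, T_est = T_est, arm = ts$arm,
                 f_c = es$f_c_HP)
    return(list(varsets = vs, esd = es, T_est = T_est))
  }
  if (is.null(T_est)) T_est <- 0.115
  es <- select_cutoffs(ts)
  vs <- lapply(ts$trials, reconstruct_variational, f_c = es$f_c_HP,
               T_est = T_est, manip = ts$manip, arm = ts$arm)
  list(varsets = vs, esd = es, T_est = T_est)
}

#' Twin-referenced isolation quality of a dynamic trial set
#'
#' Computes the time-resolved normalized RMS errors of the estimated
#' variational position, velocity, acceleration and external force against
#' the simulator twins, per perturbed trial, over `[0, T_est]`.
#'
#' @param ts A dynamic `trial_set` (trials carry twins).
#' @param varsets Matching output of [isolate_trials()].
#' @return List with per-trial matrices (`n_samples x n_trials`) of
#'   time-resolved NRMSE for `dx`, `dxd`, `dxdd`, `du_ext`, plus the
#'   per-trial window maxima (`max_*`) and window averages (`avg_*`).
#' @export
isolation_quality <- function(ts, varsets) {
  T_est <- varsets$varsets[[1]]$T_est
  chans <- c(dx = "dx", dxd = "dxd", dxdd = "dxdd", du_ext = "du_ext")
  per_trial <- lapply(seq_along(ts$trials), function(i) {
    tr <- ts$trials[[i]]
    vd <- varsets$varsets[[i]]
    tv <- twin_variational(tr, T_est, manip = ts$manip)
    lapply(chans, function(ch) nrmse(tv[[ch]], vd[[ch]], time_resolved = TRUE))
  })
  out <- list()
  for (ch in names(chans)) {
    m <- vapply(per_trial, `[[`, numeric(length(per_trial[[1]][[ch]])), ch)
    out[[ch]] <- m
    out[[paste0("max_", ch)]] <- apply(m, 2, max)
    out[[paste0("avg_", ch)]] <- colMeans(m)
  }
  out
}

#' Static-stage analysis: base inertial parameters with accuracy
#'
#' Runs the isolation and the pooled static-stage least squares, and scores
#' the result against the simulator's true base inertial parameters.
#'
#' @param ts A static `trial_set`.
#' @param T_est Estimation window \[s\].
#' @return List with `pi_hat`, `pi_true`, per-element `nae` (fractions), and
#'   the estimator output `fit`.
#' @export
analyze_static <- function(ts, T_est = 0.4) {
  iso <- isolate_trials(ts, T_est)
  fit <- static_bip_estimate(iso$varsets, T_est)
  pi_true <- bip_from_standard(ts$arm)
  list(pi_hat = fit$pi_hat, pi_true = pi_true,
       nae = nae(pi_true, fit$pi_hat), fit = fit)
}

#' Dynamic-stage analysis: sliding-window damping/stiffness with accuracy
#'
#' Isolates all trials, runs the Cholesky-constrained nonlinear least squares
#' on every sliding window, and scores each window's estimate against the
#' simulator's window-averaged ground-truth intrinsic impedance. The NAE
#' normalizer per matrix is the maximum absolute element of the
#' window-averaged true matrix.
#'
#' @param ts A dynamic `trial_set`.
#' @param pi_hat Static-stage base inertial parameters.
#' @param T_est Estimation window \[s\].
#' @param width Sliding-window width \[trials\].
#' @return List with `estimates` (list of `impedance_estimate`),
#'   `nae_D`, `nae_K` (windows x 4 matrices of per-element NAE fractions,
#'   element order 11, 12, 21, 22), window-averaged truths, and the
#'   isolation output.
#' @export
analyze_dynamic <- function(ts, pi_hat, T_est = 0.115, width = 20) {
  iso <- isolate_trials(ts, T_est)
  wins <- sliding_windows(length(iso$varsets), width)
  gt <- lapply(ts$trials, ground_truth_impedance, window = c(0, T_est))
  ests <- vector("list", length(wins))
  nae_D <- matrix(0, length(wins), 4,
                  dimnames = list(NULL, c("11", "12", "21", "22")))
  nae_K <- nae_D
  for (wi in seq_along(wins)) {
    idx <- wins[[wi]]
    est <- dynamic_impedance_estimate(iso$varsets[idx], pi_hat, window_id = wi)
    D_true <- Reduce(`+`, lapply(gt[idx], `[[`, "D_q")) / length(idx)
    K_true <- Reduce(`+`, lapply(gt[idx], `[[`, "K_q")) / length(idx)
    nae_D[wi, ] <- nae(as.numeric(t(D_true)), as.numeric(t(est$D_q)),
                       normalizer = max(abs(D_true)))
    nae_K[wi, ] <- nae(as.numeric(t(K_true)), as.numeric(t(est$K_q)),
                       normalizer = max(abs(K_true)))
    ests[[wi]] <- est
  }
  list(estimates = ests, nae_D = nae_D, nae_K = nae_K,
       D_true_overall = Reduce(`+`, lapply(gt, `[[`, "D_q")) / length(gt),
       K_true_overall = Reduce(`+`, lapply(gt, `[[`, "K_q")) / length(gt),
       iso = iso, windows = wins)
}

#' Full validation study on synthetic data
#'
#' Replicates the two-task validation: per replication, simulate the static
#' task, estimate the base inertial parameters, simulate the dynamic task,
#' isolate the feedback, estimate damping and stiffness on all sliding
#' windows, and score isolation quality and parameter recovery. Replications
#' differ only in their master seeds.
#'
#' @param reps Number of replications.
#' @param seed Master seed (per-replication seeds derived from it).
#' @param arm,muscle,noise,manip Model components.
#' @param fs Sample rate \[Hz\].
#' @param quality Also compute twin-referenced NRMSE report (slightly more
#'   work).
#' @param progress Emit one message per replication.
#' @return List of per-replication results (`static`, `dynamic`,
#'   `quality`, `cutoffs`) plus the configuration.
#' @export
run_validation <- function(reps = 3, seed = 1,
                           arm = arm_params(), muscle = muscle_model(),
                           noise = noise_model(), manip = manipulandum(),
                           fs = 2000, quality = TRUE, progress = FALSE) {
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    rs <- per_trial_seed(seed, 100003 * r)
    if (progress) message(sprintf("replication %d/%d (seed %d)", r, reps, rs))
    st <- run_static_task(arm, muscle, noise, manip, seed = rs, fs = fs)
    sa <- analyze_static(st)
    dt <- run_dynamic_task(arm, muscle, noise, manip,
                           seed = per_trial_seed(rs, 1), fs = fs)
    da <- analyze_dynamic(dt, sa$pi_hat)
    qu <- if (quality) isolation_quality(dt, da$iso) else NULL
    out[[r]] <- list(static = sa, dynamic = da, quality = qu,
                     cutoffs = da$iso$esd$f_c_HP, seed = rs)
  }
  structure(list(reps = out, seed = seed, fs = fs),
            class = "fji_validation")
}

#' Summary tables of a validation study
#'
#' @param object A [run_validation()] result.
#' @param ... Unused.
#' @return List of data frames: `bip` (per-replication BIP NAEs, %),
#'   `impedance` (cross-window mean (SD) NAEs per element, %), and
#'   `isolation` (window-maximum and window-averaged NRMSEs, %).
#' @export
summary.fji_validation <- function(object, ...) {
  reps <- object$reps
  bip <- do.call(rbind, lapply(seq_along(reps), function(r) {
    data.frame(rep = r, t(100 * reps[[r]]$static$nae))
  }))
  names(bip)[2:4] <- c("pi1", "pi2", "pi3")
  imp <- do.call(rbind, lapply(seq_along(reps), function(r) {
    d <- reps[[r]]$dynamic
    data.frame(rep = r,
               element = rep(colnames(d$nae_D), 2),
               matrix = rep(c("D", "K"), each = 4),
               nae_mean = 100 * c(colMeans(d$nae_D), colMeans(d$nae_K)),
               nae_sd = 100 * c(apply(d$nae_D, 2, stats::sd),
                                apply(d$nae_K, 2, stats::sd)))
  }))
  iso <- do.call(rbind, lapply(seq_along(reps), function(r) {
    q <- reps[[r]]$quality
    if (is.null(q)) return(NULL)
    data.frame(rep = r,
               quantity = c("dx", "dxd", "dxdd", "du_ext"),
               nrmse_max = 100 * c(mean(q$max_dx), mean(q$max_dxd),
                                   mean(q$max_dxdd), mean(q$max_du_ext)),
               nrmse_avg = 100 * c(mean(q$avg_dx), mean(q$avg_dxd),
                                   mean(q$avg_dxdd), mean(q$avg_du_ext)))
  }))
  list(bip = bip, impedance = imp, isolation = iso)
}
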