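#' Write a trial set to a hierarchical on-disk container
#'
#' Stores a `trial_set` as a directory container: a `manifest.json` holding
#' per-trial metadata (perturbed flag, angle, onset index, seed) plus the
#' configuration summary and a format version, and one CSV per trial group
#' (`trial_001.csv`, ...; the unperturbed twin, when present, is stored as
#' `trial_001_twin.csv`) with columns `t, x1, x2, xd1, xd2, xdd1, xdd2,
#' u1, u2, q1, q2, qd1, qd2, qdd1, qdd2, a1..a6`. Numeric series are written
#' with full double precision so the round trip is exact to within decimal
#' float formatting.
#'
#' @param ts A `trial_set`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_trials <- function(ts, path) {
  stopifnot(inherits(ts, "trial_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "armfji-trials", version = 1L,
               kind = ts$kind, seed = ts$seed, fs = ts$fs,
               n_trials = length(ts$trials),
               trials = lapply(seq_along(ts$trials), function(i) {
                 tr <- ts$trials[[i]]
                 m <- list(id = i, perturbed = tr$perturbed,
                           phi = if (is.na(tr$phi)) NULL else tr$phi,
                           onset_index = if (is.na(tr$onset_index)) NULL else tr$onset_index,
                           seed = tr$seed, has_twin = !is.null(tr$twin))
                 if (!is.null(tr$posture)) m$posture <- tr$posture
                 m
               }))
  jsonlite::write_json(meta, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(ts$trials)) {
    tr <- ts$trials[[i]]
    write_trial_csv(tr, file.path(path, sprintf("trial_%03d.csv", i)))
    if (!is.null(tr$twin)) {
      write_trial_csv(tr$twin, file.path(path, sprintf("trial_%03d_twin.csv", i)))
    }
  }
  invisible(path)
}

write_trial_csv <- function(tr, file) {
  df <- data.frame(t = tr$t,
                   x1 = tr$x[, 1], x2 = tr$x[, 2],
                   xd1 = tr$xd[, 1], xd2 = tr$xd[, 2],
                   xdd1 = tr$xdd[, 1], xdd2 = tr$xdd[, 2],
                   u1 = tr$u_ext[, 1], u2 = tr$u_ext[, 2],
                   q1 = tr$q[, 1], q2 = tr$q[, 2],
                   qd1 = tr$qd[, 1], qd2 = tr$qd[, 2],
                   qdd1 = tr$qdd[, 1], qdd2 = tr$qdd[, 2])
  if (!is.null(tr$a)) {
    an <- as.data.frame(tr$a)
    names(an) <- paste0("a", seq_len(ncol(an)))
    df <- cbind(df, an)
  }
  if (!is.null(tr$pert_kinematics)) {
    pk <- tr$pert_kinematics
    df <- cbind(df, pk_p = pk$p, pk_v = pk$v, pk_a = pk$a, pk_j = pk$j,
                pk_dir1 = pk$dir[1], pk_dir2 = pk$dir[2])
  }
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   file, row.names = FALSE, quote = FALSE)
}

#' Read a trial set container written by [write_trials()]
#'
#' @param path Container directory.
#' @return A `trial_set` (without model-component objects, which are not
#'   serialized; metadata and all series are restored).
#' @export
read_trials <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("read_trials: no manifest.json under '%s'", path))
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(meta$format, "armfji-trials")) {
    stop("read_trials: not an armfji trial container (format mismatch)")
  }
  n <- meta$n_trials
  trials <- vector("list", n)
  field <- function(tm, name) {
    v <- tm[[name]]
    if (is.list(v)) v <- unlist(v)
    if (is.null(v) || length(v) == 0 || all(is.na(v))) NULL else v
  }
  for (i in seq_len(n)) {
    f <- file.path(path, sprintf("trial_%03d.csv", i))
    if (!file.exists(f)) {
      stop(sprintf("read_trials: container truncated, missing trial %d of %d", i, n))
    }
    tm <- meta$trials[i, ]
    phi <- field(tm, "phi")
    onset <- field(tm, "onset_index")
    tr <- read_trial_csv(f, meta$fs, kind = meta$kind,
                         perturbed = isTRUE(tm$perturbed),
                         phi = if (is.null(phi)) NA_real_ else phi,
                         onset_index = if (is.null(onset)) NA_integer_ else as.integer(onset),
                         seed = field(tm, "seed"))
    posture <- field(tm, "posture")
    if (!is.null(posture)) tr$posture <- as.numeric(posture)
    if (isTRUE(tm$has_twin)) {
      tw <- file.path(path, sprintf("trial_%03d_twin.csv", i))
      if (!file.exists(tw)) stop(sprintf("read_trials: missing twin for trial %d", i))
      tr$twin <- read_trial_csv(tw, meta$fs, kind = meta$kind,
                                perturbed = FALSE, phi = NA_real_,
                                onset_index = NA_integer_, seed = tm$seed)
    }
    trials[[i]] <- tr
  }
  structure(list(trials = trials, kind = meta$kind, seed = meta$seed,
                 fs = meta$fs),
            class = "trial_set")
}

read_trial_csv <- function(file, fs, kind, perturbed, phi, onset_index, seed) {
  df <- utils::read.csv(file)
  acol <- grep("^a[0-9]+$", names(df), value = TRUE)
  extra <- list()
  if ("pk_p" %in% names(df)) {
    extra$pert_kinematics <- list(p = df$pk_p, v = df$pk_v, a = df$pk_a,
                                  j = df$pk_j, dir = c(df$pk_dir1[1], df$pk_dir2[1]))
  }
  new_trial(t = df$t,
            x = cbind(df$x1, df$x2), xd = cbind(df$xd1, df$xd2),
            xdd = cbind(df$xdd1, df$xdd2), u_ext = cbind(df$u1, df$u2),
            q = cbind(df$q1, df$q2), qd = cbind(df$qd1, df$qd2),
            qdd = cbind(df$qdd1, df$qdd2),
            a = if (length(acol)) as.matrix(df[acol]) else NULL,
            fs = fs, perturbed = perturbed, phi = phi,
            onset_index = onset_index, seed = seed, kind = kind,
            extra = extra)
}

#' Export a perturbation profile as a tidy table
#'
#' @param profile A [build_perturbation()] object.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_profile <- function(profile, file) {
  utils::write.csv(data.frame(t = profile$t,
                              acceleration = profile$a_prof,
                              velocity = profile$v_prof,
                              position = profile$p_prof,
                              jerk = profile$j_prof,
                              force = profile$u_prof),
                   file, row.names = FALSE)
  invisible(file)
}
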