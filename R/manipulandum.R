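#' Admittance-controlled manipulandum parameters
#'
#' The apparatus renders a virtual inertia-damper: the admittance force is
#' `u_adm = M_adm xdd + D_adm xd` and the external force acting on the arm is
#' `u_ext = u_pert - u_adm - M_handle xdd`. Defaults are the rendered
#' admittance of the reference apparatus: `M_adm = diag(5, 5)` kg,
#' `D_adm = diag(20, 20)` N s/m, with zero handle inertia.
#'
#' @param M_adm 2 x 2 diagonal admittance inertia \[kg\] (scalar accepted).
#' @param D_adm 2 x 2 diagonal admittance damping \[N s/m\] (scalar accepted).
#' @param M_handle 2 x 2 diagonal handle inertia \[kg\] (scalar accepted).
#' @return A `manipulandum` object.
#' @export
manipulandum <- function(M_adm = 5, D_adm = 20, M_handle = 0) {
  as_diag2 <- function(v, name, min_ok = 0, strict = TRUE) {
    if (is.matrix(v)) {
      stopifnot(all(dim(v) == 2))
      if (any(v[row(v) != col(v)] != 0)) stop(sprintf("manipulandum: %s must be diagonal", name))
    } else {
      v <- diag(rep(v, length.out = 2), 2)
    }
    d <- diag(v)
    if (strict && any(d <= min_ok)) stop(sprintf("manipulandum: %s must be positive definite", name))
    if (!strict && any(d < min_ok)) stop(sprintf("manipulandum: %s must be positive semidefinite", name))
    v
  }
  structure(list(M_adm = as_diag2(M_adm, "M_adm"),
                 D_adm = as_diag2(D_adm, "D_adm"),
                 M_handle = as_diag2(M_handle, "M_handle", strict = FALSE)),
            class = "manipulandum")
}

#' External endpoint force from the admittance relation
#'
#' Evaluates `u_ext = u_pert - (M_adm + M_handle) xdd - D_adm xd` sample-wise.
#'
#' @param manip A [manipulandum()] object.
#' @param xd,xdd n x 2 endpoint velocity and acceleration.
#' @param u_pert n x 2 perturbation force (or `NULL` for none).
#' @return n x 2 external force \[N\].
#' @export
admittance_force <- function(manip, xd, xdd, u_pert = NULL) {
  m <- diag(manip$M_adm) + diag(manip$M_handle)
  d <- diag(manip$D_adm)
  u <- -sweep(xdd, 2, m, `*`) - sweep(xd, 2, d, `*`)
  if (!is.null(u_pert)) u <- u + u_pert
  u
}
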