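#' Geometric and inertial description of a planar two-link arm
#'
#' Constructs an `arm_params` object describing a two-link arm moving in the
#' horizontal (gravity-free) plane: an upper arm of length `l1` and a forearm
#' (including the hand) of length `l2`, each with a mass, a joint-to-centre-of
#' gravity distance and a moment of inertia about the centre of gravity.
#'
#' The default values are generic adult segment parameters chosen so that the
#' derived base inertial parameters are of the order typically reported for a
#' seated human arm; they are a simulation default, not an anthropometric
#' authority.
#'
#' @param l1,l2 Link lengths \[m\].
#' @param lc1,lc2 Joint-to-centre-of-gravity distances \[m\].
#' @param m1,m2 Link masses \[kg\].
#' @param I1_cg,I2_cg Link moments of inertia about the centre of gravity
#'   \[kg m^2\].
#' @return An object of class `arm_params`.
#' @examples
#' arm <- arm_params()
#' bip_from_standard(arm)
#' @export
arm_params <- function(l1 = 0.30, l2 = 0.33,
                       lc1 = 0.11, lc2 = 0.16,
                       m1 = 1.93, m2 = 1.52,
                       I1_cg = 0.0141, I2_cg = 0.0188) {
  vals <- c(l1 = l1, l2 = l2, lc1 = lc1, lc2 = lc2, m1 = m1, m2 = m2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("arm_params: lengths and masses must be finite and strictly positive")
  }
  if (I1_cg < 0 || I2_cg < 0) {
    stop("arm_params: moments of inertia must be non-negative")
  }
  if (lc1 > l1 || lc2 > l2) {
    stop("arm_params: centre of gravity must lie within the link")
  }
  structure(list(l1 = l1, l2 = l2, lc1 = lc1, lc2 = lc2,
                 m1 = m1, m2 = m2, I1_cg = I1_cg, I2_cg = I2_cg),
            class = "arm_params")
}

#' @export
print.arm_params <- function(x, ...) {
  cat("Planar two-link arm\n")
  cat(sprintf("  upper arm: l1 = %.3f m, lc1 = %.3f m, m1 = %.3f kg, I1_cg = %.4f kg m^2\n",
              x$l1, x$lc1, x$m1, x$I1_cg))
  cat(sprintf("  forearm:   l2 = %.3f m, lc2 = %.3f m, m2 = %.3f kg, I2_cg = %.4f kg m^2\n",
              x$l2, x$lc2, x$m2, x$I2_cg))
  pb <- bip_from_standard(x)
  cat(sprintf("  base inertial parameters: [%.4f, %.4f, %.4f] kg m^2\n",
              pb[1], pb[2], pb[3]))
  invisible(x)
}

#' Base inertial parameters from standard segment parameters
#'
#' Reduces the standard inertial parameters of the two-link arm to the minimal
#' identifiable set for planar, gravity-free dynamics. With
#' \eqn{I_i = I_{cg,i} + m_i l_{c,i}^2} (parallel-axis theorem) the base
#' inertial parameter (BIP) vector is
#' \deqn{\bar\pi = (I_1 + m_2 l_1^2,\; I_2,\; m_2 l_{c2} l_1).}
#' Rigid-body torques are linear in this vector (see [base_regressor()]).
#'
#' @param arm An [arm_params()] object.
#' @return Numeric vector of length 3 \[kg m^2\].
#' @export
bip_from_standard <- function(arm) {
  stopifnot(inherits(arm, "arm_params"))
  I1 <- arm$I1_cg + arm$m1 * arm$lc1^2
  I2 <- arm$I2_cg + arm$m2 * arm$lc2^2
  c(I1 + arm$m2 * arm$l1^2,
    I2,
    arm$m2 * arm$lc2 * arm$l1)
}
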