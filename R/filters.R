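#' Butterworth filter design as second-order sections
#'
#' Designs a digital Butterworth low- or high-pass filter of arbitrary order
#' via the analog prototype (poles on the unit circle) and the bilinear
#' transform with frequency prewarping, returned as a cascade of biquad
#' (second-order) sections. Cascaded biquads are numerically far better
#' conditioned than a single transfer function at high order and low relative
#' cutoff, which is exactly the regime used here (order 10, cutoff around
#' 1/1000 of the sample rate).
#'
#' @param order Filter order (>= 1).
#' @param fc Cutoff frequency \[Hz\] (-3 dB point).
#' @param fs Sample rate \[Hz\].
#' @param type `"low"` or `"high"`.
#' @return Matrix with one row per section and columns
#'   `b0, b1, b2, a1, a2` (the leading denominator coefficient is 1).
#' @export
butter_sos <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2) {
    stop(sprintf("butter_sos: cutoff %.3f Hz must lie in (0, fs/2 = %.3f Hz)", fc, fs / 2))
  }
  K <- 2 * fs
  wc <- K * tan(pi * fc / fs)        # prewarped analog cutoff [rad/s]
  # analog prototype pole angles (left half plane, unit circle)
  k <- seq_len(floor(order / 2))
  theta <- pi * (2 * k + order - 1) / (2 * order)
  sections <- lapply(theta, function(th) {
    a1 <- -2 * cos(th) * wc          # s^2 + a1 s + a0
    a0 <- wc^2
    d0 <- K^2 + a1 * K + a0
    d1 <- 2 * (a0 - K^2)
    d2 <- K^2 - a1 * K + a0
    if (!is.finite(d0) || d0 == 0) stop("butter_sos: degenerate section (fc too near Nyquist)")
    if (type == "low") {
      b <- a0 * c(1, 2, 1)
    } else {
      b <- K^2 * c(1, -2, 1)
    }
    c(b / d0, d1 / d0, d2 / d0)
  })
  if (order %% 2 == 1) {             # real pole at -wc
    d0 <- K + wc
    d1 <- wc - K
    b <- if (type == "low") wc * c(1, 1, 0) else K * c(1, -1, 0)
    sections <- c(sections, list(c(b / d0, d1 / d0, 0)))
  }
  sos <- do.call(rbind, sections)
  colnames(sos) <- c("b0", "b1", "b2", "a1", "a2")
  if (any(!is.finite(sos))) stop("butter_sos: unstable section coefficients")
  sos
}

#' Apply a second-order-section cascade (single causal pass)
#'
#' Direct-form-II-transposed filtering with zero initial state, section by
#' section.
#'
#' @param sos Section matrix from [butter_sos()].
#' @param x Numeric signal.
#' @return Filtered signal, same length.
#' @export
sosfilt <- function(sos, x) {
  sosfilt_cpp(sos, as.numeric(x))
}

#' Zero-phase (forward-backward) second-order-section filtering
#'
#' Runs the cascade forward and then backward over the signal, which squares
#' the magnitude response and cancels the phase response exactly. Edge
#' transients are suppressed by odd-symmetric reflection padding before
#' filtering; the padding is removed afterwards.
#'
#' @param sos Section matrix from [butter_sos()].
#' @param x Numeric signal.
#' @param padlen Number of padding samples per side; defaults to
#'   `min(n - 1, 6 * order)` where the order is inferred from the cascade.
#' @return Filtered signal, same length as `x`, with zero phase lag.
#' @export
filtfilt_sos <- function(sos, x, padlen = NULL) {
  n <- length(x)
  order <- 2 * nrow(sos)
  if (is.null(padlen)) padlen <- min(n - 1, 6 * order)
  if (n <= 2 * padlen + 1 && padlen > 0) padlen <- max(0, (n - 2) %/% 2)
  if (padlen > 0) {
    left <- 2 * x[1] - x[(padlen + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - padlen)]
    xe <- c(left, x, right)
  } else {
    xe <- x
  }
  y <- sosfilt(sos, xe)
  y <- rev(sosfilt(sos, rev(y)))
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  y
}

#' Savitzky-Golay smoothing/differentiation coefficients
#'
#' Least-squares polynomial fit over a centred window; the returned
#' coefficients `c` give the `deriv`-th derivative estimate at the window
#' centre as `sum_j c[j] * x[i + j - h - 1]` divided by `dt^deriv`.
#'
#' @param window Odd window length \[samples\].
#' @param poly_order Polynomial order (>= `deriv`).
#' @param deriv Derivative order (0 = smoothing).
#' @return Numeric coefficient vector of length `window` (dimensionless;
#'   divide the convolution by `dt^deriv`).
#' @export
sg_coefficients <- function(window, poly_order, deriv = 0) {
  if (window %% 2 != 1) stop("sg_coefficients: window must be odd")
  if (poly_order >= window) stop("sg_coefficients: poly_order must be < window")
  if (deriv > poly_order) stop("sg_coefficients: deriv must be <= poly_order")
  h <- (window - 1) / 2
  # scaled abscissa keeps the Vandermonde well conditioned for wide windows
  A <- outer((-h:h) / h, 0:poly_order, `^`)
  G <- solve(crossprod(A), t(A))
  G[deriv + 1, ] * factorial(deriv) / h^deriv
}

#' Savitzky-Golay filtering of a signal
#'
#' Applies the Savitzky-Golay smoothing-differentiation filter with
#' odd-symmetric reflection padding at the edges, so the output has the same
#' length as the input. Exact for polynomials up to `poly_order` in the
#' interior.
#'
#' @param x Numeric signal.
#' @param fs Sample rate \[Hz\].
#' @param window Odd window length \[samples\].
#' @param poly_order Polynomial order.
#' @param deriv Derivative order.
#' @return The `deriv`-th derivative estimate of `x`, in units of
#'   `[x]/s^deriv`.
#' @export
sg_filter <- function(x, fs, window, poly_order, deriv = 0) {
  n <- length(x)
  if (n <= window) stop("sg_filter: series shorter than the filter window")
  cc <- sg_coefficients(window, poly_order, deriv)
  h <- (window - 1) / 2
  left <- 2 * x[1] - x[(h + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - h)]
  xe <- c(left, x, right)
  # y[i] = sum_j cc[j+h+1] * x[i+j], j = -h..h
  y <- stats::filter(xe, rev(cc), method = "convolution", sides = 2)
  as.numeric(y[(h + 1):(h + n)]) * fs^deriv
}

#' Window length realizing a given Savitzky-Golay cutoff frequency
#'
#' Scans odd window lengths and returns the one whose smoothing response has
#' its -3 dB point closest to `fc`. The mapping window -> cutoff is needed
#' because the filter is specified by its cutoff in the processing pipeline
#' but parameterized by its window length.
#'
#' @param fs Sample rate \[Hz\].
#' @param fc Target cutoff \[Hz\].
#' @param poly_order Polynomial order.
#' @param max_window Largest window length to consider.
#' @return Odd integer window length.
#' @export
sg_window_for_cutoff <- function(fs, fc, poly_order = 7, max_window = 401) {
  best_w <- poly_order + 2 + (poly_order %% 2)
  best_err <- Inf
  f <- seq(0.1, fs / 2, by = 0.25)
  for (w in seq(poly_order + 2 + ((poly_order + 1) %% 2), max_window, by = 2)) {
    cc <- sg_coefficients(w, poly_order, 0)
    h <- (w - 1) / 2
    # magnitude response of the symmetric smoother
    H <- vapply(f, function(ff) abs(sum(cc * cos(2 * pi * ff * (-h:h) / fs))), 0)
    i3 <- which(H <= 1 / sqrt(2))[1]
    if (is.na(i3)) next
    err <- abs(f[i3] - fc)
    if (err < best_err) {
      best_err <- err
      best_w <- w
    }
  }
  best_w
}

#' Cumulative trapezoidal integration
#'
#' @param y Numeric signal.
#' @param dt Sample interval \[s\].
#' @return Integral of `y` with zero initial condition, same length.
#' @export
cumtrapz <- function(y, dt) {
  c(0, cumsum((y[-1] + y[-length(y)]) / 2 * dt))
}
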