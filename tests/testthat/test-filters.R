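test_that("Butterworth cascade meets its design response", {
  fs <- 2000
  gain <- function(sos, f, n = 8 * fs) {
    x <- sin(2 * pi * f * seq_len(n) / fs)
    y <- sosfilt(sos, x)
    max(abs(y[(n / 2):n])) / max(abs(x[(n / 2):n]))
  }
  lp <- butter_sos(5, 20, fs, "low")
  expect_equal(gain(lp, 2), 1, tolerance = 0.01)            # passband
  expect_equal(gain(lp, 20), 1 / sqrt(2), tolerance = 0.03) # -3 dB at fc
  expect_lt(gain(lp, 100), 10^(-60 / 20))                   # deep stopband
  hp <- butter_sos(10, 20, fs, "high")
  expect_lt(gain(hp, 5), 10^(-60 / 20))                     # fc/4, order 10
  expect_equal(gain(hp, 200), 1, tolerance = 0.01)          # passband
  expect_error(butter_sos(4, 1200, fs), "Nyquist|cutoff")
})

test_that("zero-phase filtering has zero lag, kills DC, and attenuates fc/4 by 60 dB", {
  fs <- 2000
  hp <- butter_sos(10, 2, fs, "high")      # the method's own extreme regime
  n <- 30 * fs                             # long signal: slow poles need settling
  t <- seq_len(n) / fs
  mid <- (12 * fs):(18 * fs)
  y <- filtfilt_sos(hp, rep(1, n))
  expect_lt(max(abs(y[mid])), 1e-6)        # DC rejection
  x <- sin(2 * pi * 20 * t)
  yf <- filtfilt_sos(hp, x)
  cc <- sapply(-5:5, function(l) sum(x[mid] * yf[mid + l]))
  expect_equal((-5:5)[which.max(cc)], 0)   # zero phase lag
  expect_equal(max(abs(yf[mid])), 1, tolerance = 0.01)
  xs <- sin(2 * pi * 0.5 * t)
  ys <- filtfilt_sos(hp, xs)
  expect_lt(max(abs(ys[mid])), 10^(-60 / 20))
})

test_that("Savitzky-Golay differentiation is exact for polynomials", {
  fs <- 2000
  t <- seq(0, 1, by = 1 / fs)
  x <- 2 * t^3 - t^2 + 5 * t + 1
  interior <- 200:1800
  expect_equal(sg_filter(x, fs, 51, 7, 3)[interior], rep(12, length(interior)),
               tolerance = 1e-6)
  expect_equal(sg_filter(x, fs, 51, 7, 0)[interior], x[interior], tolerance = 1e-10)
  # constant input: zero jerk up to the fs^3-amplified coefficient roundoff
  expect_lt(max(abs(sg_filter(rep(3, 2001), fs, 51, 7, 3))), 1e-4)
})

test_that("Savitzky-Golay jerk of a slow sinusoid matches the analytic derivative", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)
  x <- 0.01 * sin(2 * pi * 2 * t)
  j <- compute_jerk(x, fs)
  expect_equal(max(abs(j[500:3500])), 0.01 * (2 * pi * 2)^3, tolerance = 0.01)
  expect_error(sg_filter(x[1:20], fs, 51, 7, 3), "shorter")
})

test_that("SG window search realizes the requested cutoff", {
  w <- sg_window_for_cutoff(2000, 50, 7)
  cc <- sg_coefficients(w, 7, 0)
  h <- (w - 1) / 2
  H <- function(f) abs(sum(cc * cos(2 * pi * f * (-h:h) / 2000)))
  expect_equal(H(50), 1 / sqrt(2), tolerance = 0.05)
  expect_gt(H(10), 0.99)
})

test_that("cumtrapz integrates smooth signals accurately", {
  t <- seq(0, 1, by = 5e-4)
  expect_equal(cumtrapz(cos(2 * pi * t), 5e-4),
               sin(2 * pi * t) / (2 * pi), tolerance = 1e-6)
})
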