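#' Normalized root-mean-square error of a two-channel series
#'
#' \deqn{\mathrm{NRMSE}(t) = \sqrt{\tfrac{1}{n}\sum_{i=1}^{n}
#'   \left(\frac{\chi_i(t) - \hat\chi_i(t)}{\nu_i}\right)^2}}
#' with `n = 2` the channel dimensionality. The default normalizer is the
#' per-channel maximum absolute true value over the window. Returned either
#' time-resolved (one value per sample) or averaged over the window.
#'
#' @param true,est n x 2 matrices (true and estimated series).
#' @param normalizer Per-channel normalizing values (length 2); default
#'   `max(abs(true))` per channel.
#' @param time_resolved If `TRUE`, return the per-sample series; otherwise
#'   its window average.
#' @return Scalar or length-n vector (dimensionless; multiply by 100 for %).
#' @export
nrmse <- function(true, est, normalizer = NULL, time_resolved = FALSE) {
  true <- as_config_matrix(true)
  est <- as_config_matrix(est)
  if (!all(dim(true) == dim(est))) stop("nrmse: series must have equal dimensions")
  if (is.null(normalizer)) normalizer <- apply(abs(true), 2, max)
  if (any(normalizer == 0)) stop("nrmse: degenerate (zero) normalizer")
  z <- sweep(true - est, 2, normalizer, `/`)
  v <- sqrt(rowMeans(z^2))
  if (time_resolved) v else mean(v)
}

#' Normalized absolute error of a scalar estimate
#'
#' `|true - est| / nu`; the normalizer defaults to `|true|` (appropriate for
#' base inertial parameters). For damping/stiffness elements pass the
#' window-averaged maximum true element of the matrix as `normalizer`.
#'
#' @param true,est Scalars (vectorized elementwise).
#' @param normalizer Normalizing value(s); default `abs(true)`.
#' @return Non-negative error(s) (dimensionless; multiply by 100 for %).
#' @export
nae <- function(true, est, normalizer = NULL) {
  if (is.null(normalizer)) normalizer <- abs(true)
  if (any(normalizer == 0)) stop("nae: zero normalizer")
  abs(true - est) / normalizer
}

#' Residual sum of squares with information criteria
#'
#' `RSS = (1/n) sum_i sum_j (y_ij - yhat_ij)^2` with `n = 2` the channel
#' dimensionality, `AIC = 2p + k ln(RSS)`, `BIC = ln(k) p + k ln(RSS)`,
#' where `p` is the parameter count and `k` the number of data points per
#' channel.
#'
#' @param true,est k x 2 matrices.
#' @param p Number of model parameters.
#' @return List with `rss`, `aic`, `bic`, `k`. A perfect fit (`RSS = 0`)
#'   returns `-Inf` information criteria with a `perfect_fit` flag.
#' @export
rss_aic_bic <- function(true, est, p) {
  true <- as_config_matrix(true)
  est <- as_config_matrix(est)
  k <- nrow(true)
  if (k < 1) stop("rss_aic_bic: need at least one sample")
  n <- ncol(true)
  rss <- sum((true - est)^2) / n
  if (rss == 0) {
    return(list(rss = 0, aic = -Inf, bic = -Inf, k = k, perfect_fit = TRUE))
  }
  list(rss = rss,
       aic = 2 * p + k * log(rss),
       bic = log(k) * p + k * log(rss),
       k = k, perfect_fit = FALSE)
}

#' Aggregate per-collection values into summary means and SDs
#'
#' `within`: mean and sample SD per collection. `between`: mean and SD
#' across the collection means. `cross`: the mean of the within-collection
#' means paired with the mean of the within-collection SDs (the convention
#' used for cross-simulation / cross-subject summaries).
#'
#' @param values List of numeric vectors (one per collection), or a single
#'   numeric vector (treated as one collection).
#' @param level `"within"`, `"between"`, or `"cross"`.
#' @return For `within`, a data frame with one row per collection; otherwise
#'   a list with `mean` and `sd`.
#' @export
aggregate_stats <- function(values, level = c("cross", "within", "between")) {
  level <- match.arg(level)
  if (is.numeric(values)) values <- list(values)
  if (length(values) == 0 || any(!vapply(values, length, 0L))) {
    stop("aggregate_stats: empty collection")
  }
  mns <- vapply(values, mean, 0)
  sds <- vapply(values, function(v) if (length(v) > 1) stats::sd(v) else 0, 0)
  switch(level,
         within = data.frame(collection = seq_along(values), mean = mns, sd = sds),
         between = list(mean = mean(mns), sd = if (length(mns) > 1) stats::sd(mns) else 0),
         cross = list(mean = mean(mns), sd = mean(sds)))
}
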