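# Global negative binomial overdispersion estimation. The moment identity
# phi = E(Y)^2 / (Var(Y) - E(Y)) holds within one segment; computed over a
# short sliding window most windows sit inside a segment, and the median over
# windows is robust to the minority that straddle a change-point.

#' Moment estimator of the NB dispersion on a single window
#'
#' Returns \eqn{\bar y^2 / (s^2 - \bar y)} with the unbiased variance
#' \eqn{s^2}. The value is negative when the window is under-dispersed
#' (variance below the mean) and non-finite when variance equals mean; both
#' are meaningful signals handled by [estimate_phi()].
#'
#' @param window numeric vector of counts, length >= 2.
#' @return a single numeric (possibly negative or non-finite).
#' @examples
#' window_moment_estimate(c(0, 1, 2, 3, 4))  # 8
#' @export
window_moment_estimate <- function(window) {
  if (length(window) < 2L) stop("window must contain at least 2 points")
  m <- mean(window)
  v <- stats::var(window)
  m^2 / (v - m)
}

# all width-h sliding-window moment estimates, stride 1, via cumulative sums
.sliding_moment_estimates <- function(y, h) {
  n <- length(y)
  s1 <- cumsum(y)
  s2 <- cumsum(y * y)
  i <- seq_len(n - h + 1L)
  S1 <- s1[i + h - 1L] - c(0, s1)[i]
  S2 <- s2[i + h - 1L] - c(0, s2)[i]
  m <- S1 / h
  v <- (S2 - S1^2 / h) / (h - 1)
  m^2 / (v - m)
}

#' Estimate the NB overdispersion by a sliding-window median with adaptive
#' window doubling
#'
#' Computes the moment estimator on every width-`h` sliding window (stride
#' 1), keeps the median of the finite estimates, and — whenever that median
#' is non-positive or undefined — doubles `h` and repeats. Windows wider than
#' half the series trigger a fallback to the whole-series moment estimate.
#'
#' @param y non-negative integer counts, `length(y) >= h0`.
#' @param h0 initial window width (default 15).
#' @return an object of class `dispersion_estimate`: `phi_hat` (positive),
#'   `window_used`, `n_windows` and `trace` (data.frame of the (h, median)
#'   pairs tried).
#' @examples
#' y <- simulate_profile(2000, K = 6, phi = 2.3, seed = 1)$y
#' estimate_phi(y)$phi_hat
#' @export
estimate_phi <- function(y, h0 = 15L) {
  y <- as.numeric(y)
  n <- length(y)
  h0 <- as.integer(h0)
  if (h0 < 2L) stop("'h0' must be at least 2")
  if (n < h0) stop("series shorter than the initial window width")
  h <- h0
  trace <- list()
  while (h <= n / 2) {
    est <- .sliding_moment_estimates(y, h)
    fin <- est[is.finite(est)]
    med <- if (length(fin)) stats::median(fin) else NA_real_
    trace[[length(trace) + 1L]] <- c(h = h, median = med)
    if (is.finite(med) && med > 0) {
      return(structure(list(phi_hat = med, window_used = h,
                            n_windows = length(fin),
                            trace = do.call(rbind, trace)),
                       class = "dispersion_estimate"))
    }
    h <- 2L * h
  }
  # whole-series moment fallback
  glob <- window_moment_estimate(y)
  trace[[length(trace) + 1L]] <- c(h = n, median = glob)
  if (is.finite(glob) && glob > 0) {
    return(structure(list(phi_hat = glob, window_used = n,
                          n_windows = 1L, trace = do.call(rbind, trace)),
                     class = "dispersion_estimate"))
  }
  stop("dispersion could not be estimated (no window scale yields a ",
       "positive median moment estimate); supply 'phi' explicitly")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("<dispersion_estimate> phi_hat = %.4g (window %d, %d windows)\n",
              x$phi_hat, x$window_used, x$n_windows))
  invisible(x)
}
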