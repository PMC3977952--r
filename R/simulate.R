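# Seeded generator of piecewise-constant negative binomial profiles with
# known truth, mirroring the performance-study design used throughout the
# package's tests: two alternating success probabilities (0.2 on odd
# segments for high signal, 0.8 on even segments for low signal) and a
# dispersion phi shared by all segments. Typical dispersions for RNA-seq
# coverage are phi = 0.3 (highly dispersed) and phi = 2.3 (moderately
# dispersed).

# run `code` under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Draw K-1 breakpoints uniformly among minimum-length compositions
#'
#' Segment lengths are a uniform draw over the compositions of n into K
#' parts each at least `min_len` (stars-and-bars over the slack).
#'
#' @param n series length.
#' @param K number of segments (`K * min_len <= n`).
#' @param min_len minimal segment length (default 5).
#' @param seed optional integer seed (scoped: the caller's RNG state is
#'   untouched).
#' @return strictly increasing integer vector of K-1 segment ends.
#' @export
simulate_breakpoints <- function(n, K, min_len = 5L, seed = NULL) {
  if (K < 1L) stop("'K' must be at least 1")
  if (K * min_len > n) stop("infeasible: K * min_len exceeds n")
  if (K == 1L) return(integer(0))
  .with_seed(seed, {
    slack <- n - K * min_len
    # uniform composition of `slack` into K non-negative parts
    bars <- sort(sample.int(slack + K - 1L, K - 1L))
    extra <- diff(c(0L, bars, slack + K)) - 1L
    lens <- min_len + extra
    cumsum(lens)[seq_len(K - 1L)]
  })
}

#' Simulate a piecewise-constant negative binomial profile
#'
#' Each position in segment r draws from NB\eqn{(\phi, \theta_r)} with pmf
#' \eqn{P(y) = {y+\phi-1 \choose y}\theta^\phi(1-\theta)^y} (gamma-function
#' binomial coefficient, so non-integer \eqn{\phi} is supported), giving
#' segment mean \eqn{\phi(1-\theta)/\theta} and variance
#' \eqn{\phi(1-\theta)/\theta^2}. Success probabilities alternate:
#' `theta_high_signal` on odd segments, `theta_low_signal` on even segments.
#'
#' @param n series length.
#' @param K number of segments.
#' @param phi positive dispersion, shared by all segments.
#' @param theta_high_signal success probability of odd segments (default 0.2
#'   — small theta, high mean).
#' @param theta_low_signal success probability of even segments (default 0.8).
#' @param min_len minimal segment length (default 5).
#' @param seed optional integer seed.
#' @return an object of class `sim_profile`: `y` (integer counts),
#'   `true_breaks`, `true_theta` (per segment), `phi`, `n`, `K`, `seed`.
#' @examples
#' sim <- simulate_profile(1000, K = 10, phi = 2.3, seed = 42)
#' table(labels_from_breakpoints(sim$true_breaks, sim$n))
#' @export
simulate_profile <- function(n, K, phi, theta_high_signal = 0.2,
                             theta_low_signal = 0.8, min_len = 5L,
                             seed = NULL) {
  if (phi <= 0) stop("'phi' must be positive")
  th <- c(theta_high_signal, theta_low_signal)
  if (any(th <= 0 | th >= 1)) stop("'theta' values must lie in (0, 1)")
  .with_seed(seed, {
    breaks <- simulate_breakpoints(n, K, min_len = min_len, seed = NULL)
    lens <- diff(c(0L, breaks, n))
    theta_r <- ifelse(seq_len(K) %% 2L == 1L, theta_high_signal,
                      theta_low_signal)
    y <- stats::rnbinom(n, size = phi, prob = rep(theta_r, lens))
    structure(list(y = as.integer(y), true_breaks = breaks,
                   true_theta = theta_r, phi = phi, n = as.integer(n),
                   K = as.integer(K), seed = seed),
              class = "sim_profile")
  })
}

#' @export
print.sim_profile <- function(x, ...) {
  cat(sprintf("<sim_profile> n = %d, K = %d, phi = %g, theta in {%s}\n",
              x$n, x$K, x$phi,
              paste(unique(x$true_theta), collapse = ", ")))
  invisible(x)
}
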