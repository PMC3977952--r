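# Choice of the number of segments. The workhorse is a non-asymptotic
# "oracle" penalty beta * K * (1 + 4 sqrt(1.1 + log(n/K)))^2 whose constant
# beta is calibrated from the data by the slope heuristic: at large K the
# optimal cost decreases almost linearly in the penalty shape, and twice the
# magnitude of that slope is the classical minimal-penalty calibration.

#' Oracle penalty shape
#'
#' The dimension-dependent factor \eqn{K (1 + 4\sqrt{1.1 + \log(n/K)})^2}
#' of the oracle penalty (natural log). Strictly increasing in K for K <= n.
#'
#' @param K number of segments (vectorized), 1 <= K <= n.
#' @param n series length.
#' @return numeric penalty shape value(s).
#' @examples
#' oracle_penalty_shape(10, 1000)
#' @export
oracle_penalty_shape <- function(K, n) {
  if (any(K < 1 | K > n)) stop("'K' must be between 1 and n")
  K * (1 + 4 * sqrt(1.1 + log(n / K)))^2
}

#' Calibrate the oracle-penalty constant by the slope heuristic
#'
#' Least-squares fit of `costs` against `shapes` restricted to the top
#' `fit_fraction` of the K range (the large-K regime where the optimal cost
#' decreases roughly linearly in the shape); returns twice the magnitude of
#' the fitted slope. A non-negative fitted slope falls back to a robust
#' median-of-pairwise-slopes (Theil-Sen) fit; if that is also non-negative
#' the data carry no usable slope and an error is raised.
#'
#' @param costs optimal costs \eqn{C_{K,n}} for K = 1..Kmax (Kmax >= 10).
#' @param shapes matching [oracle_penalty_shape()] values.
#' @param fit_fraction fraction of the K range (from the top) used for the
#'   fit; default 0.5.
#' @return positive scalar beta.
#' @export
slope_heuristic_beta <- function(costs, shapes, fit_fraction = 0.5) {
  m <- length(costs)
  if (length(shapes) != m) stop("'costs' and 'shapes' lengths differ")
  if (m < 10L) stop("slope-heuristic calibration needs Kmax >= 10")
  idx <- seq.int(max(1L, floor(m * (1 - fit_fraction)) + 1L), m)
  x <- shapes[idx]; z <- costs[idx]
  sl <- stats::coef(stats::lm(z ~ x))[[2L]]
  if (!is.finite(sl) || sl >= 0) {
    warning("least-squares slope non-negative; using Theil-Sen fallback")
    pr <- utils::combn(length(idx), 2L)
    sl <- stats::median((z[pr[2L, ]] - z[pr[1L, ]]) /
                          (x[pr[2L, ]] - x[pr[1L, ]]), na.rm = TRUE)
    if (!is.finite(sl) || sl >= 0)
      stop("slope heuristic failed: cost does not decrease with the ",
           "penalty shape at large K")
  }
  2 * abs(sl)
}

#' Select the number of segments
#'
#' Builds the per-K criterion table for a fitted segmentation and returns the
#' minimizing K. Criteria: `"oracle"` — cost + beta * shape with beta
#' calibrated by [slope_heuristic_beta()] (or supplied); `"aic"` — cost +
#' D_K; `"bic"` — cost + (D_K / 2) log n; with model dimension D_K = 2K - 1
#' (K segment parameters plus K - 1 breakpoints).
#'
#' @param fit a [pdp_segment()] result.
#' @param criterion `"oracle"`, `"aic"` or `"bic"`.
#' @param beta optional fixed penalty constant for `"oracle"` (skips the
#'   slope-heuristic calibration).
#' @param fit_fraction passed to [slope_heuristic_beta()].
#' @return an object of class `criterion_table`: data.frame with columns
#'   `K`, `cost`, `shape`, `criterion`, and attributes `K_hat`, `beta`,
#'   `criterion_name`.
#' @examples
#' sim <- simulate_profile(1000, K = 5, phi = 2.3, seed = 7)
#' fit <- pdp_segment(sim$y, phi = 2.3, Kmax = 31)
#' attr(select_K(fit), "K_hat")
#' @export
select_K <- function(fit, criterion = c("oracle", "aic", "bic"),
                     beta = NULL, fit_fraction = 0.5) {
  stopifnot(inherits(fit, "pdp_fit"))
  criterion <- match.arg(criterion)
  K <- seq_len(fit$Kmax)
  costs <- as.numeric(fit$costs)
  n <- fit$n
  shape <- oracle_penalty_shape(K, n)
  DK <- 2 * K - 1
  crit <- switch(criterion,
    oracle = {
      if (is.null(beta)) beta <- slope_heuristic_beta(costs, shape, fit_fraction)
      costs + beta * shape
    },
    aic = costs + DK,
    bic = costs + DK / 2 * log(n))
  tab <- data.frame(K = K, cost = costs, shape = shape, criterion = crit)
  structure(tab,
            K_hat = K[which.min(crit)],
            beta = if (criterion == "oracle") beta else NA_real_,
            criterion_name = criterion,
            class = c("criterion_table", "data.frame"))
}

#' @export
print.criterion_table <- function(x, ...) {
  cat(sprintf("<criterion_table> %s criterion, K_hat = %d",
              attr(x, "criterion_name"), attr(x, "K_hat")))
  if (is.finite(attr(x, "beta")))
    cat(sprintf(" (beta = %.4g)", attr(x, "beta")))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 12), row.names = FALSE)
  if (nrow(x) > 12) cat("  ...", nrow(x) - 12, "more rows\n")
  invisible(x)
}
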