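# Main segmentation interface: the pruned DP sweep over k = 1..Kmax, the
# traceback, constrained-breakpoint queries, and the unpruned quadratic DP
# used as an exactness oracle at small n.

#' Exact segmentation of a count series by pruned dynamic programming
#'
#' Computes, for every number of segments k up to `Kmax`, the optimal
#' partition of `y` minimizing the total segment cost under the chosen loss
#' family, by a functional-pruning dynamic programming sweep. The result is
#' exact: costs agree with exhaustive minimization over all partitions.
#'
#' For count losses the series is first plateau-compressed by default
#' (see [compress_series()]); this cannot change the optimal cost and
#' usually shortens the sweep considerably. Reported breakpoints are 1-based
#' inclusive segment ends in the original coordinates.
#'
#' @param y non-negative integer counts (any numeric for `"gaussian"`), or a
#'   `count_series` object from [read_counts()].
#' @param model loss family: `"nbinom"`, `"poisson"` or `"gaussian"`.
#' @param phi negative binomial dispersion. `NULL` (default) estimates it
#'   with [estimate_phi()] for the nbinom family; ignored otherwise.
#' @param Kmax maximal number of segments; default
#'   `floor(sqrt(n_effective))` where `n_effective` is the (compressed)
#'   series length.
#' @param weights optional positive integer weights (a pre-compressed
#'   series); disables internal compression.
#' @param compress logical; default `TRUE` for count families, `FALSE` for
#'   Gaussian.
#' @param tol absolute tolerance in theta for the interval bookkeeping of the
#'   pruning; does not affect reported costs.
#' @return an object of class `pdp_fit` with components `n`, `model`, `phi`,
#'   `phi_source`, `Kmax`, `costs` (vector of optimal costs \eqn{C_{k,n}}),
#'   `cost_matrix` and `backpointer` (in compressed coordinates),
#'   `breakpoints` (list over k of original-coordinate segment ends),
#'   `theta` (list over k of per-segment parameter estimates), `map` (the
#'   plateau map or `NULL`) and `diagnostics`.
#' @examples
#' fit <- pdp_segment(c(0, 0, 0, 5, 5, 5), model = "poisson", Kmax = 3)
#' fit$breakpoints[[2]]   # breakpoint after position 3
#' @export
pdp_segment <- function(y, model = c("nbinom", "poisson", "gaussian"),
                        phi = NULL, Kmax = NULL, weights = NULL,
                        compress = NULL, tol = 1e-9) {
  model <- match.arg(model)
  if (inherits(y, "count_series")) {
    if (is.null(weights)) weights <- y$weights
    y <- y$values
  }
  y <- as.numeric(y)
  n_orig <- if (is.null(weights)) length(y) else sum(weights)
  if (length(y) < 1L) stop("empty series")
  if (model != "gaussian" && any(y < 0 | y != round(y) | !is.finite(y)))
    stop("count losses require non-negative integer counts")

  phi_source <- "none"
  if (model == "nbinom") {
    if (is.null(phi)) {
      est <- estimate_phi(if (is.null(weights)) y else rep(y, weights))
      phi <- est$phi_hat
      phi_source <- "estimated"
    } else {
      phi_source <- "supplied"
    }
    if (!is.numeric(phi) || phi <= 0) stop("'phi' must be positive")
  } else {
    phi <- 1
  }

  map <- NULL
  if (is.null(weights)) {
    if (is.null(compress)) compress <- model != "gaussian"
    if (compress) {
      map <- compress_series(y)
      yv <- map$values
      wv <- as.numeric(map$weights)
    } else {
      yv <- y
      wv <- rep(1, length(y))
    }
  } else {
    if (length(weights) != length(y) || any(weights < 1 | weights != round(weights)))
      stop("'weights' must be positive integers matching 'y'")
    yv <- y
    wv <- as.numeric(weights)
    map <- structure(list(values = yv, weights = as.integer(wv),
                          offsets = c(1L, 1L + cumsum(wv)[-length(wv)])),
                     class = "plateau_map")
  }
  n_eff <- length(yv)
  if (is.null(Kmax)) Kmax <- max(1L, min(n_eff, floor(sqrt(n_eff))))
  Kmax <- as.integer(Kmax)
  if (Kmax < 1L || Kmax > n_eff)
    stop("'Kmax' must be between 1 and the number of (compressed) points (",
         n_eff, ")")

  res <- .pdp_pass_cpp(yv, wv, model, phi, Kmax, tol)
  C <- res$cost
  BP <- res$backpointer

  breakpoints <- vector("list", Kmax)
  theta <- vector("list", Kmax)
  for (k in seq_len(Kmax)) {
    bk <- .backtrack_at(BP, k, n_eff)
    breakpoints[[k]] <- if (is.null(map)) bk else
      map_breakpoints_to_original(bk, map)
    theta[[k]] <- .segment_theta(yv, wv, bk, model, phi)
  }

  structure(list(
    n = n_orig, n_effective = n_eff,
    model = model, phi = phi, phi_source = phi_source,
    Kmax = Kmax,
    costs = C[, n_eff],
    cost_matrix = C, backpointer = BP,
    breakpoints = breakpoints, theta = theta,
    map = map, compressed = !is.null(map),
    diagnostics = res$diagnostics,
    tol = tol
  ), class = "pdp_fit")
}

# traceback of the (k, t) cell of a backpointer matrix; returns the k-1
# segment ends (in sweep coordinates), strictly increasing
.backtrack_at <- function(BP, k, t) {
  if (k < 1L || k > nrow(BP)) stop("'k' must be between 1 and Kmax")
  if (k == 1L) return(integer(0))
  out <- integer(k - 1L)
  cur <- t
  for (kk in seq(k, 2L)) {
    cur <- BP[kk, cur]
    out[kk - 1L] <- cur
  }
  out
}

# per-segment closed-form parameter estimates from weighted data
.segment_theta <- function(yv, wv, breaks_eff, model, phi) {
  bounds <- c(0L, breaks_eff, length(yv))
  vapply(seq_len(length(bounds) - 1L), function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    sw <- sum(wv[idx]); sy <- sum(wv[idx] * yv[idx])
    switch(model,
      nbinom = {
        d1 <- phi * sw
        th <- if (d1 + sy > 0) d1 / (d1 + sy) else 0.5
        min(max(th, 1e-12), 1 - 1e-12)
      },
      poisson = max(sy / sw, 1e-12),
      gaussian = sy / sw)
  }, numeric(1))
}

#' Extract the breakpoints of the optimal segmentation in K segments
#'
#' @param fit a `pdp_fit`.
#' @param K number of segments (1..Kmax).
#' @return integer vector of K-1 segment ends (1-based inclusive, original
#'   coordinates).
#' @export
get_breakpoints <- function(fit, K) {
  stopifnot(inherits(fit, "pdp_fit"))
  if (K < 1L || K > fit$Kmax) stop("'K' must be between 1 and Kmax")
  fit$breakpoints[[K]]
}

#' Per-segment summary table for a fitted segmentation
#'
#' @param fit a `pdp_fit`.
#' @param K number of segments.
#' @return data.frame with columns `segment`, `start`, `end` (1-based
#'   inclusive), `n_r`, `mean` (fitted mean, \eqn{\phi(1-\theta)/\theta} for
#'   the negative binomial) and `theta_hat`.
#' @export
segment_table <- function(fit, K) {
  stopifnot(inherits(fit, "pdp_fit"))
  br <- get_breakpoints(fit, K)
  th <- fit$theta[[K]]
  starts <- c(1L, br + 1L)
  ends <- c(br, fit$n)
  mean_r <- switch(fit$model,
    nbinom = fit$phi * (1 - th) / th,
    poisson = th,
    gaussian = th)
  data.frame(segment = seq_len(K), start = starts, end = ends,
             n_r = ends - starts + 1L, mean = mean_r, theta_hat = th)
}

#' @export
print.pdp_fit <- function(x, ...) {
  cat(sprintf("<pdp_fit> %s loss, n = %d", x$model, x$n))
  if (x$compressed)
    cat(sprintf(" (compressed to %d, factor %.2f)",
                x$n_effective, x$n / x$n_effective))
  cat(sprintf(", Kmax = %d\n", x$Kmax))
  if (x$model == "nbinom")
    cat(sprintf("  phi = %.4g (%s)\n", x$phi, x$phi_source))
  cat(sprintf("  optimal costs C[1..%d]: %s ...\n", x$Kmax,
              paste(signif(utils::head(x$costs, 5), 6), collapse = ", ")))
  invisible(x)
}

#' Plot a fitted segmentation
#'
#' Square-root counts with the fitted segment means and breakpoints overlaid.
#'
#' @param x a `pdp_fit`.
#' @param K number of segments to display.
#' @param y ignored (original series is stored in the fit's plateau map when
#'   compression was used; otherwise pass the series here).
#' @param ... passed to [plot()].
#' @export
plot.pdp_fit <- function(x, K, y = NULL, ...) {
  if (is.null(y)) {
    if (is.null(x$map)) stop("original series unavailable; pass 'y'")
    y <- decompress_series(x$map)
  }
  graphics::plot(sqrt(y), col = "darkred", pch = 16, cex = 0.4,
                 xlab = "position", ylab = "sqrt(count)", ...)
  tab <- segment_table(x, K)
  graphics::segments(tab$start, sqrt(tab$mean), tab$end, sqrt(tab$mean),
                     col = "blue", lwd = 2)
  graphics::abline(v = get_breakpoints(x, K) + 0.5, col = "blue", lty = 3)
  invisible(x)
}

#' Unpruned dynamic programming (quadratic-time exactness oracle)
#'
#' Direct implementation of the segment-neighbourhood recursion without any
#' pruning, in O(Kmax n^2). Intended for testing and small series only; uses
#' the reference R loss implementations, independently of the C++ sweep.
#'
#' @inheritParams pdp_segment
#' @param phi dispersion (required for `"nbinom"`; no estimation here).
#' @return list with `cost` (Kmax x n matrix of optimal costs, `NA` where
#'   t < k) and `backpointer`.
#' @export
naive_dp <- function(y, model = c("nbinom", "poisson", "gaussian"),
                     phi = 1, Kmax, weights = NULL) {
  model <- match.arg(model)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  if (Kmax < 1 || Kmax > n) stop("'Kmax' must be between 1 and n")
  W <- c(0, cumsum(weights))
  WY <- c(0, cumsum(weights * y))
  WY2 <- c(0, cumsum(weights * y * y))
  eps <- 1e-12
  # cost of segments (i..t) for all i in `from`, fixed t (1-based)
  segcost <- function(from, t) {
    d1w <- W[t + 1L] - W[from]
    d2 <- WY[t + 1L] - WY[from]
    switch(model,
      nbinom = {
        d1 <- phi * d1w
        th <- ifelse(d1 + d2 > 0, d1 / (d1 + d2), 0.5)
        th <- pmin(pmax(th, eps), 1 - eps)
        -d1 * log(th) - d2 * log1p(-th)
      },
      poisson = {
        th <- pmax(d2 / d1w, eps)
        d1w * th - d2 * log(th)
      },
      gaussian = (WY2[t + 1L] - WY2[from]) - d2^2 / d1w)
  }
  C <- matrix(NA_real_, Kmax, n)
  BP <- matrix(NA_integer_, Kmax, n)
  for (t in seq_len(n)) C[1L, t] <- segcost(1L, t)
  BP[1L, ] <- 0L
  if (Kmax >= 2L) {
    for (k in 2:Kmax) {
      for (t in k:n) {
        taus <- (k - 1L):(t - 1L)
        tot <- C[k - 1L, taus] + segcost(taus + 1L, t)
        i <- which.min(tot)          # which.min takes the first: smallest tau
        C[k, t] <- tot[i]
        BP[k, t] <- taus[i]
      }
    }
  }
  list(cost = C, backpointer = BP)
}

#' Optimal segmentation constrained to a fixed change-point
#'
#' Cost and breakpoints of the best segmentation of `y` into `K` segments
#' whose j-th change-point is at position `t`, obtained by combining a
#' forward sweep (first j segments over points 1..t) with a sweep on the
#' reversed series (remaining K-j segments over points t+1..n). Minimizing
#' the returned cost over `t` recovers the unconstrained optimum.
#'
#' @inheritParams pdp_segment
#' @param K total number of segments.
#' @param j which change-point is constrained (1..K-1).
#' @param t position of the j-th change-point (j <= t <= n-(K-j)); may be a
#'   vector, in which case costs for all requested positions are returned.
#' @return list with `t`, `cost` (vector parallel to `t`), and for scalar
#'   `t` the combined `breakpoints` of one optimal constrained segmentation.
#' @export
best_segmentation_with_breakpoint <- function(y, K, j, t,
                                              model = c("nbinom", "poisson", "gaussian"),
                                              phi = NULL, tol = 1e-9) {
  model <- match.arg(model)
  y <- as.numeric(y)
  n <- length(y)
  if (K < 2 || K > n) stop("'K' must be between 2 and n")
  if (j < 1 || j > K - 1) stop("'j' must be between 1 and K-1")
  if (any(t < j | t > n - (K - j)))
    stop("infeasible 't' for the requested (K, j)")
  if (model == "nbinom" && is.null(phi))
    phi <- estimate_phi(y)$phi_hat
  # uncompressed sweeps so that forward/backward coordinates line up with t
  fwd <- pdp_segment(y, model = model, phi = phi, Kmax = j, compress = FALSE,
                     tol = tol)
  bwd <- pdp_segment(rev(y), model = model, phi = phi, Kmax = K - j,
                     compress = FALSE, tol = tol)
  cost <- fwd$cost_matrix[j, t] + bwd$cost_matrix[K - j, n - t]
  out <- list(t = t, cost = unname(cost))
  if (length(t) == 1L) {
    left <- .backtrack_at(fwd$backpointer, j, t)
    right <- n - rev(.backtrack_at(bwd$backpointer, K - j, n - t))
    out$breakpoints <- c(left, t, right)
  }
  out
}
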