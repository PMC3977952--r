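# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code under fixed seeds; the oracles deliberately avoid the
# package's own accumulator/sweep code paths.

# largest relative deviation, guarding against division by tiny costs
rel_diff <- function(a, b) max(abs(a - b) / pmax(1, abs(b)))

# dense-grid minimization oracle for a scalar function
grid_min <- function(f, lo, hi, m = 200001L) {
  x <- seq(lo, hi, length.out = m)
  v <- f(x)
  i <- which.min(v)
  list(theta = x[i], value = v[i])
}

# independent closed-form segment cost (direct formulas, no accumulators)
oracle_segment_cost <- function(y, w, model, phi) {
  eps <- 1e-12
  sw <- sum(w); sy <- sum(w * y)
  if (model == "nbinom") {
    d1 <- phi * sw
    th <- min(max(if (d1 + sy > 0) d1 / (d1 + sy) else 0.5, eps), 1 - eps)
    -d1 * log(th) - sy * log1p(-th)
  } else if (model == "poisson") {
    th <- max(sy / sw, eps)
    sw * th - sy * log(th)
  } else {
    sum(w * y^2) - sy^2 / sw
  }
}

# total cost of a segmentation given by 1-based inclusive segment ends
oracle_partition_cost <- function(y, breaks, model, phi, w = rep(1, length(y))) {
  bounds <- c(0L, breaks, length(y))
  sum(vapply(seq_len(length(bounds) - 1L), function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    oracle_segment_cost(y[idx], w[idx], model, phi)
  }, numeric(1)))
}

# exhaustive minimum over every partition of y into k segments
oracle_best_partition <- function(y, k, model, phi) {
  n <- length(y)
  if (k == 1L) return(list(cost = oracle_partition_cost(y, integer(0), model, phi),
                           breaks = integer(0)))
  combos <- utils::combn(n - 1L, k - 1L)
  costs <- apply(combos, 2L, function(b)
    oracle_partition_cost(y, b, model, phi))
  i <- which.min(costs)
  list(cost = costs[i], breaks = combos[, i])
}

# a piecewise-constant NB test series with plateaux (low counts -> runs)
plateau_series <- function(n, seed, phi = 0.3) {
  simulate_profile(n, K = max(2L, n %/% 60L), phi = phi, seed = seed)$y
}

# quadratic-time Rand index straight from the displayed pair sum
oracle_rand_index <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      s <- s + (a[i] == a[j]) * (b[i] == b[j]) +
        (a[i] != a[j]) * (b[i] != b[j])
    }
  }
  2 * s / ((n - 1) * (n - 2))
}

# brute-force Hellinger distance by pmf summation (gamma-function pmf).
# sqrt(P1 P2) decays geometrically at rate x = sqrt((1-t1)(1-t2)), slower
# than either pmf, so the truncation bound must use that ratio.
oracle_hellinger_nb <- function(t1, t2, phi, tail = 1e-13) {
  x <- sqrt((1 - t1) * (1 - t2))
  ymax <- 200L
  repeat {
    y <- 0:ymax
    terms <- sqrt(dnbinom(y, size = phi, prob = t1) *
                    dnbinom(y, size = phi, prob = t2))
    # term ratio is x (y + phi) / (y + 1), decreasing toward x: bound the
    # tail by the geometric series at the current ratio
    r <- x * (ymax + phi) / (ymax + 1)
    if ((r < 1 && terms[length(terms)] * r / (1 - r) < tail) || ymax > 2e6)
      break
    ymax <- ymax * 4L
  }
  sqrt(max(0, 1 - sum(terms)))
}
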