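# Convex one-parameter loss families: negative binomial (success probability
# theta, fixed dispersion phi), Poisson (mean theta) and Gaussian (mean theta).
# Losses are defined up to the additive term that does not depend on theta, so
# costs are comparable within one model but not across phi values.

.EPS_PARAM <- 1e-12   # clip for open parameter-space boundaries
.TOL_THETA <- 1e-9    # absolute bisection tolerance in theta
.MAX_BISECT <- 200L

#' Loss model description
#'
#' Describes one of the three convex one-parameter loss families used for
#' segmentation: negative binomial (parameter \eqn{\theta \in (0,1)} is the
#' success probability, dispersion \eqn{\phi > 0} fixed and shared by all
#' segments), Poisson (\eqn{\theta \in (0,\infty)} is the mean) and Gaussian
#' (\eqn{\theta \in R} is the mean, unit variance).
#'
#' Under the negative binomial parametrization used throughout the package,
#' a count has mean \eqn{\phi(1-\theta)/\theta} and variance
#' \eqn{\phi(1-\theta)/\theta^2}: small \eqn{\theta} means high signal.
#'
#' @param family one of `"nbinom"`, `"poisson"`, `"gaussian"`.
#' @param phi positive dispersion, used only by the negative binomial family.
#' @return an object of class `loss_model` with fields `family`, `phi`,
#'   `lower`, `upper` (the clipped numeric bounds of the open parameter space).
#' @examples
#' loss_model("nbinom", phi = 2.3)
#' @export
loss_model <- function(family = c("nbinom", "poisson", "gaussian"), phi = 1) {
  family <- match.arg(family)
  if (family == "nbinom") {
    if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0)
      stop("'phi' must be a single positive number for the nbinom family")
  }
  bounds <- switch(family,
    nbinom   = c(.EPS_PARAM, 1 - .EPS_PARAM),
    poisson  = c(.EPS_PARAM, Inf),
    gaussian = c(-Inf, Inf))
  structure(list(family = family, phi = as.numeric(phi),
                 lower = bounds[1L], upper = bounds[2L]),
            class = "loss_model")
}

#' @export
print.loss_model <- function(x, ...) {
  cat("<loss_model>", x$family)
  if (x$family == "nbinom") cat(sprintf(" (phi = %g)", x$phi))
  cat(sprintf(", parameter space (%g, %g)\n", x$lower, x$upper))
  invisible(x)
}

.check_theta <- function(theta, model) {
  if (any(theta <= model$lower - .EPS_PARAM | theta >= model$upper + .EPS_PARAM))
    stop("'theta' outside the open parameter space of the ", model$family,
         " family")
}

#' Point loss of a single observation
#'
#' The per-observation loss \eqn{\gamma(y, \theta)} (negative log-likelihood up
#' to an additive term free of \eqn{\theta}): negative binomial
#' \eqn{-\phi\log\theta - y\log(1-\theta)}; Poisson \eqn{\theta - y\log\theta};
#' Gaussian \eqn{(y-\theta)^2}. Convex in \eqn{\theta} for every fixed y.
#'
#' @param y non-negative count (any numeric for the Gaussian family);
#'   vectorized.
#' @param theta parameter value strictly inside the family's parameter space.
#' @param model a [loss_model()].
#' @return numeric loss value(s).
#' @examples
#' point_loss(0, 0.5, loss_model("nbinom", phi = 1))  # log 2
#' @export
point_loss <- function(y, theta, model) {
  stopifnot(inherits(model, "loss_model"))
  .check_theta(theta, model)
  if (model$family != "gaussian" && any(y < 0))
    stop("counts must be non-negative")
  switch(model$family,
    nbinom   = -model$phi * log(theta) - y * log1p(-theta),
    poisson  = theta - y * log(theta),
    gaussian = (y - theta)^2)
}

#' Segment-cost accumulator
#'
#' Compact coefficient representation of a segment's cost function
#' \eqn{c(r,\theta) = \sum_{t \in r} w_t \gamma(y_t, \theta)}. Two scalars
#' suffice for the count families (the coefficient of \eqn{-\log\theta} and of
#' \eqn{-\log(1-\theta)} for the negative binomial; of \eqn{\theta} and
#' \eqn{-\log\theta} for the Poisson); the Gaussian keeps the three
#' coefficients of the quadratic.
#'
#' @param model a [loss_model()].
#' @return an object of class `seg_cost_acc` (empty accumulator).
#' @seealso [acc_add()], [acc_cost()], [cost_min()], [level_set()]
#' @export
new_accumulator <- function(model) {
  stopifnot(inherits(model, "loss_model"))
  structure(list(model = model, d = c(0, 0, 0), npts = 0L),
            class = "seg_cost_acc")
}

#' Add a (weighted) observation to a segment-cost accumulator
#'
#' After the update the accumulator represents its previous cost function plus
#' \eqn{w\,\gamma(y,\theta)} for every \eqn{\theta}; a weight w is exactly
#' equivalent to adding the same point w times (used by plateau compression).
#'
#' @param acc a `seg_cost_acc`.
#' @param y observation value.
#' @param w positive integer weight (default 1).
#' @return the updated accumulator.
#' @export
acc_add <- function(acc, y, w = 1) {
  stopifnot(inherits(acc, "seg_cost_acc"), w >= 1)
  m <- acc$model
  if (m$family != "gaussian" && (y < 0 || y != round(y)))
    stop("count families require non-negative integer observations")
  acc$d <- switch(m$family,
    nbinom   = acc$d + c(w * m$phi, w * y, 0),
    poisson  = acc$d + c(w, w * y, 0),
    gaussian = acc$d + c(w, w * y, w * y * y))
  acc$npts <- acc$npts + as.integer(w)
  acc
}

#' Evaluate an accumulator's cost function
#'
#' @param acc a `seg_cost_acc`.
#' @param theta parameter value(s) inside the parameter space.
#' @return the segment cost \eqn{c(r,\theta)} at each `theta`.
#' @export
acc_cost <- function(acc, theta) {
  stopifnot(inherits(acc, "seg_cost_acc"))
  m <- acc$model
  .check_theta(theta, m)
  d <- acc$d
  switch(m$family,
    nbinom   = -d[1L] * log(theta) - d[2L] * log1p(-theta),
    poisson  = d[1L] * theta - d[2L] * log(theta),
    gaussian = d[1L] * theta^2 - 2 * d[2L] * theta + d[3L])
}

# unconstrained minimizer, clipped into the numeric parameter bounds
.acc_argmin <- function(acc) {
  m <- acc$model
  d <- acc$d
  th <- switch(m$family,
    nbinom   = if (d[1L] + d[2L] > 0) d[1L] / (d[1L] + d[2L]) else 0.5,
    poisson  = if (d[1L] > 0) d[2L] / d[1L] else 1,
    gaussian = if (d[1L] > 0) d[2L] / d[1L] else 0)
  min(max(th, acc$model$lower), acc$model$upper)
}

#' Closed-form minimizer and minimal cost of a segment
#'
#' Negative binomial: \eqn{\hat\theta = d_1/(d_1+d_2)} which equals
#' \eqn{\phi/(\phi + \bar y_r)}; Poisson and Gaussian: the (weighted) segment
#' mean. The minimizer is clipped into the numeric parameter bounds, so an
#' all-zero segment under the negative binomial returns
#' \eqn{\hat\theta = 1 - \epsilon} with cost essentially 0.
#'
#' @param acc a non-empty `seg_cost_acc`.
#' @return list with `theta` (the minimizer) and `value` (the optimal cost).
#' @export
cost_min <- function(acc) {
  stopifnot(inherits(acc, "seg_cost_acc"))
  if (acc$npts < 1L) stop("cost_min() needs a non-empty accumulator")
  th <- .acc_argmin(acc)
  list(theta = th, value = acc_cost(acc, th))
}

#' Level set of a shifted segment cost
#'
#' Solves \eqn{\{\theta : \mathrm{offset} + c(r,\theta) \le c\}} over the
#' parameter space. By convexity the solution is a single (possibly empty or
#' degenerate) interval: closed form for the Gaussian quadratic, bracketed
#' bisection on each side of the minimizer for the count families.
#'
#' @param acc a `seg_cost_acc`.
#' @param offset additive constant (e.g. the cost of the best previous
#'   partition).
#' @param c threshold.
#' @return numeric vector `c(lower, upper)` or `numeric(0)` when the set is
#'   empty.
#' @export
level_set <- function(acc, offset = 0, c) {
  stopifnot(inherits(acc, "seg_cost_acc"))
  m <- acc$model
  target <- c - offset
  if (m$family == "gaussian") {
    d <- acc$d
    if (d[1L] <= 0) {                       # empty acc: constant function d3
      return(if (d[3L] <= target) c(m$lower, m$upper) else numeric(0))
    }
    disc <- (2 * d[2L])^2 - 4 * d[1L] * (d[3L] - target)
    if (disc < 0) return(numeric(0))
    r <- (2 * d[2L] + c(-1, 1) * sqrt(disc)) / (2 * d[1L])
    return(c(max(r[1L], m$lower), min(r[2L], m$upper)))
  }
  if (acc$npts < 1L)                        # constant zero function
    return(if (0 <= target) c(m$lower, m$upper) else numeric(0))
  th0 <- .acc_argmin(acc)
  if (acc_cost(acc, th0) > target) return(numeric(0))
  f <- function(x) acc_cost(acc, x)
  lo <- if (f(m$lower) <= target) m$lower else
    .bisect_left(f, m$lower, th0, target)
  hi_brk <- m$upper
  if (!is.finite(hi_brk)) {                 # poisson: geometric expansion
    u <- max(th0, 1)
    while (u < 1e290 && f(u) <= target) u <- u * 2
    hi_brk <- u
  }
  hi <- if (f(hi_brk) <= target) hi_brk else
    .bisect_right(f, th0, hi_brk, target)
  c(lo, hi)
}

# f(a) > target, f(b) <= target: return outer (left) bound of the root
.bisect_left <- function(f, a, b, target) {
  for (i in seq_len(.MAX_BISECT)) {
    if (b - a <= .TOL_THETA) break
    mid <- 0.5 * (a + b)
    if (f(mid) <= target) b <- mid else a <- mid
  }
  a
}

# f(a) <= target, f(b) > target: return outer (right) bound of the root
.bisect_right <- function(f, a, b, target) {
  for (i in seq_len(.MAX_BISECT)) {
    if (b - a <= .TOL_THETA) break
    mid <- 0.5 * (a + b)
    if (f(mid) <= target) a <- mid else b <- mid
  }
  b
}
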