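test_that("a clean two-level Poisson series is split at the level change", {
  y <- c(0, 0, 0, 5, 5, 5)
  fit <- pdp_segment(y, model = "poisson", Kmax = 3, compress = FALSE)
  expect_equal(get_breakpoints(fit, 2), 3L)
  # exhaustive check over the 5 possible single breakpoints
  ex <- oracle_best_partition(y, 2, "poisson", NA)
  expect_equal(fit$costs[2], ex$cost, tolerance = 1e-12)
  expect_equal(ex$breaks, 3L)
  expect_equal(fit$costs[2], 15 - 15 * log(5), tolerance = 1e-9)
  expect_equal(fit$theta[[2]], c(1e-12, 5))
  expect_length(get_breakpoints(fit, 1), 0)
})

test_that("pruned sweep costs match exhaustive enumeration over all partitions", {
  set.seed(11)
  y <- rpois(9, 3) + c(0, 0, 0, 6, 6, 6, 0, 0, 0)
  for (fam in c("nbinom", "poisson", "gaussian")) {
    phi <- 0.8
    fit <- pdp_segment(y, model = fam, phi = phi, Kmax = 4, compress = FALSE)
    for (k in 1:4) {
      ex <- oracle_best_partition(y, k, fam, phi)
      expect_equal(fit$costs[k], ex$cost, tolerance = 1e-9)
    }
  }
  # partition count: n = 5, k = 3 has choose(4, 2) = 6 distinct partitions
  expect_equal(ncol(utils::combn(4, 2)), 6)
})

test_that("pruned sweep agrees with the unpruned quadratic DP on random series", {
  set.seed(23)
  for (fam in c("nbinom", "poisson", "gaussian")) {
    for (s in 1:4) {
      y <- if (fam == "gaussian") {
        rnorm(70, mean = rep(c(0, 4, 1), c(25, 25, 20)))
      } else {
        rnbinom(70, size = 0.5, prob = rep(c(0.7, 0.2, 0.4), c(25, 25, 20)))
      }
      fit <- pdp_segment(y, model = fam, phi = 0.5, Kmax = 5,
                         compress = FALSE)
      nd <- naive_dp(y, model = fam, phi = 0.5, Kmax = 5)
      expect_lt(rel_diff(fit$costs, nd$cost[, 70]), 1e-8)
      # backpointer tracebacks reach the same costs
      for (k in 1:5)
        expect_lt(rel_diff(
          oracle_partition_cost(y, get_breakpoints(fit, k), fam, 0.5),
          fit$costs[k]), 1e-8)
    }
  }
})

test_that("weighted points behave exactly like repeated observations", {
  set.seed(5)
  v <- rpois(18, 2)
  w <- sample(1:4, 18, replace = TRUE)
  dense <- rep(v, w)
  fw <- pdp_segment(v, model = "nbinom", phi = 0.7, Kmax = 5, weights = w)
  fd <- pdp_segment(dense, model = "nbinom", phi = 0.7, Kmax = 5,
                    compress = FALSE)
  expect_lt(rel_diff(fw$costs, fd$costs), 1e-9)
})

test_that("extra change-points cannot lower the cost of a constant series", {
  fit <- pdp_segment(rep(4, 30), model = "poisson", Kmax = 4,
                     compress = FALSE)
  expect_true(all(abs(fit$costs - fit$costs[1]) < 1e-9))
})

test_that("costs are non-increasing in the number of segments", {
  set.seed(9)
  for (s in 1:5) {
    y <- plateau_series(200, seed = s)
    fit <- pdp_segment(y, model = "nbinom", phi = 0.3, Kmax = 10)
    expect_true(all(diff(fit$costs) <= 1e-9))
  }
})

test_that("candidate live sets tile the parameter space during the sweep", {
  set.seed(31)
  y <- rpois(50, 4)
  fit <- pdp_segment(y, model = "poisson", Kmax = 6, compress = FALSE)
  expect_lt(fit$diagnostics$max_partition_gap, 1e-6)
  yn <- rnbinom(50, size = 0.5, prob = 0.4)
  fitn <- pdp_segment(yn, model = "nbinom", phi = 0.5, Kmax = 6,
                      compress = FALSE)
  expect_lt(fitn$diagnostics$max_partition_gap, 1e-6)
})

test_that("identical input yields identical segmentations (tie determinism)", {
  set.seed(13)
  y <- rep(rpois(20, 3), each = 3)   # plenty of exact ties
  f1 <- pdp_segment(y, model = "poisson", Kmax = 6)
  f2 <- pdp_segment(y, model = "poisson", Kmax = 6)
  expect_identical(f1$breakpoints, f2$breakpoints)
  expect_identical(f1$costs, f2$costs)
})

test_that("k = n puts every point in its own segment at the pointwise minimum", {
  y <- c(2, 0, 5, 1)
  fit <- pdp_segment(y, model = "poisson", Kmax = 4, compress = FALSE)
  per_point <- sum(vapply(y, function(yy)
    oracle_segment_cost(yy, 1, "poisson", NA), numeric(1)))
  expect_equal(fit$costs[4], per_point, tolerance = 1e-10)
  expect_equal(get_breakpoints(fit, 4), 1:3)
})

test_that("invalid inputs are rejected", {
  expect_error(pdp_segment(c(1, 2, 3), model = "poisson", Kmax = 9),
               "Kmax")
  expect_error(pdp_segment(c(1, -2, 3), model = "poisson", Kmax = 2),
               "non-negative")
  expect_error(pdp_segment(c(1, 2.5, 3), model = "nbinom", phi = 1,
                           Kmax = 2), "integer")
  expect_error(pdp_segment(numeric(0), model = "poisson", Kmax = 1))
})

test_that("constrained best segmentation decomposes the optimum over the fixed breakpoint", {
  y <- c(0, 0, 0, 5, 5, 5)
  b <- best_segmentation_with_breakpoint(y, K = 2, j = 1, t = 3,
                                         model = "poisson")
  full <- pdp_segment(y, model = "poisson", Kmax = 2, compress = FALSE)
  expect_equal(b$cost, full$costs[2], tolerance = 1e-10)
  expect_equal(b$breakpoints, 3)
  curve <- best_segmentation_with_breakpoint(y, K = 2, j = 1, t = 1:5,
                                             model = "poisson")
  expect_equal(which.min(curve$cost), 3L)
  expect_true(all(curve$cost[-3] > curve$cost[3]))

  # min over t equals the unconstrained optimum, for every j
  set.seed(17)
  y2 <- rnbinom(40, size = 0.5, prob = rep(c(0.6, 0.2, 0.5, 0.15),
                                           each = 10))
  K <- 4
  fit <- pdp_segment(y2, model = "nbinom", phi = 0.5, Kmax = K,
                     compress = FALSE)
  for (j in 1:(K - 1)) {
    ts <- seq.int(j, length(y2) - (K - j))
    cv <- best_segmentation_with_breakpoint(y2, K = K, j = j, t = ts,
                                            model = "nbinom", phi = 0.5)
    expect_equal(min(cv$cost), fit$costs[K], tolerance = 1e-9)
  }
  expect_error(best_segmentation_with_breakpoint(y, K = 2, j = 1, t = 6,
                                                 model = "poisson"),
               "infeasible")
})
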