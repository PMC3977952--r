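test_that("the oracle penalty shape evaluates and grows as expected", {
  # direct evaluation: 10 * (1 + 4 sqrt(1.1 + log 100))^2  [derived constant]
  expect_equal(oracle_penalty_shape(10, 1000), 1113.911, tolerance = 1e-4)
  expect_equal(oracle_penalty_shape(1000, 1000),
               1000 * (1 + 4 * sqrt(1.1))^2)
  shapes <- oracle_penalty_shape(1:1000, 1000)
  expect_true(all(diff(shapes) > 0))
  expect_error(oracle_penalty_shape(1001, 1000))
})

test_that("slope-heuristic calibration recovers a planted slope", {
  shapes <- oracle_penalty_shape(1:30, 2000)
  set.seed(8)
  for (s in c(0.2, 1.5)) {
    costs <- 5000 - s * shapes + rnorm(30, sd = 1e-3)
    expect_equal(slope_heuristic_beta(costs, shapes), 2 * s,
                 tolerance = 1e-3)
  }
  # structureless costs: both fits find no negative slope
  expect_error(
    suppressWarnings(slope_heuristic_beta(rep(10, 20),
                                          oracle_penalty_shape(1:20, 500))),
    "slope heuristic failed")
  expect_error(slope_heuristic_beta(1:5, 1:5), "Kmax >= 10")
})

test_that("select_K builds consistent criterion tables for all criteria", {
  sim <- simulate_profile(800, K = 6, phi = 2.3, seed = 77)
  fit <- pdp_segment(sim$y, model = "nbinom", phi = 2.3, Kmax = 20)
  for (crit in c("oracle", "aic", "bic")) {
    tab <- select_K(fit, crit)
    expect_s3_class(tab, "criterion_table")
    expect_equal(nrow(tab), 20L)
    kh <- attr(tab, "K_hat")
    expect_true(kh >= 1 && kh <= 20)
    expect_equal(tab$criterion[kh], min(tab$criterion))
    expect_equal(tab$cost, unname(fit$costs))
  }
  # explicit beta shows the limiting behavior of the oracle criterion
  expect_equal(attr(select_K(fit, "oracle", beta = 1e-12), "K_hat"), 20L)
  expect_equal(attr(select_K(fit, "oracle", beta = 1e12), "K_hat"), 1L)
})

test_that("a constant-signal profile selects a single segment", {
  hits <- sum(vapply(1:10, function(i) {
    set.seed(5000 + i)
    y <- rnbinom(600, size = 2.3, prob = 0.5)
    fit <- pdp_segment(y, model = "nbinom", phi = 2.3, Kmax = 15)
    attr(select_K(fit, "oracle"), "K_hat") == 1L
  }, logical(1)))
  expect_gte(hits, 9)
})

test_that("the plug-in estimate phi/(phi+mean) reproduces the optimal segment cost", {
  # the criterion's first term, written with theta_hat_r = phi/(phi+ybar_r),
  # is exactly the minimized cost because that theta is d1/(d1+d2)
  for (s in 1:5) {
    sim <- simulate_profile(500, K = 6, phi = 0.5, seed = 200 + s)
    fit <- pdp_segment(sim$y, model = "nbinom", phi = 0.5, Kmax = 10,
                       compress = FALSE)
    for (K in c(4, 10)) {
      lab <- labels_from_breakpoints(get_breakpoints(fit, K), sim$n)
      ybar <- tapply(sim$y, lab, mean)
      th <- pmin(pmax(0.5 / (0.5 + ybar), 1e-12), 1 - 1e-12)
      plug <- sum(-0.5 * log(th[lab]) - sim$y * log1p(-th[lab]))
      expect_lt(rel_diff(plug, fit$costs[K]), 1e-9)
    }
  }
})

test_that("the full pipeline recovers the true number of segments", {
  khats <- vapply(1:20, function(i) {
    sim <- simulate_profile(1000, K = 10, phi = 2.3, seed = 4000 + i)
    fit <- pdp_segment(sim$y, model = "nbinom", phi = 2.3, Kmax = 31)
    attr(select_K(fit, "oracle"), "K_hat")
  }, integer(1))
  expect_gte(mean(abs(khats - 10L) <= 1L), 0.8)
})
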