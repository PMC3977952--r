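test_that("point losses match their defining formulas", {
  nb1 <- loss_model("nbinom", phi = 1)
  expect_equal(point_loss(0, 0.5, nb1), log(2))
  expect_equal(point_loss(3, 3, loss_model("gaussian")), 0)
  expect_equal(point_loss(4, 2.5, loss_model("poisson")), 2.5 - 4 * log(2.5))
  # the point-loss minimizer over theta is phi/(phi+y)
  g <- grid_min(function(th) -log(th) - 2 * log1p(-th), 1e-6, 1 - 1e-6)
  expect_equal(g$theta, 1 / 3, tolerance = 1e-4)
  expect_equal(point_loss(2, 1 / 3, nb1), g$value, tolerance = 1e-8)
  expect_equal(point_loss(2, 1 / 3, nb1), 1.909543, tolerance = 1e-6)
})

test_that("theta outside the open parameter space is a domain error", {
  expect_error(point_loss(1, 0, loss_model("nbinom", phi = 1)))
  expect_error(point_loss(1, 1.2, loss_model("nbinom", phi = 1)))
  expect_error(point_loss(1, -0.5, loss_model("poisson")))
  expect_error(loss_model("nbinom", phi = -1))
})

test_that("accumulator updates follow the two-scalar rule and weights equal repetition", {
  nb3 <- loss_model("nbinom", phi = 3)
  a <- acc_add(new_accumulator(nb3), 4)
  expect_equal(a$d[1:2], c(3, 4))
  aw <- acc_add(new_accumulator(nb3), 4, w = 3)
  a3 <- acc_add(acc_add(acc_add(new_accumulator(nb3), 4), 4), 4)
  expect_equal(aw$d, a3$d)
  expect_equal(aw$npts, 3L)

  po <- loss_model("poisson")
  b <- Reduce(function(acc, y) acc_add(acc, y), c(2, 0, 5),
              new_accumulator(po))
  expect_equal(b$d[1:2], c(3, 7))
  expect_equal(acc_cost(b, 1), 3)
})

test_that("accumulated cost equals the sum of point losses (point additivity)", {
  set.seed(42)
  for (fam in c("nbinom", "poisson", "gaussian")) {
    model <- loss_model(fam, phi = 0.7)
    y <- rpois(12, 4)
    acc <- Reduce(function(a, yy) acc_add(a, yy), y, new_accumulator(model))
    thetas <- if (fam == "nbinom") c(0.05, 0.3, 0.9) else c(0.2, 1.7, 6)
    for (th in thetas)
      expect_equal(acc_cost(acc, th), sum(point_loss(y, th, model)),
                   tolerance = 1e-10)
  }
})

test_that("cost_min returns the closed-form minimizer, matching a grid search", {
  nb3 <- loss_model("nbinom", phi = 3)
  acc <- Reduce(function(a, y) acc_add(a, y), c(2, 4, 6),
                new_accumulator(nb3))
  cm <- cost_min(acc)
  expect_equal(cm$theta, 9 / 21)
  expect_equal(cm$value, -9 * log(3 / 7) - 12 * log(4 / 7), tolerance = 1e-12)
  g <- grid_min(function(th) -9 * log(th) - 12 * log1p(-th), 1e-6, 1 - 1e-6)
  expect_equal(cm$value, g$value, tolerance = 1e-6)

  # all-zero segment: minimizer clipped to the upper boundary, cost ~ 0
  az <- acc_add(acc_add(new_accumulator(nb3), 0), 0)
  cmz <- cost_min(az)
  expect_equal(cmz$theta, 1 - 1e-12)
  expect_lt(abs(cmz$value), 1e-9)

  po <- Reduce(function(a, y) acc_add(a, y), c(5, 5, 5),
               new_accumulator(loss_model("poisson")))
  cmp <- cost_min(po)
  expect_equal(cmp$theta, 5)
  expect_equal(cmp$value, 15 - 15 * log(5))

  expect_error(cost_min(new_accumulator(nb3)), "non-empty")
})

test_that("cost functions are convex in theta (midpoint inequality on grids)", {
  set.seed(7)
  for (fam in c("nbinom", "poisson", "gaussian")) {
    model <- loss_model(fam, phi = 1.3)
    acc <- Reduce(function(a, y) acc_add(a, y), rpois(8, 3),
                  new_accumulator(model))
    grid <- if (fam == "nbinom") seq(0.02, 0.98, length.out = 25)
            else seq(0.1, 8, length.out = 25)
    for (i in 1:24) {
      th1 <- grid[i]; th2 <- grid[i + 1]
      mid <- acc_cost(acc, (th1 + th2) / 2)
      expect_lte(mid, (acc_cost(acc, th1) + acc_cost(acc, th2)) / 2 + 1e-10)
    }
  }
})

test_that("level sets are correct intervals of the shifted cost", {
  nb <- loss_model("nbinom", phi = 2)
  acc <- Reduce(function(a, y) acc_add(a, y), c(1, 3, 0, 2),
                new_accumulator(nb))
  cm <- cost_min(acc)
  # below the minimum: empty; at the minimum: degenerate
  expect_length(level_set(acc, 0, cm$value - 1e-6), 0)
  tang <- level_set(acc, 0, cm$value)
  expect_equal(tang[1], cm$theta, tolerance = 1e-6)
  expect_equal(tang[2], cm$theta, tolerance = 1e-6)
  # generic threshold: endpoints sit on the level, interior below it
  for (off in c(0, 2.5)) {
    iv <- level_set(acc, off, cm$value + off + 3)
    expect_equal(acc_cost(acc, iv[1]) + off, cm$value + off + 3,
                 tolerance = 1e-6)
    expect_equal(acc_cost(acc, iv[2]) + off, cm$value + off + 3,
                 tolerance = 1e-6)
    inner <- seq(iv[1] + 1e-6, iv[2] - 1e-6, length.out = 11)
    expect_true(all(acc_cost(acc, inner) + off <= cm$value + off + 3 + 1e-8))
  }
  # gaussian closed form: points {0,2}, solve 2(th-1)^2 + 2 <= 4
  ga <- acc_add(acc_add(new_accumulator(loss_model("gaussian")), 0), 2)
  expect_equal(level_set(ga, 0, 4), c(0, 2), tolerance = 1e-12)
  # poisson right tail is found by geometric expansion
  po <- acc_add(new_accumulator(loss_model("poisson")), 2)
  ivp <- level_set(po, 0, cost_min(po)$value + 5)
  expect_equal(po$d[1] * ivp[2] - po$d[2] * log(ivp[2]),
               cost_min(po)$value + 5, tolerance = 1e-6)
})
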