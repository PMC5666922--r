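test_that("one-sided and target transforms hit their branch values exactly", {
  expect_identical(desirability_one_sided(-0.5, 0, 1, direction = "max"), 0)
  expect_identical(desirability_one_sided(0, 0, 1, direction = "max"), 0)
  expect_identical(desirability_one_sided(1, 0, 1, direction = "max"), 1)
  expect_identical(desirability_one_sided(2, 0, 1, direction = "max"), 1)
  expect_identical(desirability_one_sided(0.5, 0, 1, direction = "max"), 0.5)
  expect_identical(desirability_one_sided(0, 0, 1, direction = "min"), 1)
  expect_identical(desirability_one_sided(1, 0, 1, direction = "min"), 0)
  expect_identical(desirability_one_sided(0.5, 0, 1, direction = "min"), 0.5)
  # exponent bends the ramp
  expect_identical(desirability_one_sided(0.5, 0, 1, s = 2,
                                          direction = "max"), 0.25)

  expect_identical(desirability_target(1, 0, 1, 2), 1)
  expect_identical(desirability_target(0, 0, 1, 2), 0)
  expect_identical(desirability_target(2, 0, 1, 2), 0)
  expect_identical(desirability_target(0.5, 0, 1, 2), 0.5)
  expect_identical(desirability_target(1.5, 0, 1, 2), 0.5)
  expect_identical(desirability_target(-1, 0, 1, 2), 0)

  # degenerate side: target at a bound collapses that side to a step
  expect_identical(desirability_target(1, 1, 1, 2), 1)
  expect_identical(desirability_target(0.9, 1, 1, 2), 0)
  expect_identical(desirability_target(1.5, 1, 1, 2), 0.5)

  expect_error(desirability_one_sided(0.5, 1, 0), "domain error")
  expect_error(desirability_target(0.5, 0, 3, 2), "domain error")

  expect_identical(desirability_in_range(c(0.5, -0.1, 1.1), 0, 1),
                   c(1, 0, 0))
})

test_that("overall desirability reproduces the reference aggregates", {
  d1 <- reference_calibration(1)
  d1 <- d1$desirability[d1$goal == "target"]
  expect_length(d1, 15)
  expect_equal(overall_desirability(d1), 0.625, tolerance = 0.002)

  d2 <- reference_calibration(2)
  d2 <- d2$desirability[d2$goal == "target"]
  expect_length(d2, 6)
  expect_equal(overall_desirability(d2), 0.817, tolerance = 0.002)

  d3 <- reference_calibration(3)
  d3 <- d3$desirability[d3$goal == "target"]
  expect_length(d3, 9)
  expect_equal(overall_desirability(d3), 0.554, tolerance = 0.002)

  expect_identical(overall_desirability(rep(1, 5)), 1)
  expect_identical(overall_desirability(c(0.5, 0, 0.9)), 0)
  expect_error(overall_desirability(numeric(0)), "empty")
})

test_that("desirability is monotone/unimodal and D monotone in each d", {
  grid <- seq(-1, 3, length.out = 401)
  dmax <- desirability_one_sided(grid, 0, 2, s = 1.7, direction = "max")
  expect_true(all(diff(dmax) >= 0))
  dmin <- desirability_one_sided(grid, 0, 2, s = 0.6, direction = "min")
  expect_true(all(diff(dmin) <= 0))
  dt <- desirability_target(grid, 0, 1, 3, s = 2)
  peak <- which.max(dt)
  expect_equal(grid[peak], 1, tolerance = 0.011)
  expect_true(all(diff(dt[seq_len(peak)]) >= 0))
  expect_true(all(diff(dt[peak:length(dt)]) <= 0))

  set.seed(61)
  for (i in 1:20) {
    d <- runif(6, 0.05, 0.95)
    j <- sample(6, 1)
    d_up <- d
    d_up[j] <- d[j] + 0.04
    expect_gt(overall_desirability(d_up), overall_desirability(d))
  }
})

test_that("desirability is invariant to affine rescaling of the response", {
  set.seed(71)
  for (i in 1:20) {
    A <- runif(1, -5, 5)
    B <- A + runif(1, 0.5, 4)
    tg <- runif(1, A, B)
    f <- runif(1, A - 1, B + 1)
    k <- runif(1, 0.1, 50)
    c0 <- runif(1, -10, 10)
    expect_equal(desirability_target(f, A, tg, B, s = 2),
                 desirability_target(k * f + c0, k * A + c0, k * tg + c0,
                                     k * B + c0, s = 2),
                 tolerance = 1e-12)
    expect_equal(desirability_one_sided(f, A, B, direction = "max"),
                 desirability_one_sided(k * f + c0, k * A + c0, k * B + c0,
                                        direction = "max"),
                 tolerance = 1e-12)
  }
})

test_that("the optimizer solves a single-response toy exactly (grid oracle)", {
  # one response depending on one parameter only: y = Cartil_E, target 39
  toy <- structure(list(
    y = list(intercept = 0, coefficients = c(Cartil_E = 1))
  ), class = "response_bundle", provenance = "reference")
  ranges <- default_parameter_ranges()
  cfg <- structure(list(
    criterion = NA,
    input_goals = lapply(seq_len(nrow(ranges)), function(i) {
      goal_spec(ranges$parameter[i], "in_range",
                low = ranges$min[i], high = ranges$max[i])
    }),
    output_goals = list(y = goal_spec("y", "target", target = 39,
                                      low = 23, high = 55))
  ), class = "criterion_config")
  names(cfg$input_goals) <- ranges$parameter

  res <- optimize_desirability(toy, cfg, box = ranges, n_starts = 16,
                               seed = 2)
  # dense-grid oracle over the only active dimension
  grid <- seq(23, 55, length.out = 1e6)
  d_grid <- desirability_target(grid, 23, 39, 55)
  expect_gte(res$D + 1e-9, max(d_grid))
  expect_equal(res$D, 1, tolerance = 1e-6)
  expect_equal(unname(res$predictions["y"]), 39, tolerance = 1e-4)

  # restricting the box away from the pre-image lowers the optimum to the
  # boundary value, never above the unrestricted one
  tight <- ranges
  tight$min[tight$parameter == "Cartil_E"] <- 45
  res_tight <- optimize_desirability(toy, cfg, box = tight, n_starts = 16,
                                     seed = 2)
  expect_lte(res_tight$D, res$D)
  expect_equal(res_tight$D, desirability_target(45, 23, 39, 55),
               tolerance = 1e-6)

  # determinism under a fixed seed
  res_again <- optimize_desirability(toy, cfg, box = ranges, n_starts = 16,
                                     seed = 2)
  expect_identical(res$params, res_again$params)
  expect_identical(res$D, res_again$D)
})

test_that("criterion configurations assign goals per the three criteria", {
  cam <- zero_noise_campaign()
  for (cr in 1:3) {
    cfg <- criterion_config(cr, cam$bounds)
    expect_length(cfg$input_goals, 11)
    expect_true(all(vapply(cfg$input_goals, `[[`, "", "goal") == "in_range"))
    goals <- vapply(cfg$output_goals, `[[`, "", "goal")
    cls <- response_catalogue()$class
    names(cls) <- response_catalogue()$response
    targeted <- names(goals)[goals == "target"]
    if (cr == 1) expect_length(targeted, 15)
    if (cr == 2) expect_setequal(targeted, names(cls)[cls == "stiffness"])
    if (cr == 3) expect_setequal(targeted, names(cls)[cls == "bulge"])
    # targets equal the experimental values and sit inside [A, B]
    for (g in cfg$output_goals) {
      tg <- experimental_targets()
      expect_identical(g$target, tg$target[tg$response == g$variable])
      expect_true(g$low <= g$target && g$target <= g$high)
    }
  }
})
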