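test_that("perfect line gives exact coefficients with zero-width intervals", {
  x <- 1:5
  # summary.lm warns on a degenerate perfect fit; that is the fixture's point
  fit <- suppressWarnings(fit_linear(x, 2 * x + 1))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$slope_hw, 0, tolerance = 1e-12)
  expect_equal(fit$intercept_hw, 0, tolerance = 1e-12)
  expect_error(fit_linear(1:2, 1:2), "3")
  expect_error(fit_linear(rep(1, 5), 1:5), "variance")
})

test_that("confidence half-widths equal the textbook t-interval formulas", {
  set.seed(21)
  x <- stats::runif(40, 0, 10)
  y <- 1.5 * x - 2 + stats::rnorm(40, 0, 0.8)
  fit <- fit_linear(x, y)
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  s2 <- sum((y - a - b * x)^2) / (n - 2)
  se_b <- sqrt(s2 / sum((x - mean(x))^2))
  se_a <- sqrt(s2 * (1 / n + mean(x)^2 / sum((x - mean(x))^2)))
  tq <- stats::qt(0.975, n - 2)
  expect_equal(fit$slope, b, tolerance = 1e-10)
  expect_equal(fit$slope_hw, tq * se_b, tolerance = 1e-10)
  expect_equal(fit$intercept_hw, tq * se_a, tolerance = 1e-10)
})

test_that("station-specific models override the pooled regression", {
  m_l4 <- select_nutrient_model("L4", "nitrate")
  expect_equal(m_l4$slope, -0.939)
  expect_equal(m_l4$intercept, 24.666)
  m_l8 <- select_nutrient_model("L8", "nitrate")
  expect_equal(m_l8$slope, -0.540)
  expect_equal(m_l8$intercept, 14.077)
  expect_equal(select_nutrient_model("unknown", "phosphate")$slope, -0.032)
  expect_error(select_nutrient_model("L1", "nitrate", list()), "empty")
  expect_error(select_nutrient_model("L1", "silicate"), "species")
})

test_that("nutrient reconstruction applies the validity mask and clipping", {
  m <- select_nutrient_model("L8", "nitrate")
  out <- nutrient_from_theta(c(20, 14, 26.5), m)
  expect_equal(out$concentration[1], -0.540 * 20 + 14.077) # 3.277
  expect_true(is.na(out$concentration[2]))
  expect_identical(out$flag[2], "theta-out-of-range")
  expect_identical(out$flag[3], "clipped") # -0.540 * 26.5 + 14.077 < 0
  expect_equal(out$concentration[3], 0)
  p <- nutrient_from_theta(20, select_nutrient_model("L8", "phosphate"))
  expect_equal(p$concentration, -0.032 * 20 + 0.819) # 0.179
  # monotonically decreasing in theta for a negative-slope model
  th <- seq(15.1, 24, by = 0.1)
  conc <- nutrient_from_theta(th, m)$concentration
  expect_true(all(diff(conc) < 0))
})

test_that("calibration chain composes as a single affine map", {
  chain <- default_calibration_chain()
  out <- apply_calibration_chain(c(0.5, 0), chain)
  expect_equal(out$chl[1], 1.11 * (1.42 * 0.5 + 0.10) - 0.08) # 0.819 mg m-3
  expect_equal(out$chl[2], 1.11 * 0.10 - 0.08) # 0.031 mg m-3
  comp <- compose_calibration(chain)
  flu <- seq(0, 2, by = 0.05)
  expect_equal(
    apply_calibration_chain(flu, chain)$chl,
    pmax(comp["slope"] * flu + comp["intercept"], 0),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  # strongly negative input is clipped and flagged
  neg <- apply_calibration_chain(-1, chain)
  expect_equal(neg$chl, 0)
  expect_identical(neg$flag, "clipped")
})

test_that("fitting the chain recovers known coefficients", {
  depths <- seq(100, 400, by = 10)
  flu_tm <- seq(0.1, 1.5, length.out = length(depths))
  flu_ref <- 1.42 * flu_tm + 0.10
  chl <- 1.11 * flu_ref - 0.08
  tm <- data.frame(depth = depths, fluorescence = flu_tm)
  ctd <- data.frame(depth = depths, fluorescence = flu_ref)
  bot <- data.frame(depth = depths, chl = chl)
  # noise-free with min_depth 0: exact recovery
  chain <- suppressWarnings(fit_calibration_chain(tm, ctd, bot, min_depth = 0))
  expect_equal(stage1_coef(chain), c(slope = 1.42, intercept = 0.10))
  expect_equal(stage2_coef(chain), c(slope = 1.11, intercept = -0.08))
  # all pairs shallower than min_depth: error
  shallow <- data.frame(depth = depths - 95, fluorescence = flu_tm)
  expect_error(
    fit_calibration_chain(shallow, ctd, bot, min_depth = 400),
    "fewer than 3"
  )
  # noisy recovery within the fitted confidence intervals, most seeds
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    ctd_n <- data.frame(
      depth = depths, fluorescence = flu_ref + stats::rnorm(length(depths), 0, 0.02)
    )
    bot_n <- data.frame(
      depth = depths, chl = chl + stats::rnorm(length(depths), 0, 0.02)
    )
    ch <- fit_calibration_chain(tm, ctd_n, bot_n, min_depth = 100)
    abs(ch$stage1$slope - 1.42) <= ch$stage1$slope_hw &&
      abs(ch$stage2$slope - 1.11) <= ch$stage2$slope_hw
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})
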