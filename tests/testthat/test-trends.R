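test_that("a noiseless parabola is recovered exactly", {
  temps <- seq(23, 41, 2)
  v <- 2 - 0.1 * (temps - 32)^2
  f <- fit_component_trend(v, temps)
  expect_true(all(f$retained))
  expect_equal(unname(f$coefficients["quadratic_T"]), -0.1,
               tolerance = 1e-8)
  expect_equal(unname(f$coefficients["linear_T"]), 0.1 * 2 * 32,
               tolerance = 1e-8)
  expect_equal(f$fitted, v, tolerance = 1e-8)
  expect_equal(sum((v - f$fitted)^2), 0, tolerance = 1e-12)
})

test_that("constant values simplify to an intercept-only model", {
  temps <- seq(23, 41, 2)
  f <- fit_component_trend(rep(3.7, 10), temps)
  expect_false(any(f$retained))
  expect_equal(unname(f$coefficients),
               c(3.7, 0, 0), tolerance = 1e-10)
  expect_equal(f$fitted, rep(3.7, 10), tolerance = 1e-10)
})

test_that("U-shaped noisy data retains a significant quadratic term", {
  temps <- seq(23, 41, 2)
  set.seed(4)
  v <- 5 + 0.05 * (temps - 31)^2 + rnorm(10, sd = 0.15)
  f <- fit_component_trend(v, temps)
  expect_true(f$retained["quadratic"])
  tab <- f$terms
  fq <- tab$statistic[tab$term == "quadratic_T"]
  expect_gt(fq, qf(0.95, 1, 7))
  # cross-check the full fit against a generic least-squares solve
  X <- cbind(1, temps, temps^2)
  beta <- solve(crossprod(X), crossprod(X, v))
  expect_equal(unname(f$coefficients), unname(drop(beta)),
               tolerance = 1e-6)
})

test_that("OLS residuals are orthogonal to the design columns", {
  temps <- seq(23, 41, 2)
  set.seed(5)
  v <- 1 + 0.02 * temps + rnorm(10, sd = 0.1)
  f <- fit_component_trend(v, temps)
  r <- v - f$fitted
  tc <- temps - mean(temps)
  expect_lt(abs(sum(r)), 1e-8 * max(abs(v)))
  expect_lt(abs(sum(r * tc)), 1e-8 * max(abs(v)) * max(abs(tc)))
})

test_that("trend fits are invariant to shifting the temperature origin", {
  temps <- seq(23, 41, 2)
  set.seed(6)
  v <- 0.01 + 0.002 * (temps - 30)^2 + rnorm(10, sd = 0.004)
  f1 <- fit_component_trend(v, temps)
  f2 <- fit_component_trend(v, temps - 31)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-8)
  expect_equal(f1$terms$statistic, f2$terms$statistic, tolerance = 1e-6)

  k <- c(1, 1, 2, 4, 6, 8, 9, 9, 10, 10)
  g1 <- fit_proportion_trend(k, 10, temps)
  g2 <- fit_proportion_trend(k, 10, temps - 31)
  expect_equal(g1$lr_chisq, g2$lr_chisq, tolerance = 1e-8)
  expect_equal(g1$slope, g2$slope, tolerance = 1e-8)
  expect_equal(g1$fitted, g2$fitted, tolerance = 1e-8)
})

test_that("short inputs are refused", {
  expect_error(fit_component_trend(1:3, c(23, 25, 27)), "at least 4")
  expect_error(fit_proportion_trend(c(1, 2), 10, c(23, 25)), "at least 3")
})

test_that("flat proportions give a null logistic trend", {
  temps <- seq(23, 41, 2)
  f <- fit_proportion_trend(rep(5, 10), 10, temps)
  expect_equal(f$lr_chisq, 0, tolerance = 1e-8)
  expect_equal(f$slope, 0, tolerance = 1e-6)
  expect_false(f$separation)
})

test_that("logistic slope recovery matches a grid-refinement oracle", {
  temps <- seq(23, 41, 2)
  alpha <- -9.6; beta <- 0.3; G <- 1000
  p <- plogis(alpha + beta * temps)
  k <- round(G * p)
  f <- fit_proportion_trend(k, G, temps)
  oracle <- logistic_mle_grid(k, G, temps)
  expect_equal(f$slope, unname(oracle["beta"]), tolerance = 0.01)
  # both within 5% of the generating slope at this sample size
  expect_lt(abs(f$slope - beta) / beta, 0.05)
  expect_lt(abs(oracle["beta"] - beta) / beta, 0.05)
  # the IRLS solution zeroes the score equations
  tc <- temps - mean(temps)
  X <- cbind(1, tc)
  grad <- crossprod(X, k - G * f$fitted)
  expect_lt(max(abs(grad)), 1e-6)
})

test_that("separated counts are flagged and reported as sign only", {
  temps <- seq(23, 41, 2)
  # glm additionally warns about fitted probabilities of 0/1 here
  w <- capture_warnings(f <- fit_proportion_trend(c(rep(0, 9), 10), 10,
                                                  temps))
  expect_true(any(grepl("sign only", w)))
  expect_true(f$separation)
  expect_true(is.na(f$slope))
  expect_equal(f$slope_sign, 1)
  w <- capture_warnings(f0 <- fit_proportion_trend(rep(0, 10), 10, temps))
  expect_true(any(grepl("sign only", w)))
  expect_equal(f0$slope_sign, 0)
})

test_that("a spurious quadratic term is not endorsed", {
  temps <- seq(23, 41, 2)
  k <- c(1, 1, 2, 3, 4, 6, 7, 8, 9, 9)
  f <- fit_proportion_trend(k, 10, temps, quadratic = TRUE)
  expect_false(f$quadratic_improves)
  expect_gt(f$slope, 0)
})

test_that("component trend table covers every component", {
  sim <- simulate_experiment(simulation_config(), seed = 2)
  scores <- build_score_table(sim$records, sim$config$design)
  comp <- partition_all(scores)
  tab <- fit_component_trends(comp)
  expect_setequal(unique(tab$response),
                  c("total", "sigma2_G", "sigma2_E", "sigma2_GE",
                    "responsiveness", "inconsistency"))
  expect_true(all(tab$retained %in% c("yes", "no")))
})
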