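test_that("evaluating the built-in reference coefficients matches desk arithmetic", {
  m <- ib_reference_model()
  # age 0: the sqrt-scale value is the intercept itself
  expect_equal(predict(m, ages = 0, type = "sqrt"), 15.4403)
  expect_equal(predict(m, ages = 0), 15.4403^2)
  # age 1: sum of numerator coefficients over sum of denominator terms
  num1 <- 15.4403 + 19.6695 - 1.0425 + 0.2895
  den1 <- 1 + 0.8408 + 0.4985 - 0.0402 + 0.0015
  expect_equal(predict(m, ages = 1, type = "sqrt"), num1 / den1)
  expect_equal(predict(m, ages = 1), (num1 / den1)^2, tolerance = 1e-12)
  # vectorised evaluation agrees with the independent helper curve
  ages <- seq(0, 17, by = 0.5)
  expect_equal(predict(m, ages = ages, type = "sqrt"),
               unname(ref_eval_sqrt(ages)), tolerance = 1e-12)
})

test_that("a constant model predicts its squared intercept everywhere", {
  d <- data.frame(x = seq(0, 10, length.out = 20), y = 2)
  fit <- ratpoly(d$x, y = d$y, degrees = c(0, 0))
  expect_equal(unname(coef(fit)), 2, tolerance = 1e-12)
  expect_equal(predict(fit, ages = c(0, 3.7, 16)), rep(4, 3),
               tolerance = 1e-10)
})

test_that("noise-free rational curves are recovered exactly by both stages", {
  x <- seq(0, 10, length.out = 50)
  y <- (1 + 2 * x) / (1 + 0.5 * x)
  for (refine in c(TRUE, FALSE)) {
    fit <- ratpoly(x, y = y, degrees = c(1, 1), refine = refine)
    expect_equal(unname(coef(fit)), c(1, 2, 0.5), tolerance = 1e-8)
  }
})

test_that("with zero denominator degree the fit is ordinary polynomial least squares", {
  # exact representation: y = x^2 + 1 through 5 integer points
  x <- 0:4; y <- c(1, 2, 5, 10, 17)
  fit <- ratpoly(x, y = y, degrees = c(2, 0))
  oracle <- unname(coef(lm(y ~ x + I(x^2))))
  expect_equal(unname(coef(fit)), oracle, tolerance = 1e-10)
  expect_equal(unname(coef(fit)), c(1, 0, 1), tolerance = 1e-10)

  # and on noisy data the linearised stage IS the polynomial LS solution
  set.seed(8)
  xn <- runif(60, 0, 5); yn <- 2 + xn - 0.3 * xn^2 + rnorm(60)
  fit <- ratpoly(xn, y = yn, degrees = c(2, 0), refine = FALSE)
  expect_equal(unname(coef(fit)),
               unname(coef(lm(yn ~ xn + I(xn^2)))), tolerance = 1e-9)
})

test_that("refinement never increases the sqrt-scale residual sum of squares", {
  fit <- default_fit()
  expect_lte(fit$rss, fit$stage1$rss)
  # and a genuinely nonlinear case improves on the linearised objective
  expect_lt(fit$rss, 0.99 * fit$stage1$rss)
})

test_that("the coefficient table is self-consistent and matches printed uncertainty", {
  fit <- default_fit()
  ct <- coefficient_table(fit)
  expect_equal(ct$t * ct$se, ct$estimate, tolerance = 1e-10)
  expect_true(all(ct$ci_low < ct$estimate & ct$estimate < ct$ci_high))
  expect_identical(ct$term, letters[1:8])

  # printed reference rows: value/SE reproduces the printed T statistic
  expect_lt(abs(15.4403 / 0.2607 - 59.2154), 0.15)
  expect_lt(abs(0.0015 / 0.0003 - 4.9879), 0.15)
})

test_that("JSON serialisation round-trips a fitted model", {
  fit <- default_fit()
  f <- tempfile(fileext = ".json")
  write_ratpoly_json(fit, f)
  back <- read_ratpoly_json(f)
  expect_equal(coef(back), coef(fit))
  expect_equal(back$degrees, c(num = 3, den = 4))
  expect_equal(unname(vcov(back)), unname(vcov(fit)))
  ages <- seq(0, 17, 0.25)
  expect_equal(predict(back, ages = ages), predict(fit, ages = ages))
})

test_that("evaluation refuses ages where the denominator is not positive", {
  x <- seq(0, 1, length.out = 30)
  y <- 1 / (1 - 0.4 * x)
  fit <- suppressWarnings(ratpoly(x, y = y, degrees = c(0, 1)))
  expect_equal(unname(coef(fit)), c(1, -0.4), tolerance = 1e-6)
  expect_error(predict(fit, ages = 2.5), "denominator.*2.5")
})

test_that("fit preconditions are enforced", {
  expect_error(ratpoly(1:5, y = rnorm(5), degrees = c(3, 4)), "at least")
  expect_error(ratpoly(rep(1, 30), y = rnorm(30), degrees = c(2, 0)),
               "identical|rank")
})

test_that("simulate draws reproducible levels around the fitted curve", {
  fit <- default_fit()
  s1 <- simulate(fit, nsim = 2, seed = 5, ages = c(1, 5, 10))
  s2 <- simulate(fit, nsim = 2, seed = 5, ages = c(1, 5, 10))
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0))
  big <- simulate(fit, seed = 6, ages = rep(5, 20000),
                  sigma_sqrt = 0)[[1]]
  expect_equal(unique(round(big, 9)),
               round(predict(fit, ages = 5), 9))
})
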