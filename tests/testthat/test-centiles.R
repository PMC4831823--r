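test_that("centiles are monotone in probability, non-negative, and median = squared mean", {
  m <- ib_reference_model()
  ct <- centile_table(m, sigma_sqrt = sqrt(8.1))
  vals <- as.matrix(as.data.frame(ct)[-1L])
  expect_true(all(vals >= 0))
  expect_true(all(apply(vals, 1L, function(r) all(diff(r) > 0))))
  expect_equal(unname(vals[, "p50"]), predict(m, ages = 0:17),
               tolerance = 1e-12)
})

test_that("zero dispersion collapses every centile onto the mean curve", {
  m <- ib_reference_model()
  ct <- centile_table(m, sigma_sqrt = 0, ages = 0:5)
  vals <- as.matrix(as.data.frame(ct)[-1L])
  expect_true(all(vals == vals[, 1L]))
  expect_equal(unname(vals[, 1L]), predict(m, ages = 0:5))
})

test_that("early-age centiles reproduce the published table", {
  ct <- centile_table(ib_reference_model(), sigma_sqrt = sqrt(8.1),
                      ages = 0:2)
  df <- as.data.frame(ct)
  # 50th-centile column, rounding-robust ages: published 238 / 223 / 146
  expect_equal(round(df$p50), c(238, 223, 146))
  expect_true(all(abs(df$p50 - c(238, 223, 146)) <= 2))
  # age-0 interquartile range: published 183-301, width 118
  iqr0 <- df$p75[1] - df$p25[1]
  expect_lt(abs(iqr0 - 118), 6)
})

test_that("sqrt-scale interval half-widths are identical at every age", {
  ct <- centile_table(ib_reference_model(), sigma_sqrt = sqrt(8.1))
  df <- as.data.frame(ct)
  hw95 <- sqrt(df$p97.5) - sqrt(df$p2.5)
  hw50 <- sqrt(df$p75) - sqrt(df$p25)
  expect_equal(max(hw95) - min(hw95), 0, tolerance = 1e-10)
  expect_equal(max(hw50) - min(hw50), 0, tolerance = 1e-10)
})

test_that("centile input contracts are enforced", {
  m <- ib_reference_model()
  expect_error(centile_table(m, sigma_sqrt = -1), "sigma")
  expect_error(centile_table(m, sigma_sqrt = 1, probabilities = c(0.5, 1)),
               "inside")
})

test_that("prediction bands enclose confidence bands enclose the fit", {
  fit <- default_fit()
  b <- prediction_bands(fit, ages = seq(0, 17, 0.5))
  expect_true(all(b$pi_low <= b$ci_low))
  expect_true(all(b$ci_low <= b$fit & b$fit <= b$ci_high))
  expect_true(all(b$ci_high <= b$pi_high))
})

test_that("bands collapse onto the curve when both uncertainty sources vanish", {
  fit <- default_fit()
  frozen <- fit
  frozen$vcov <- fit$vcov * 0
  b <- prediction_bands(frozen, ages = 0:17, sigma_sqrt = 0)
  expect_equal(b$ci_low, b$fit, tolerance = 1e-10)
  expect_equal(b$pi_high, b$fit, tolerance = 1e-10)
})

test_that("bands require a coefficient covariance", {
  expect_error(prediction_bands(ib_reference_model()), "covariance")
})

test_that("curve landmarks locate the published peaks and childhood plateau", {
  lm_ <- curve_landmarks(ib_reference_model(), sigma_sqrt = sqrt(8.1))
  peak <- lm_[lm_$type == "max" & !lm_$boundary, ][1L, ]
  expect_gt(peak$age, 0.2); expect_lt(peak$age, 0.4)
  expect_lt(abs(peak$level - 270), 5)
  # published IQR at the postnatal peak: 210-335
  expect_lt(abs(peak$iqr_low - 210), 10)
  expect_lt(abs(peak$iqr_high - 335), 10)
  # childhood plateau: mean level stays in the low range over ages 4-7
  lev47 <- predict(ib_reference_model(), ages = seq(4, 7, 0.01))
  expect_gt(min(lev47), 80)
  expect_lt(max(lev47), 92)
  # the late-adolescent rise ends in a boundary maximum at 17
  top <- lm_[lm_$type == "max" & lm_$boundary, ]
  expect_equal(top$age, 17)
})

test_that("a strictly increasing curve has only boundary landmarks", {
  x <- seq(0, 17, length.out = 30)
  fit <- ratpoly(x, y = 1 + 0.5 * x, degrees = c(1, 0))
  lm_ <- curve_landmarks(fit, interval = c(0, 17))
  expect_true(all(lm_$boundary))
  expect_equal(lm_$type[order(lm_$age)], c("min", "max"))
})

test_that("centile CSV writing mirrors the table layout", {
  ct <- centile_table(ib_reference_model(), sigma_sqrt = sqrt(8.1),
                      ages = 0:3)
  f <- tempfile(fileext = ".csv")
  write_centile_csv(ct, f)
  back <- read.csv(f, check.names = FALSE)
  expect_equal(back$age, 0:3)
  expect_equal(back$p50, as.data.frame(ct)$p50, tolerance = 1e-9)
})
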