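test_that("residual normality scores Gaussian residuals high and flat ones lower", {
  set.seed(21)
  gauss <- residual_normality(rnorm(10000))
  unif <- residual_normality(runif(10000, -1, 1))
  expect_gte(gauss, 95)
  expect_lt(unif, gauss)
  expect_error(residual_normality(rnorm(10)), "at least 30")
})

test_that("the reference curve passes the in-utero non-negativity check", {
  chk <- check_nonnegativity(ib_reference_model())
  expect_false(chk$violation)
  # the anchor forces the curve through ~0 at conception; the minimum sits
  # within rounding distance below zero, not materially negative
  expect_gt(chk$min_value, -0.1)
  expect_lt(chk$min_value, 0.05)
})

test_that("a curve with a numerator root after conception is flagged", {
  # noise-free (1,1) model m(x) = 5(x + 0.3)/(1 + 0.1x): negative in utero
  x <- seq(0, 17, length.out = 40)
  y <- 5 * (x + 0.3) / (1 + 0.1 * x)
  fit <- ratpoly(x, y = y, degrees = c(1, 1))
  chk <- check_nonnegativity(fit)
  expect_true(chk$violation)
  expect_true(all(chk$offending_ages < -0.28))
  expect_lt(chk$min_value, -2)

  # constant positive curves never violate
  const <- ratpoly(x, y = rep(2, 40), degrees = c(0, 0))
  expect_false(check_nonnegativity(const)$violation)
})

test_that("selection applies the rejection, underfit and parsimony rules", {
  aug <- default_cohort()
  sel <- select_ratpoly(aug, num_degrees = 1:4, den_degrees = 0:5)
  expect_s3_class(sel, "ratpoly_selection")
  expect_equal(sum(sel$selected), 1L)
  win <- sel[sel$selected, ]
  # the selected candidate is admissible and not underfit
  expect_false(win$negativity_violation)
  expect_true(win$den_ok)
  expect_false(win$underfit)
  # parsimony: no admissible non-underfit candidate has fewer parameters
  pool <- sel[!sel$failed & !sel$negativity_violation & sel$den_ok &
                !sel$underfit, ]
  expect_equal(win$n_params, min(pool$n_params))
  # on the default synthetic cohort the generating cubic numerator term is
  # statistically weak, so parsimony settles on a 6-parameter neighbour of
  # the generating (3,4) form
  expect_equal(c(win$num_degree, win$den_degree), c(4, 1))
  # underfit is judged relative to the best admissible r2
  best <- max(sel$r2[!sel$failed & !sel$negativity_violation & sel$den_ok])
  expect_true(all(sel$underfit[!is.na(sel$r2)] ==
                    (!sel$failed & !sel$negativity_violation & sel$den_ok &
                       sel$r2 < 0.9 * best)[!is.na(sel$r2)]))
})

test_that("selection is invariant to candidate enumeration order", {
  aug <- default_cohort()
  a <- select_ratpoly(aug, num_degrees = 2:3, den_degrees = 3:4)
  b <- select_ratpoly(aug, num_degrees = 3:2, den_degrees = 4:3)
  expect_equal(attr(a, "selected_degrees"), attr(b, "selected_degrees"))
  expect_equal(coef(selected_model(a)), coef(selected_model(b)))
})

test_that("a negativity violator is never selected even with the top r2", {
  aug <- default_cohort()
  # (4,5) scores the best r2 on this cohort but swings negative in utero;
  # the clean lower-r2 (3,0) candidate must win
  sel <- select_ratpoly(aug, num_degrees = c(3, 4), den_degrees = c(0, 5))
  sub <- sel[(sel$num_degree == 4 & sel$den_degree == 5) |
               (sel$num_degree == 3 & sel$den_degree == 0), ]
  viol <- sub[sub$num_degree == 4, ]
  expect_true(viol$negativity_violation || !viol$den_ok)
  expect_false(viol$selected)
  win <- sel[sel$selected, ]
  expect_false(win$negativity_violation)
})

test_that("a single-candidate grid selects itself without an underfit flag", {
  aug <- default_cohort()
  sel <- select_ratpoly(aug, num_degrees = 1, den_degrees = 0)
  expect_equal(nrow(sel), 1L)
  expect_true(sel$selected)
  expect_false(sel$underfit)
})

test_that("the generating degrees dominate smaller models by a margin that grows as noise shrinks", {
  cfg <- default_generator_config()
  margins <- sapply(c(2.85, 0.5), function(s) {
    cfg$sigma_sqrt <- s
    d <- generate_cohort(cfg, seed = 17)
    aug <- impute_adult_values(add_conception_anchors(d), seed = 18)
    full <- suppressWarnings(ratpoly(aug, degrees = c(3, 4)))
    small <- suppressWarnings(ratpoly(aug, degrees = c(2, 2)))
    full$diagnostics$r2 - small$diagnostics$r2
  })
  expect_true(all(margins > 0))
  expect_gt(margins[2], margins[1])
})
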