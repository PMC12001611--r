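test_that("effects on geometric fixtures: immediate effect is the gap at delta, not at zero", {
  f3b <- its_fit(fixture_f3(), "bernal")
  f3w <- its_fit(fixture_f3(), "wagner")
  # lines meet at delta: immediate effect 0; intercept gap -3; slopes 1 -> 2
  for (f in list(f3b, f3w)) {
    expect_equal(immediate_effect(f)$estimate, 0, tolerance = 1e-12)
    expect_equal(difference_in_intercepts(f)$estimate, -3, tolerance = 1e-12)
    expect_equal(gradual_effect(f)$estimate, 1, tolerance = 1e-12)
    tr <- trend_estimates(f)
    expect_equal(tr$estimate, c(1, 2), tolerance = 1e-12)
  }
  # the classic misinterpretation guard: the two quantities differ
  expect_false(isTRUE(all.equal(immediate_effect(f3b)$estimate,
                                difference_in_intercepts(f3b)$estimate)))

  f1 <- its_fit(fixture_f1(), "bernal")
  expect_equal(immediate_effect(f1)$estimate, 1, tolerance = 1e-12)
  expect_equal(difference_in_intercepts(f1)$estimate, 1, tolerance = 1e-12)

  f2 <- its_fit(fixture_f2(), "wagner")
  et2 <- its_effects(f2)
  expect_equal(et2$estimate[et2$label == "immediate effect"], 0,
               tolerance = 1e-12)
  expect_equal(et2$estimate[et2$label == "pre-intervention trend"], 0.5)
  expect_equal(et2$estimate[et2$label == "post-intervention trend"], 0.5)
  expect_true(all(et2$exact_fit))
  expect_true(all(is.na(et2$p.value)))
})

test_that("effect tables are numerically invariant to the parametrization", {
  set.seed(21)
  for (i in 1:30) {
    d <- random_its()
    eb <- its_effects(its_fit(d, "bernal"))
    ew <- its_effects(its_fit(d, "wagner"))
    expect_equal(eb$label, ew$label)
    expect_lt(rel_diff(eb$estimate, ew$estimate), 1e-9)
    expect_lt(rel_diff(eb$se, ew$se), 1e-9)
    fb <- its_fit(d, "bernal"); fw <- its_fit(d, "wagner")
    expect_lt(abs(fw$beta[[3]] - fb$beta[[3]] -
                    attr(d, "delta") * fb$beta[[4]]), 1e-10)
  }
})

test_that("immediate effect equals the fitted-line gap at delta", {
  set.seed(22)
  for (i in 1:20) {
    d <- random_its()
    f <- its_fit(d, "bernal")
    b <- f$beta; delta <- f$delta
    gap <- (b[[1]] + b[[3]] + (b[[2]] + b[[4]]) * delta) -
      (b[[1]] + b[[2]] * delta)
    expect_lt(abs(immediate_effect(f)$estimate - gap), 1e-10)
  }
})

test_that("effect table contains the six labels once, in order", {
  et <- its_effects(its_fit(fixture_f4(), "wagner"))
  expect_equal(et$label, c(
    "baseline level", "pre-intervention trend", "difference in intercepts",
    "immediate effect", "gradual effect", "post-intervention trend"
  ))
  expect_true(all(et$df == 2))
  expect_true(all(et$p.value >= 0 & et$p.value <= 1))
})

test_that("linear combination SE reduces to coefficient SEs and matches a direct refit", {
  d <- fixture_f4()
  fb <- its_fit(d, "bernal")
  expect_equal(linear_combination_se(fb, c(0, 0, 1, 0)),
               sqrt(fb$vcov[3, 3]))
  # on the converted fit, the unit-weight SE of beta2 equals the direct
  # wagner-fit SE of beta2 (and on the bernal fit it needs weight delta on beta3)
  fw <- its_fit(d, "wagner")
  expect_equal(linear_combination_se(fb, c(0, 0, 1, fb$delta)),
               sqrt(fw$vcov[3, 3]), tolerance = 1e-10)
  conv <- convert_parametrization(fb)
  expect_equal(linear_combination_se(conv, c(0, 0, 1, 0)),
               sqrt(fw$vcov[3, 3]), tolerance = 1e-10)
  expect_error(linear_combination_se(fb, c(0, 0, Inf, 0)), "finite")
  # exact fit: all combination SEs are zero
  f2 <- its_fit(fixture_f2(), "bernal")
  expect_equal(linear_combination_se(f2, c(1, -2, 3, 0.5)), 0)
})

test_that("parametrization conversion matches a direct refit and round-trips", {
  set.seed(23)
  for (i in 1:15) {
    d <- random_its()
    fb <- its_fit(d, "bernal")
    fw <- its_fit(d, "wagner")
    conv <- convert_parametrization(fb)
    expect_equal(conv$parametrization, "wagner")
    expect_lt(rel_diff(conv$beta, fw$beta), 1e-10)
    expect_lt(rel_diff(conv$vcov, fw$vcov), 1e-10)
    back <- convert_parametrization(conv)
    expect_lt(rel_diff(back$beta, fb$beta), 1e-12)
    expect_lt(rel_diff(back$vcov, fb$vcov), 1e-12)
  }
})

test_that("two-sided t test matches the t distribution and flags exact fits", {
  expect_equal(t_test(0, 1, 10)$p.value, 1)
  expect_equal(t_test(2 * 1.5, 1.5, 54)$p.value,
               2 * (1 - pt(2, 54)), tolerance = 1e-12)
  # monotone decreasing in |t|
  ps <- sapply(c(0.5, 1, 2, 5, 20), function(t) t_test(t, 1, 8)$p.value)
  expect_true(all(diff(ps) < 0))
  ex <- t_test(1, 0, 5)
  expect_true(ex$exact_fit)
  expect_true(is.na(ex$p.value))
  # agreement with lm's printed p-values on the noisy fixture
  f <- its_fit(fixture_f4(), "bernal")
  ol <- summary(oracle_lm(fixture_f4(), "bernal"))$coefficients
  et <- its_effects(f)
  expect_equal(et$p.value[et$label == "gradual effect"],
               unname(ol["z", 4]), tolerance = 1e-9)
})
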