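test_that("noiseless fixtures are recovered exactly with zero residual variance", {
  f2 <- its_fit(fixture_f2(), "bernal")
  expect_equal(unname(f2$beta), c(2, 0.5, 0, 0), tolerance = 1e-12)
  expect_equal(f2$sigma2, 0, tolerance = 1e-20)
  expect_equal(unname(sqrt(diag(f2$vcov))), rep(0, 4), tolerance = 1e-12)

  f1 <- its_fit(fixture_f1(), "bernal")
  expect_equal(unname(f1$beta), c(1, 0, 1, 0), tolerance = 1e-12)

  f3b <- its_fit(fixture_f3(), "bernal")
  expect_equal(unname(f3b$beta), c(0, 1, -3, 1), tolerance = 1e-12)
  f3w <- its_fit(fixture_f3(), "wagner")
  expect_equal(unname(f3w$beta), c(0, 1, 0, 1), tolerance = 1e-12)
})

test_that("closed-form and matrix fits agree with the independent lm oracle", {
  for (tag in c("bernal", "wagner")) {
    d <- fixture_f4()
    fm <- fit_ols_matrix(d, tag)
    fc <- fit_closed_form(d, tag)
    ol <- oracle_lm(d, tag)
    expect_lt(rel_diff(unname(fm$beta), unname(coef(ol))), 1e-10)
    expect_lt(rel_diff(unname(fc$beta), unname(coef(ol))), 1e-10)
    expect_lt(rel_diff(fm$sigma2, summary(ol)$sigma^2), 1e-10)
    expect_lt(rel_diff(unname(fm$vcov), unname(vcov(ol))), 1e-10)
    expect_lt(rel_diff(unname(fc$vcov), unname(vcov(ol))), 1e-10)
  }
})

test_that("closed-form estimators match the matrix solution across random designs", {
  set.seed(101)
  for (i in 1:100) {
    d <- random_its()
    for (tag in c("bernal", "wagner")) {
      fm <- fit_ols_matrix(d, tag)
      fc <- fit_closed_form(d, tag)
      expect_lt(rel_diff(fc$beta, fm$beta), 1e-9)
      expect_lt(rel_diff(diag(fc$vcov), diag(fm$vcov)), 1e-9)
      expect_lt(rel_diff(fc$sigma2, fm$sigma2), 1e-12)
    }
  }
})

test_that("pre-segment sufficiency: segment-wise simple regressions reproduce the coefficients", {
  set.seed(7)
  d <- random_its(m = 12, n = 9, sigma = 1.5)
  f <- fit_closed_form(d, "bernal")
  pre <- d[d$post == 0, ]
  post <- d[d$post == 1, ]
  cpre <- coef(lm(outcome ~ time, data = pre))
  cpost <- coef(lm(outcome ~ time, data = post))
  expect_equal(unname(f$beta[1:2]), unname(cpre), tolerance = 1e-9)
  expect_equal(f$beta[[2]] + f$beta[[4]], unname(cpost[2]), tolerance = 1e-9)
  expect_equal(f$beta[[1]] + f$beta[[3]], unname(cpost[1]), tolerance = 1e-9)
})

test_that("fitted values and residuals are identical across parametrizations", {
  set.seed(8)
  for (i in 1:10) {
    d <- random_its()
    fb <- its_fit(d, "bernal")
    fw <- its_fit(d, "wagner")
    expect_equal(fb$fitted, fw$fitted, tolerance = 1e-9)
    expect_equal(fb$residuals, fw$residuals, tolerance = 1e-9)
  }
})

test_that("residual variance follows RSS/(N-p)", {
  expect_equal(estimate_sigma2(rep(0, 6), 6, 4), 0)
  expect_equal(estimate_sigma2(c(1, -1, 1, -1, 0, 0), 6, 4), 2)
  expect_error(estimate_sigma2(rep(1, 4), 4, 4), "degrees of freedom")
})

test_that("closed-form variances match hand arithmetic and the covariance diagonal", {
  # pre times {0,1,2}: centered_ss = 2, sum t^2 = 5 -> var(b1) = 1/2, var(b0) = 5/6
  d <- fixture_f4()
  ss <- segment_summaries(d)
  v <- closed_form_variances(ss[ss$segment == "pre", ],
                             ss[ss$segment == "post", ],
                             sigma2 = 1, delta = 3)
  expect_equal(v$var_beta1, 1 / 2)
  expect_equal(v$var_beta0, 5 / 6)
  expect_equal(closed_form_variances(ss[2, ], ss[1, ], 0, 3) |>
                 unlist() |> unname(), rep(0, 5))

  set.seed(11)
  for (i in 1:25) {
    dr <- random_its()
    sr <- segment_summaries(dr)
    fb <- fit_ols_matrix(dr, "bernal")
    fw <- fit_ols_matrix(dr, "wagner")
    vr <- closed_form_variances(sr[sr$segment == "pre", ],
                                sr[sr$segment == "post", ],
                                fb$sigma2, attr(dr, "delta"))
    expect_lt(rel_diff(vr$var_beta0, fb$vcov[1, 1]), 1e-9)
    expect_lt(rel_diff(vr$var_beta1, fb$vcov[2, 2]), 1e-9)
    expect_lt(rel_diff(vr$var_beta3, fb$vcov[4, 4]), 1e-9)
    expect_lt(rel_diff(vr$var_beta2_bernal, fb$vcov[3, 3]), 1e-9)
    expect_lt(rel_diff(vr$var_beta2_wagner, fw$vcov[3, 3]), 1e-9)
  }
})

test_that("covariance matrix is symmetric with nonnegative diagonal", {
  set.seed(12)
  d <- random_its()
  for (tag in c("bernal", "wagner")) {
    f <- its_fit(d, tag)
    expect_equal(f$vcov, t(f$vcov), tolerance = 1e-12)
    expect_true(all(diag(f$vcov) >= 0))
    expect_true(all(eigen(f$vcov, only.values = TRUE)$values > -1e-9))
  }
})

test_that("broom accessors expose the fit", {
  d <- fixture_f4()
  f <- its_fit(d, "wagner")
  td <- tidy(f)
  expect_equal(nrow(td), 4)
  ol <- summary(oracle_lm(d, "wagner"))$coefficients
  expect_equal(td$estimate, unname(ol[, 1]), tolerance = 1e-9)
  expect_equal(td$std.error, unname(ol[, 2]), tolerance = 1e-9)
  expect_equal(td$p.value, unname(ol[, 4]), tolerance = 1e-9)
  gl <- glance(f)
  expect_equal(gl$nobs, 6)
  expect_equal(gl$df.residual, 2)
  au <- augment(f)
  expect_equal(au$.fitted + au$.resid, d$outcome)
})
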