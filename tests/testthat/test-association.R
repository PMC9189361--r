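test_that("fit_linear matches the closed-form normal-equation oracle", {
  set.seed(31)
  for (k in 1:50) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- rnorm(1) * x + rnorm(1) + rnorm(n, sd = runif(1, 0.1, 2))
    f <- fit_linear(x, y)
    o <- ols_oracle(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$p_slope, o$p, tolerance = 1e-10)
  }
})

test_that("noiseless points on a printed equation are recovered to 4 digits", {
  x <- 0:9
  f <- fit_linear(x, -0.3209 * x + 1.332)
  expect_equal(signif(f$slope, 4), -0.3209)
  expect_equal(signif(f$intercept, 4), 1.332)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_identical(f$equation, "Y = -0.3209*X + 1.332")

  id <- fit_linear(1:5, 1:5)
  expect_equal(id$slope, 1)
  expect_equal(id$intercept, 0, tolerance = 1e-12)
  expect_lt(id$p_slope, 0.001)

  expect_error(fit_linear(rep(1, 5), 1:5), "constant")
  expect_error(fit_linear(1:2, 1:2), "3")
})

test_that("tidy and glance expose the fit in broom style", {
  f <- fit_linear(1:6, 2 * (1:6) + rnorm(6, sd = 0.1))
  td <- tidy(f)
  expect_identical(td$term, c("(Intercept)", "x"))
  expect_equal(td$estimate[2], f$slope)
  gl <- glance(f)
  expect_identical(names(gl), c("r.squared", "p.value", "nobs", "equation"))
  expect_equal(gl$nobs, 6L)
})

test_that("slope test holds its nominal type-I error under the null", {
  set.seed(77)
  reps <- 500
  hits <- vapply(seq_len(reps), function(i) {
    fit_linear(rnorm(20), rnorm(20))$p_slope < 0.05
  }, logical(1))
  expect_equal(mean(hits), 0.05, tolerance = 0.6)  # +/- ~0.03 at 500 reps
})

test_that("stage report recovers the generating structure", {
  # noiseless: equations reproduce the generating coefficients to 4 digits
  noiseless <- stage_association_report(simulate_cohort(noise_scale = 0, seed = 3))
  p <- default_cohort_params()
  for (g in mm_groups()) {
    row <- p[p$group == g, ]
    sub <- noiseless[noiseless$stage == g, ]
    mm <- sub[sub$association == "miR-23 with methylation", ]
    expect_equal(signif(mm$slope, 4), signif(row$mir23_slope, 4))
    expect_equal(signif(mm$intercept, 4), signif(row$mir23_intercept, 4))
    um <- sub[sub$association == "uPA with methylation", ]
    expect_equal(signif(um$slope, 4), signif(row$upa_slope, 4))
  }

  # moderate noise: all 12 slope signs as expected
  noisy <- stage_association_report(simulate_cohort(seed = 4))
  expect_true(all(noisy$sign_ok))
  expect_equal(nrow(noisy), 12L)
  expect_true(all(noisy$expected_sign ==
                    rep(c(-1, -1, 1), times = 4)))

  expect_error(stage_association_report(data.frame(group = "Blood")),
               "missing column")
  expect_error(stage_association_report(simulate_cohort(seed = 1),
                                        stages = c("Blood", "Lung")),
               "must be present")
})

test_that("permuted methylation destroys the methylation associations", {
  set.seed(55)
  n_null <- 0
  reps <- 100
  for (k in seq_len(reps)) {
    cohort <- simulate_cohort(seed = 1000 + k)
    cohort$meth_rate <- sample(cohort$meth_rate)
    rep_k <- stage_association_report(cohort)
    meth_rows <- rep_k[rep_k$association != "uPA with miR-23", ]
    if (all(meth_rows$p_value > 0.05)) n_null <- n_null + 1
  }
  # 8 independent null tests per cohort: expect ~0.95^8 = 66%+ clean cohorts
  expect_gte(n_null / reps, 0.5)
})

test_that("group comparison handles identical and separated groups", {
  same <- data.frame(g = rep(c("a", "b", "c"), each = 3),
                     v = rep(c(1, 2, 3), times = 3))
  cmp <- compare_groups(same, v, g)
  expect_equal(cmp$omnibus$statistic, 0)
  expect_equal(cmp$omnibus$p_value, 1)
  expect_false(any(cmp$pairwise$significant))

  withr::with_seed(21, {
    sep <- data.frame(
      g = rep(c("intraosseous", "blood", "bonetumor", "extra"), each = 10),
      v = rnorm(40, rep(c(1, 3, 3, 6), each = 10), 0.5))
  })
  cmp2 <- compare_groups(sep, v, g)
  expect_lt(cmp2$omnibus$p_value, 1e-6)
  pw <- cmp2$pairwise
  intra <- pw[pw$group1 == "intraosseous" | pw$group2 == "intraosseous", ]
  expect_true(all(intra$significant))
  bb <- pw[pw$group1 == "blood" & pw$group2 == "bonetumor", ]
  expect_false(bb$significant)
  expect_equal(cmp2$means$group[1], "intraosseous")
  expect_equal(cmp2$means$group[4], "extra")
})

test_that("Bonferroni adjustment multiplies by the pairwise family size", {
  withr::with_seed(9, {
    d <- data.frame(g = rep(letters[1:4], each = 6), v = rnorm(24))
  })
  cmp <- compare_groups(d, v, g)
  expect_equal(nrow(cmp$pairwise), choose(4, 2))
  expect_equal(cmp$pairwise$p_adj, pmin(1, 6 * cmp$pairwise$p_raw))
  expect_true(all(cmp$pairwise$p_adj >= cmp$pairwise$p_raw))
  # flags after adjustment are a subset of unadjusted flags
  expect_true(all(!cmp$pairwise$significant | cmp$pairwise$p_raw < 0.05))

  expect_error(compare_groups(data.frame(g = "a", v = 1), v, g), "two groups")
  expect_error(compare_groups(data.frame(g = c("a", "a", "b"), v = 1:3), v, g),
               "at least 2")
})

test_that("sample-size formula matches the closed-form z-quantile expression", {
  expect_identical(required_sample_size(1), 16L)
  expect_identical(required_sample_size(2), 4L)
  manual <- ceiling(2 * (qnorm(0.975) + qnorm(0.8))^2 / 1^2)
  expect_equal(required_sample_size(1), as.integer(manual))
  # n grows without bound as the effect size shrinks
  ns <- vapply(c(2, 1, 0.5, 0.25, 0.1), required_sample_size, integer(1))
  expect_true(all(diff(ns) > 0))
  expect_error(required_sample_size(0), "positive")
})
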