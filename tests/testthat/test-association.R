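test_that("crude_or reproduces known point estimates and the Woolf interval", {
  est <- crude_or(fourfold_table(106, 53, 42, 84))
  expect_equal(est$point, 4.000, tolerance = 1e-12)
  # frozen from the closed form: exp(ln 4 -/+ 1.959964 * sqrt(sum(1/cell)))
  expect_equal(est$ci_low, 2.436093, tolerance = 1e-5)
  expect_equal(est$ci_high, 6.567893, tolerance = 1e-5)
  expect_false(est$corrected)
  expect_equal(crude_or(fourfold_table(1, 1, 1, 1))$point, 1.0)
})

test_that("crude_or symmetries and zero-cell correction", {
  tab <- fourfold_table(12, 7, 5, 20)
  est <- crude_or(tab)
  # invariant under swapping exposure and outcome labels together
  est_swap <- crude_or(fourfold_table(20, 5, 7, 12))
  expect_equal(est_swap$point, est$point)
  # inverts under swapping exposure labels only
  est_inv <- crude_or(fourfold_table(5, 20, 12, 7))
  expect_equal(est_inv$point, 1 / est$point)
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
  # CI width shrinks when all counts scale up
  est4 <- crude_or(fourfold_table(48, 28, 20, 80))
  expect_lt(est4$ci_high / est4$ci_low, est$ci_high / est$ci_low)
  # Haldane-Anscombe keeps zero-cell tables finite and flags them
  z <- crude_or(fourfold_table(10, 0, 5, 12))
  expect_true(z$corrected)
  expect_true(is.finite(z$point) && is.finite(z$ci_high))
  expect_equal(z$point, (10.5 * 12.5) / (0.5 * 5.5))
  expect_error(crude_or(fourfold_table(0, 0, 0, 0)), "all-zero")
})

test_that("chi-square matches the closed form and a generic routine", {
  res <- chi_square_2x2(fourfold_table(106, 53, 42, 84))
  expect_equal(res$statistic, 31.288716, tolerance = 1e-5)
  expect_equal(res$df, 1L)
  ref <- stats::chisq.test(matrix(c(106, 53, 42, 84), 2, byrow = TRUE),
                           correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)

  null <- chi_square_2x2(fourfold_table(5, 5, 5, 5))
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 1)
  # invariant under simultaneous row and column swap
  expect_equal(chi_square_2x2(fourfold_table(84, 42, 53, 106))$statistic,
               res$statistic)
  expect_error(chi_square_2x2(fourfold_table(3, 4, 0, 0)), "margin")
})

test_that("pooled t statistic matches the long-hand formula and t.test", {
  expect_equal(t_test_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(t_test_two_sample(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  withr::with_seed(5, {
    x <- rnorm(40, 60, 8); y <- rnorm(35, 58, 8)
  })
  res <- t_test_two_sample(x, y)
  sp2 <- ((39) * var(x) + (34) * var(y)) / 73
  expect_equal(res$statistic,
               (mean(x) - mean(y)) / sqrt(sp2 * (1 / 40 + 1 / 35)),
               tolerance = 1e-12)
  expect_equal(res$df, 73L)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(t_test_two_sample(1, c(1, 2)), "at least 2")
})

test_that("one-binary-covariate logistic fit equals the crude odds ratio", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      counts <- sample(3:60, 4, replace = TRUE)
      df <- records_from_fourfold(counts[1], counts[2], counts[3], counts[4],
                                  var = "exposure")
      fit <- fit_logistic(df, covariates = "exposure")
      or <- crude_or(fourfold_table(counts[1], counts[2], counts[3],
                                    counts[4]))
      expect_equal(fit$coefficients$B[2], log(or$point), tolerance = 1e-6)
      expect_true(fit$converged)
    }
  })
})

test_that("IRLS agrees with glm on a multivariable ordinal fit", {
  sp <- cohort_spec(control_dist = c(0.35, 0.15, 0.3, 0.2),
                    stratum_ors = c(1.5, 2.5, 5),
                    n_cases = 600, n_controls = 600, seed = 3,
                    extra_variables = c(noise = 0.3))
  df <- generate_cohort(sp)
  cb <- default_codebook()
  df$drinking <- withr::with_seed(4, sample(c("no", "occasionally", "regular"),
                                            nrow(df), replace = TRUE))
  fit <- fit_logistic(df, covariates = c("family_history", "diabetes",
                                         "drinking"),
                      adjust_for_sex = TRUE, cb = cb)
  X <- data.frame(fh = df$family_history, dm = df$diabetes,
                  dr = match(df$drinking, c("no", "occasionally",
                                            "regular")) - 1,
                  sex = match(df$sex, c("male", "female")) - 1,
                  y = as.integer(df$is_case))
  ref <- stats::glm(y ~ fh + dm + dr + sex, data = X, family = binomial())
  expect_equal(fit$coefficients$B, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$SE,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  expect_equal(fit$log_lik, as.numeric(logLik(ref)), tolerance = 1e-6)
  # Wald, OR and CI honor their defining identities
  co <- fit$coefficients
  expect_equal(co$OR, exp(co$B))
  expect_equal(co$wald, (co$B / co$SE)^2)
  z <- qnorm(0.975)
  expect_equal(co$ci_low, exp(co$B - z * co$SE))
  expect_equal(co$ci_high, exp(co$B + z * co$SE))
})

test_that("degenerate designs are reported, not silently fitted", {
  df <- records_from_fourfold(8, 6, 7, 9, var = "exposure")
  df$flat <- 0L
  expect_error(fit_logistic(df, covariates = c("exposure", "flat")),
               "singular")
  # perfect separation: non-converged result with diagnostics, no error
  sep <- records_from_joint(cases = c(0, 0, 20, 0), controls = c(20, 0, 0, 0),
                            vars = c("exposure", "other"))
  fit <- fit_logistic(sep, covariates = "exposure")
  expect_false(fit$converged)
  expect_true(fit$separation)
  expect_error(fit_logistic(df, outcome = "missing_col",
                            covariates = "exposure"), "not a column")
})
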