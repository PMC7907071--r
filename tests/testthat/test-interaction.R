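test_that("RERI, SI, AP, PAP reproduce worked values and simple arithmetic", {
  expect_equal(reri(4.354, 4.505, 16.537), 8.678, tolerance = 1e-12)
  expect_equal(synergy_index(4.354, 4.505, 16.537), 2.265199,
               tolerance = 1e-6)
  ap2 <- attributable_proportions(4.354, 4.505, 16.537)
  expect_equal(ap2$ap, 0.524763, tolerance = 1e-6)
  expect_equal(ap2$pap, 0.558538, tolerance = 1e-6)

  expect_equal(reri(1, 1, 1), 0)
  expect_equal(attributable_proportions(1, 1, 1)$ap, 0)
  expect_equal(reri(2, 2, 4), 1)
  expect_equal(synergy_index(2, 2, 4), 1.5)
  expect_equal(attributable_proportions(2, 2, 4)$ap, 0.25)
  expect_equal(attributable_proportions(2, 2, 4)$pap, 1 / 3)

  # undefined-result signals, not crashes
  expect_true(is.na(synergy_index(1, 1, 3)))
  expect_true(is.na(attributable_proportions(2, 2, 1)$pap))
  expect_error(reri(0, 1, 2), "finite and > 0")
  expect_error(reri(Inf, 1, 2), "finite and > 0")
})

test_that("measure identities, symmetry and monotonicity hold over random triples", {
  withr::with_seed(101, {
    for (i in 1:1000) {
      tr <- random_or_triple()
      r <- reri(tr$or01, tr$or10, tr$or11)
      s <- synergy_index(tr$or01, tr$or10, tr$or11)
      ap2 <- attributable_proportions(tr$or01, tr$or10, tr$or11)
      # ap*or11 = pap*(or11-1) = reri
      expect_equal(ap2$ap * tr$or11, r, tolerance = 1e-12)
      expect_equal(ap2$pap * (tr$or11 - 1), r, tolerance = 1e-9)
      # si = 1 <=> reri = 0 is checked on the equivalent sign relation:
      # si - 1 and reri share their sign when the denominator is positive
      denom <- (tr$or10 - 1) + (tr$or01 - 1)
      if (denom > 0) expect_equal(sign(s - 1), sign(r))
      # with or11 > 1 both denominators are positive and pap's is the
      # smaller, so ap < pap exactly when the interaction is positive
      if (tr$or11 > 1 && r > 0) expect_lt(ap2$ap, ap2$pap)
      if (tr$or11 > 1 && r < 0) expect_gt(ap2$ap, ap2$pap)
      # exchanging exposure labels leaves every measure unchanged
      expect_identical(reri(tr$or10, tr$or01, tr$or11), r)
      expect_identical(synergy_index(tr$or10, tr$or01, tr$or11), s)
      expect_identical(attributable_proportions(tr$or10, tr$or01, tr$or11),
                       ap2)
      # reri strictly increasing in or11, decreasing in the singles
      eps <- 0.1
      expect_gt(reri(tr$or01, tr$or10, tr$or11 + eps), r)
      expect_lt(reri(tr$or01 + eps, tr$or10, tr$or11), r)
      expect_lt(reri(tr$or01, tr$or10 + eps, tr$or11), r)
    }
  })
  # exact additivity: si = 1 and reri = 0 together
  expect_equal(synergy_index(2, 3, 4), 1)
  expect_equal(reri(2, 3, 4), 0)
})

test_that("direction classification follows both rules, which can disagree", {
  d <- classify_direction(4.354, 4.505, 16.537)
  expect_identical(d, list(sum_rule = "positive", reri_rule = "positive"))
  expect_identical(classify_direction(0.741, 4.942, 4.0)$sum_rule, "reverse")
  d2 <- classify_direction(2, 2, 3.5)     # 0 < reri < 1
  expect_identical(d2$sum_rule, "reverse")
  expect_identical(d2$reri_rule, "positive")
  expect_identical(classify_direction(2, 3, 5)$sum_rule, "additive")
  expect_identical(classify_direction(2, 3, 4)$reri_rule, "none")
})

test_that("joint_odds_ratios reproduces printed stratum ORs from counts", {
  ors2 <- joint_odds_ratios(study_tables("table2"))
  expect_equal(round(ors2$or10$point, 3), 4.505)
  expect_equal(round(ors2$or01$point, 3), 4.354)
  ors5 <- joint_odds_ratios(study_tables("table5"))
  expect_equal(round(ors5$or11$point, 3), 6.521)
  expect_equal(ors5$or11$point, 92 * 93 / (32 * 41), tolerance = 1e-12)
  flat <- joint_table(cases = rep(10, 4), controls = rep(10, 4))
  ors <- joint_odds_ratios(flat)
  expect_equal(c(ors$or01$point, ors$or10$point, ors$or11$point), rep(1, 3))
})

test_that("delta intervals agree with the saturated IRLS fit covariance", {
  jt <- joint_table(cases = c(30, 22, 175, 187), controls = c(95, 16, 123, 36))
  ci <- interaction_ci(jt, method = "delta")
  # independent route: fit the saturated two-factor logistic on expanded
  # records and push the Hosmer-Lemeshow gradient through its vcov
  df <- records_from_joint(jt$counts$cases, jt$counts$controls,
                           vars = c("fh", "dm"))
  df$z1 <- as.integer(df$fh == 1 & df$dm == 0)
  df$z2 <- as.integer(df$fh == 0 & df$dm == 1)
  df$z3 <- as.integer(df$fh == 1 & df$dm == 1)
  ref <- stats::glm(is_case ~ z1 + z2 + z3, data = df, family = binomial())
  b <- coef(ref)[2:4]; V <- vcov(ref)[2:4, 2:4]
  g <- c(-exp(b[1]), -exp(b[2]), exp(b[3]))
  se <- sqrt(drop(t(g) %*% V %*% g))
  r <- exp(b[3]) - exp(b[1]) - exp(b[2]) + 1
  expect_equal(ci$ci_reri, unname(c(r - qnorm(0.975) * se,
                                    r + qnorm(0.975) * se)),
               tolerance = 1e-5)
  expect_true(ci$ci_reri[1] <= 8.6 && ci$ci_reri[2] >= 8.6)
})

test_that("degenerate and bootstrap interval contracts hold", {
  flat <- joint_table(cases = rep(25, 4), controls = rep(25, 4))
  d <- interaction_ci(flat, method = "delta")
  expect_true(d$ci_reri[1] <= 0 && d$ci_reri[2] >= 0)
  b1 <- interaction_ci(flat, method = "bootstrap", reps = 1000, seed = 77)
  b2 <- interaction_ci(flat, method = "bootstrap", reps = 1000, seed = 77)
  expect_identical(b1, b2)   # same seed, identical intervals
  expect_true(b1$ci_reri[1] <= 0 && b1$ci_reri[2] >= 0)
  expect_error(interaction_ci(flat, method = "bootstrap", reps = 1000),
               "seed")
  expect_error(interaction_ci(flat, method = "bootstrap", reps = 200,
                              seed = 1), ">= 1000")
})

test_that("the composed analysis matches its parts on engineered records", {
  df <- records_from_joint(cases = c(30, 22, 175, 187),
                           controls = c(95, 16, 123, 36))
  m <- run_interaction_analysis(df, "family_history", "diabetes")
  ors <- joint_odds_ratios(crosstab_joint(df, "family_history", "diabetes"))
  expect_equal(m$or11$point, ors$or11$point)
  expect_equal(m$reri, reri(ors$or01$point, ors$or10$point, ors$or11$point))
  expect_equal(m$ap * m$or11$point, m$reri, tolerance = 1e-12)
  expect_identical(m$direction_sum_rule, "positive")
  expect_error(run_interaction_analysis(df, "diabetes", "diabetes"),
               "distinct")
})

test_that("a cohort with additive (independent) effects has RERI near zero", {
  sp <- cohort_spec(control_dist = c(0.4, 0.25, 0.25, 0.1),
                    stratum_ors = c(or01 = 1.5, or10 = 2, or11 = 2.5),
                    n_cases = 50000, n_controls = 50000, seed = 8)
  m <- run_interaction_analysis(generate_cohort(sp), "family_history",
                                "diabetes")
  expect_lt(abs(m$reri), 0.15)
  expect_true(m$ci$ci_reri[1] <= 0 && m$ci$ci_reri[2] >= 0)
})

test_that("footnote-literal mode reproduces two-decimal worked arithmetic", {
  m <- interaction_from_ors(4.354, 4.505, 16.537, footnote_literal = TRUE)
  expect_equal(round(m$reri, 2), 8.68)
  expect_equal(round(m$si, 2), 2.27)
  expect_equal(m$ap_pct, 52.48)
  expect_equal(m$pap_pct, 55.86)
})
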