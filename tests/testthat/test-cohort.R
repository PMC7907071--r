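test_that("codebook validates recode maps and roles", {
  expect_error(codebook(list(x = list(levels = "a", recode = c(a = 0),
                                      role = "exposure"))),
               "outcome")
  expect_error(codebook(list(
    y = list(levels = c("control", "case"), recode = c(control = 0, case = 1),
             role = "outcome"),
    x = list(levels = c("no", "yes"), recode = c(no = 0), role = "exposure"))),
    "cover exactly")
  expect_error(codebook(list(
    y = list(levels = c("control", "case"), recode = c(control = 0, case = 1),
             role = "outcome"),
    x = list(levels = c("no", "yes"), recode = c(no = 0, yes = 2),
             role = "exposure"))),
    "\\{0, 1\\}")
  cb <- default_codebook()
  expect_identical(outcome_variable(cb), "hypertension")
  expect_true(all(c("family_history", "diabetes", "drinking", "taste",
                    "smoking", "sports", "pressure") %in% variable_names(cb)))
  # every recode map is total over declared levels with image in {0,1}
  for (v in variable_names(cb)) {
    rc <- cb$variables[[v]]$recode
    expect_setequal(names(rc), variable_levels(cb, v))
    expect_true(all(rc %in% c(0L, 1L)))
  }
})

test_that("codebook YAML round-trips", {
  cb <- default_codebook()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_codebook(cb, path)
  cb2 <- read_codebook(path)
  expect_identical(cb2$variables, cb$variables)
})

test_that("read_cohort parses a small file and validates levels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,hypertension,sex,age,drinking",
    "s1,case,male,50,no",
    "s2,control,female,47,occasionally",
    "s3,case,male,61,regular",
    "s4,control,male,63,no"), path)
  rec <- read_cohort(path, quiet = TRUE)
  expect_equal(nrow(rec), 4L)
  expect_equal(sum(rec$is_case), 2L)
  expect_equal(sum(is.na(rec$drinking)), 0L)

  writeLines(c("subject_id,hypertension,drinking",
               "s1,case,sometimes"), path)
  expect_error(read_cohort(path, quiet = TRUE), "drinking")
  writeLines(c("subject_id,drinking", "s1,no"), path)
  expect_error(read_cohort(path, quiet = TRUE), "format error")
})

test_that("write-then-read round-trips every field for random cohorts", {
  cb <- default_codebook()
  for (seed in c(11, 12, 13)) {
    df <- random_cohort(60, seed, cb)
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort(df, path)
    back <- read_cohort(path, cb, quiet = TRUE)
    expect_identical(back, df[names(back)])
  }
})

test_that("dichotomize applies the published recodes and is idempotent", {
  cb <- default_codebook()
  df <- add_is_case(data.frame(
    subject_id = sprintf("s%d", 1:6),
    hypertension = rep(c("case", "control"), 3),
    drinking = c("occasionally", "regular", "no", "no", "regular", "no"),
    taste = c("balance", "light", "salty", "salty", "light", "balance"),
    pressure = c("none", "little", "more", "none", "none", "more"),
    stringsAsFactors = FALSE))
  d1 <- dichotomize(df, "drinking", cb)
  expect_identical(d1$drinking, c(1L, 1L, 0L, 0L, 1L, 0L))
  d2 <- dichotomize(d1, "taste", cb)
  expect_identical(d2$taste, c(0L, 0L, 1L, 1L, 0L, 0L))
  d3 <- dichotomize(d2, "pressure", cb)
  expect_identical(d3$pressure, c(0L, 1L, 1L, 0L, 0L, 1L))
  # idempotent on its own output; other columns untouched
  expect_identical(dichotomize(d3, "drinking", cb), d3)
  expect_identical(d3$hypertension, df$hypertension)
  expect_error(dichotomize(df, "nope", cb), "not declared")
})

test_that("dichotomize propagates missing values and identity-binary input", {
  cb <- default_codebook()
  df <- add_is_case(data.frame(
    subject_id = c("s1", "s2", "s3"),
    hypertension = c("case", "control", "case"),
    drinking = c(NA, "regular", "no"),
    family_history = c(1L, 0L, 1L),
    stringsAsFactors = FALSE))
  out <- dichotomize(df, "drinking", cb)
  expect_identical(out$drinking, c(NA, 1L, 0L))
  expect_identical(dichotomize(df, "family_history", cb)$family_history,
                   df$family_history)
})

test_that("summarize_cohort tallies match a direct loop count", {
  sp <- cohort_spec(control_dist = c(0.35, 0.15, 0.3, 0.2),
                    stratum_ors = c(2, 3, 7),
                    n_cases = 342, n_controls = 342, seed = 42)
  df <- generate_cohort(sp)
  s <- summarize_cohort(df)
  expect_equal(s$n_total, 684L)
  expect_equal(s$n_cases + s$n_controls, s$n_total)
  # percentages sum to 100 over observed levels, per group and variable
  for (v in unique(s$levels$variable)) {
    sub <- s$levels[s$levels$variable == v, ]
    expect_equal(sum(sub$cases_pct), 100)
    expect_equal(sum(sub$controls_pct), 100)
  }
  # counts equal the sum of indicator functions over records
  for (i in seq_len(nrow(s$levels))) {
    v <- s$levels$variable[i]; lv <- s$levels$level[i]
    expect_equal(s$levels$cases_n[i],
                 sum(!is.na(df[[v]]) & as.character(df[[v]]) == lv &
                       df$is_case))
    expect_equal(s$levels$controls_n[i],
                 sum(!is.na(df[[v]]) & as.character(df[[v]]) == lv &
                       !df$is_case))
  }
  expect_error(summarize_cohort(df[0, ]), "empty")
  one <- summarize_cohort(df[1, , drop = FALSE])
  expect_true(all(one$levels$cases_pct[one$levels$cases_n > 0] == 100))
})
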