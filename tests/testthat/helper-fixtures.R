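# fixtures built in code, shared across test files

# tiny hand-countable cohort: 5 cases, 5 controls, two binary exposures
toy_cohort <- function() {
  data.frame(
    subject_id = sprintf("s%02d", 1:10),
    pair_id = NA_character_,
    hypertension = rep(c("case", "control"), each = 5),
    sex = rep(c("male", "female"), 5),
    age = c(40L, 52L, 61L, 45L, 58L, 39L, 50L, 63L, 44L, 60L),
    family_history = c(1L, 1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L),
    diabetes = c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
}
add_is_case <- function(df) { df$is_case <- df$hypertension == "case"; df }

# random valid cohort with categorical levels for round-trip property tests
random_cohort <- function(n, seed, cb = default_codebook()) {
  withr::with_seed(seed, {
    df <- data.frame(
      subject_id = sprintf("r%05d", seq_len(n)),
      pair_id = ifelse(runif(n) < 0.5, sprintf("p%04d", seq_len(n)),
                       NA_character_),
      hypertension = sample(c("case", "control"), n, replace = TRUE),
      sex = sample(c("male", "female"), n, replace = TRUE),
      age = sample(28:87, n, replace = TRUE),
      stringsAsFactors = FALSE)
    for (v in c("family_history", "diabetes", "drinking", "taste")) {
      lv <- variable_levels(cb, v)
      vals <- sample(lv, n, replace = TRUE)
      vals[runif(n) < 0.05] <- NA    # sprinkle missingness
      df[[v]] <- vals
    }
    add_is_case(df)
  })
}

# expand a 2x2x2 count table into one subject record per count unit
records_from_joint <- function(cases, controls,
                               vars = c("family_history", "diabetes")) {
  e1 <- c(0L, 0L, 1L, 1L); e2 <- c(0L, 1L, 0L, 1L)
  rows <- list()
  k <- 0L
  for (i in 1:4) {
    for (cc in c(TRUE, FALSE)) {
      m <- if (cc) cases[i] else controls[i]
      if (m == 0) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = NA_character_,
        is_case = rep(cc, m),
        v1 = rep(e1[i], m), v2 = rep(e2[i], m))
    }
  }
  df <- do.call(rbind, rows)
  df$subject_id <- sprintf("x%05d", seq_len(nrow(df)))
  names(df)[names(df) == "v1"] <- vars[1]
  names(df)[names(df) == "v2"] <- vars[2]
  df
}

# expand a fourfold table (a,b,c,d) into records with one exposure
records_from_fourfold <- function(a, b, c, d, var = "exposure") {
  records_from_joint(cases = c(c, 0, a, 0), controls = c(d, 0, b, 0),
                     vars = c(var, ".dummy"))
}

# random strictly-positive OR triple away from boundary cases
random_or_triple <- function() {
  or <- exp(runif(3, -1.5, 2.5))
  # keep or11 away from 1 and the SI denominator away from 0
  if (abs(or[3] - 1) < 1e-3) or[3] <- or[3] + 0.01
  if (abs((or[1] - 1) + (or[2] - 1)) < 1e-3) or[1] <- or[1] + 0.01
  list(or01 = or[1], or10 = or[2], or11 = or[3])
}
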