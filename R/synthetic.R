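#' Specification of a synthetic matched case-control cohort
#'
#' Describes a 1:1 (or unmatched) case-control cohort over two binary
#' exposures with a known ground truth: controls are drawn from
#' \code{control_dist} over the four exposure strata, and cases from
#' the distribution proportional to \code{control_dist} times the
#' stratum odds ratios — a construction under which the population
#' stratum odds ratios equal the specified values exactly, so the true
#' RERI / SI / AP / PAP are known in closed form.
#'
#' @param control_dist Four probabilities over the strata
#'   \code{(e1,e2) = (0,0), (0,1), (1,0), (1,1)}, each in (0,1),
#'   summing to 1 (within 1e-12).
#' @param stratum_ors Named or ordered triple \code{c(or01, or10,
#'   or11)} of positive finite stratum odds ratios (the implicit
#'   reference OR00 is 1).
#' @param n_cases,n_controls Arm sizes.
#' @param exposures Names of the two exposure columns in the generated
#'   cohort.
#' @param matching \code{"pair"} for a 1:1 matched design (same sex,
#'   age gap at most \code{max_age_gap}; requires equal arm sizes) or
#'   \code{"none"}.
#' @param sex_ratio Probability that a subject (or pair) is male.
#' @param age_range Integer age bounds in years, inclusive.
#' @param max_age_gap Maximum within-pair age difference in years.
#' @param extra_variables Optional named numeric vector of prevalences
#'   for independent binary noise exposures, identical in both arms.
#' @param seed Master seed; all generator randomness derives from it.
#' @return An object of class \code{cohort_spec}.
#' @examples
#' sp <- cohort_spec(control_dist = c(95, 16, 123, 36) / 270,
#'                   stratum_ors = c(or01 = 4.354, or10 = 4.505,
#'                                   or11 = 16.537),
#'                   n_cases = 500, n_controls = 500, seed = 11)
#' expected_tables(sp)
#' @export
cohort_spec <- function(control_dist, stratum_ors, n_cases, n_controls,
                        exposures = c("family_history", "diabetes"),
                        matching = c("pair", "none"), sex_ratio = 0.5,
                        age_range = c(28L, 87L), max_age_gap = 5L,
                        extra_variables = NULL, seed = 1L) {
  matching <- match.arg(matching)
  stopifnot(length(control_dist) == 4L, length(stratum_ors) == 3L,
            length(exposures) == 2L, length(age_range) == 2L)
  if (any(control_dist <= 0) || any(control_dist >= 1) ||
      abs(sum(control_dist) - 1) > 1e-12) {
    stop("control_dist must be four probabilities in (0,1) summing to 1",
         call. = FALSE)
  }
  assert_positive_finite(stratum_ors, "stratum_ors")
  if (n_cases < 1L || n_controls < 1L) {
    stop("arm sizes must be positive", call. = FALSE)
  }
  if (matching == "pair" && n_cases != n_controls) {
    stop("pair matching requires n_cases == n_controls", call. = FALSE)
  }
  assert_prob(sex_ratio, "sex_ratio")
  if (age_range[1] > age_range[2] || any(age_range < 0)) {
    stop("generation error: degenerate age range", call. = FALSE)
  }
  if (exposures[1] == exposures[2]) {
    stop("the two exposures must have distinct names", call. = FALSE)
  }
  ors <- as.double(stratum_ors)
  names(ors) <- c("or01", "or10", "or11")
  structure(list(control_dist = as.double(control_dist),
                 stratum_ors = ors,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 exposures = as.character(exposures),
                 matching = matching, sex_ratio = sex_ratio,
                 age_range = as.integer(age_range),
                 max_age_gap = as.integer(max_age_gap),
                 extra_variables = extra_variables,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d cases / %d controls, matching %s, seed %d\n",
              x$n_cases, x$n_controls, x$matching, x$seed))
  cat(sprintf("  exposures: %s x %s\n", x$exposures[1], x$exposures[2]))
  cat(sprintf("  control stratum probs (00,01,10,11): %s\n",
              paste(fmt_num(x$control_dist, 4), collapse = ", ")))
  cat(sprintf("  stratum ORs: or01 %.3f, or10 %.3f, or11 %.3f\n",
              x$stratum_ors["or01"], x$stratum_ors["or10"],
              x$stratum_ors["or11"]))
  invisible(x)
}

# case stratum probabilities implied by the spec: control prob x OR,
# renormalized; stratum order (00, 01, 10, 11)
case_stratum_probs <- function(spec) {
  w <- spec$control_dist * c(1, spec$stratum_ors["or01"],
                             spec$stratum_ors["or10"],
                             spec$stratum_ors["or11"])
  w / sum(w)
}

#' Analytic expected joint table of a cohort specification
#'
#' Closed-form expected cell counts (arm size times stratum
#' probability), real-valued — the simulation-free oracle for recovery
#' tests: feeding the expected table to
#' \code{\link{joint_odds_ratios}} returns the specified stratum odds
#' ratios exactly.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return A \code{\link{joint_table}} of expected (real-valued)
#'   counts.
#' @export
expected_tables <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  joint_table(cases = spec$n_cases * case_stratum_probs(spec),
              controls = spec$n_controls * spec$control_dist,
              exposures = spec$exposures,
              label = "expected counts")
}

#' True interaction measures of a cohort specification
#'
#' The ground-truth RERI, SI, AP and PAP implied by the specified
#' stratum odds ratios.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return An \code{interaction_measures} object (no intervals).
#' @export
true_interaction <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  m <- interaction_from_ors(spec$stratum_ors["or01"],
                            spec$stratum_ors["or10"],
                            spec$stratum_ors["or11"])
  m$exposures <- spec$exposures
  m$label <- "ground truth"
  m
}

#' Generate a synthetic matched case-control cohort
#'
#' Draws control exposure strata from the spec's control distribution
#' and case strata from the implied case distribution (control
#' probability times stratum OR, renormalized). Under pair matching,
#' case and control of a pair share a \code{pair_id} and sex, and their
#' ages differ by at most the configured gap; matching variables are
#' generated independently of the exposures, so matched and unmatched
#' analyses agree asymptotically. All randomness derives
#' deterministically from the spec's master seed: the same spec yields
#' the identical cohort.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return A cohort data frame compatible with the package's analysis
#'   functions (and with \code{\link{write_cohort}} /
#'   \code{\link{read_cohort}} under the default codebook when the
#'   exposure names are codebook variables): columns
#'   \code{subject_id}, \code{pair_id}, \code{hypertension},
#'   \code{sex}, \code{age}, the two exposures dichotomized to 0/1, any
#'   extra noise variables, and the derived \code{is_case}.
#' @examples
#' sp <- cohort_spec(control_dist = rep(0.25, 4),
#'                   stratum_ors = c(1, 1, 1),
#'                   n_cases = 100, n_controls = 100, seed = 7)
#' head(generate_cohort(sp))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_ca <- spec$n_cases
  n_co <- spec$n_controls
  strata <- cbind(e1 = c(0L, 0L, 1L, 1L), e2 = c(0L, 1L, 0L, 1L))

  ca_idx <- with_seed(derive_seed(spec$seed, 1L),
                      sample.int(4L, n_ca, replace = TRUE,
                                 prob = case_stratum_probs(spec)))
  co_idx <- with_seed(derive_seed(spec$seed, 2L),
                      sample.int(4L, n_co, replace = TRUE,
                                 prob = spec$control_dist))

  if (spec$matching == "pair") {
    demo <- with_seed(derive_seed(spec$seed, 3L), {
      sex <- ifelse(stats::runif(n_ca) < spec$sex_ratio, "male", "female")
      age_ca <- sample(seq(spec$age_range[1], spec$age_range[2]), n_ca,
                       replace = TRUE)
      # control age drawn uniformly from the feasible window around the
      # case's age, so the gap bound holds by construction
      lo <- pmax(spec$age_range[1], age_ca - spec$max_age_gap)
      hi <- pmin(spec$age_range[2], age_ca + spec$max_age_gap)
      age_co <- lo + floor(stats::runif(n_ca) * (hi - lo + 1L))
      list(sex_ca = sex, sex_co = sex, age_ca = age_ca,
           age_co = as.integer(age_co),
           pair_ca = sprintf("p%06d", seq_len(n_ca)),
           pair_co = sprintf("p%06d", seq_len(n_co)))
    })
  } else {
    demo <- with_seed(derive_seed(spec$seed, 3L), {
      sex <- ifelse(stats::runif(n_ca + n_co) < spec$sex_ratio,
                    "male", "female")
      age <- sample(seq(spec$age_range[1], spec$age_range[2]), n_ca + n_co,
                    replace = TRUE)
      list(sex_ca = sex[seq_len(n_ca)], sex_co = sex[n_ca + seq_len(n_co)],
           age_ca = age[seq_len(n_ca)], age_co = age[n_ca + seq_len(n_co)],
           pair_ca = rep(NA_character_, n_ca),
           pair_co = rep(NA_character_, n_co))
    })
  }

  df <- data.frame(
    subject_id = c(sprintf("case%06d", seq_len(n_ca)),
                   sprintf("ctrl%06d", seq_len(n_co))),
    pair_id = c(demo$pair_ca, demo$pair_co),
    hypertension = c(rep("case", n_ca), rep("control", n_co)),
    sex = c(demo$sex_ca, demo$sex_co),
    age = c(demo$age_ca, demo$age_co),
    stringsAsFactors = FALSE)
  df[[spec$exposures[1]]] <- strata[c(ca_idx, co_idx), "e1"]
  df[[spec$exposures[2]]] <- strata[c(ca_idx, co_idx), "e2"]

  if (!is.null(spec$extra_variables)) {
    for (k in seq_along(spec$extra_variables)) {
      nm <- names(spec$extra_variables)[k]
      prev <- spec$extra_variables[[k]]
      assert_prob(prev, nm)
      df[[nm]] <- with_seed(derive_seed(spec$seed, 10L + k),
                            as.integer(stats::runif(n_ca + n_co) < prev))
    }
  }
  df$is_case <- df$hypertension == "case"
  df
}
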