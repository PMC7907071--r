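#' Stratum odds ratios of a joint exposure table
#'
#' Computes the three non-reference stratum odds ratios of a 2x2x2
#' table against the double-unexposed cell: \code{or01} (exposure 2
#' only), \code{or10} (exposure 1 only) and \code{or11} (both), each by
#' \code{\link{collapse_to_fourfold}} then \code{\link{crude_or}}.
#'
#' @param joint A \code{\link{joint_table}}.
#' @param level Confidence level for the Woolf intervals.
#' @return A list with elements \code{or01}, \code{or10}, \code{or11},
#'   each an \code{or_estimate}.
#' @examples
#' joint_odds_ratios(study_tables("table3"))
#' @export
joint_odds_ratios <- function(joint, level = 0.95) {
  stopifnot(inherits(joint, "joint_table"))
  list(or01 = crude_or(collapse_to_fourfold(joint, c(0L, 1L)), level),
       or10 = crude_or(collapse_to_fourfold(joint, c(1L, 0L)), level),
       or11 = crude_or(collapse_to_fourfold(joint, c(1L, 1L)), level))
}

check_or_triple <- function(or01, or10, or11) {
  for (x in list(or01 = or01, or10 = or10, or11 = or11)) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("domain error: stratum odds ratios must be finite and > 0",
           call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Relative excess risk due to interaction
#'
#' \code{RERI = OR11 - OR10 - OR01 + 1}: the departure of the joint
#' odds ratio from additivity of the two single-exposure excesses.
#' Zero under exact additivity.
#'
#' @param or01,or10,or11 Positive finite stratum odds ratios (exposure 2
#'   only, exposure 1 only, both) against the double-unexposed
#'   reference.
#' @return A single number.
#' @examples
#' reri(4.354, 4.505, 16.537)   # 8.678
#' @export
reri <- function(or01, or10, or11) {
  check_or_triple(or01, or10, or11)
  # grouped so the result is exactly invariant under swapping the two
  # exposure labels (floating-point addition is commutative)
  unname(or11 - (or10 + or01) + 1)
}

#' Synergy index
#'
#' \code{SI = (OR11 - 1) / ((OR10 - 1) + (OR01 - 1))}: the ratio of the
#' joint excess effect to the sum of the single-exposure excesses; 1
#' under additivity, above 1 for synergy. Undefined (returned as
#' \code{NA}) when the denominator is zero, i.e. when the two additive
#' single-exposure effects cancel or are both absent.
#'
#' @inheritParams reri
#' @return A single number, or \code{NA_real_} when undefined.
#' @examples
#' synergy_index(4.354, 4.505, 16.537)   # 2.265
#' @export
synergy_index <- function(or01, or10, or11) {
  check_or_triple(or01, or10, or11)
  denom <- (or10 - 1) + (or01 - 1)
  if (denom == 0) return(NA_real_)
  unname((or11 - 1) / denom)
}

#' Attributable proportions due to interaction
#'
#' \code{AP = RERI / OR11} is the fraction of the dual-exposure effect
#' attributable to interaction; \code{PAP = RERI / (OR11 - 1)} is the
#' same fraction relative to the excess (above-baseline) effect of the
#' dual exposure, undefined (\code{NA}) when \code{OR11 = 1}. Both are
#' returned as fractions; reports render them as percentages.
#'
#' @inheritParams reri
#' @return A list with elements \code{ap} and \code{pap}.
#' @examples
#' attributable_proportions(4.354, 4.505, 16.537)
#' @export
attributable_proportions <- function(or01, or10, or11) {
  check_or_triple(or01, or10, or11)
  r <- reri(or01, or10, or11)
  list(ap = unname(r / or11),
       pap = if (or11 == 1) NA_real_ else unname(r / (or11 - 1)))
}

#' Classify the direction of additive interaction
#'
#' Two rules are always reported side by side. The sum rule compares
#' the joint OR with the plain sum of the single-exposure ORs
#' (\code{positive} if \code{OR11 > OR10 + OR01}, \code{reverse} if
#' smaller, \code{additive} if equal) — note this threshold is
#' equivalent to \code{RERI > 1}, not \code{RERI > 0}. The RERI rule
#' classifies by the sign of RERI (\code{positive}, \code{negative},
#' \code{none}); the two rules can disagree when \code{0 < RERI < 1}.
#'
#' @inheritParams reri
#' @return A list with elements \code{sum_rule} and \code{reri_rule}.
#' @examples
#' classify_direction(0.741, 4.942, 4.0)   # sum rule: reverse
#' @export
classify_direction <- function(or01, or10, or11) {
  check_or_triple(or01, or10, or11)
  s <- or10 + or01
  r <- reri(or01, or10, or11)
  list(sum_rule = if (or11 > s) "positive"
                  else if (or11 < s) "reverse" else "additive",
       reri_rule = if (r > 0) "positive"
                   else if (r < 0) "negative" else "none")
}

# cells of a joint table as a list of 8 counts, Haldane-corrected as a
# block if any cell is zero (keeps the saturated-fit covariance finite)
joint_cells <- function(joint) {
  ct <- joint$counts[order(joint$counts$e1, joint$counts$e2), ]
  cells <- list(a0 = ct$cases[1], b0 = ct$controls[1],
                a01 = ct$cases[2], b01 = ct$controls[2],
                a10 = ct$cases[3], b10 = ct$controls[3],
                a11 = ct$cases[4], b11 = ct$controls[4])
  corrected <- any(unlist(cells) == 0)
  if (corrected) cells <- lapply(cells, `+`, 0.5)
  cells$corrected <- corrected
  cells
}

# log stratum ORs (b1 = ln OR10, b2 = ln OR01, b3 = ln OR11) and their
# saturated-logistic covariance in closed form: var(b_k) sums the four
# reciprocal cells of its collapsed 2x2; cov(b_j, b_k) keeps only the
# shared reference-cell terms
saturated_log_ors <- function(cells) {
  ref <- 1 / cells$a0 + 1 / cells$b0
  b <- c(log(cells$a10 * cells$b0 / (cells$b10 * cells$a0)),
         log(cells$a01 * cells$b0 / (cells$b01 * cells$a0)),
         log(cells$a11 * cells$b0 / (cells$b11 * cells$a0)))
  v <- c(1 / cells$a10 + 1 / cells$b10,
         1 / cells$a01 + 1 / cells$b01,
         1 / cells$a11 + 1 / cells$b11) + ref
  sigma <- matrix(ref, 3, 3)
  diag(sigma) <- v
  list(b = b, sigma = sigma)
}

delta_interaction_ci <- function(joint, level) {
  cells <- joint_cells(joint)
  fit <- saturated_log_ors(cells)
  b <- fit$b; sigma <- fit$sigma
  z <- z_quantile(level)
  e1 <- exp(b[1]); e2 <- exp(b[2]); e3 <- exp(b[3])

  r <- e3 - e1 - e2 + 1
  g_r <- c(-e1, -e2, e3)
  se_r <- sqrt(drop(t(g_r) %*% sigma %*% g_r))
  ci_reri <- c(r - z * se_r, r + z * se_r)

  ap <- r / e3
  g_ap <- c(-exp(b[1] - b[3]), -exp(b[2] - b[3]),
            exp(b[1] - b[3]) + exp(b[2] - b[3]) - exp(-b[3]))
  se_ap <- sqrt(drop(t(g_ap) %*% sigma %*% g_ap))
  ci_ap <- c(ap - z * se_ap, ap + z * se_ap)

  # SI interval on the log scale; defined only when both the joint
  # excess and the summed single excesses are positive
  if (e3 > 1 && e1 + e2 > 2) {
    lsi <- log(e3 - 1) - log(e1 + e2 - 2)
    g_si <- c(-e1 / (e1 + e2 - 2), -e2 / (e1 + e2 - 2), e3 / (e3 - 1))
    se_si <- sqrt(drop(t(g_si) %*% sigma %*% g_si))
    ci_si <- exp(c(lsi - z * se_si, lsi + z * se_si))
  } else {
    ci_si <- c(NA_real_, NA_real_)
  }
  list(ci_reri = ci_reri, ci_ap = ci_ap, ci_si = ci_si,
       method = "delta", level = level, corrected = cells$corrected,
       n_undefined = if (all(is.finite(ci_si))) 0L else 1L,
       warning = FALSE)
}

bootstrap_interaction_ci <- function(joint, level, reps, seed) {
  ct <- joint$counts[order(joint$counts$e1, joint$counts$e2), ]
  n_cases <- sum(ct$cases)
  n_controls <- sum(ct$controls)
  if (n_cases == 0 || n_controls == 0) {
    stop("domain error: bootstrap needs cases and controls", call. = FALSE)
  }
  stats_mat <- with_seed(seed, {
    ca <- stats::rmultinom(reps, n_cases, ct$cases / n_cases)
    co <- stats::rmultinom(reps, n_controls, ct$controls / n_controls)
    vapply(seq_len(reps), function(i) {
      jt <- joint_table(ca[, i], co[, i], exposures = joint$exposures)
      ors <- joint_odds_ratios(jt, level)
      o01 <- ors$or01$point; o10 <- ors$or10$point; o11 <- ors$or11$point
      c(reri = reri(o01, o10, o11),
        ap = attributable_proportions(o01, o10, o11)$ap,
        si = synergy_index(o01, o10, o11))
    }, double(3))
  })
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qi <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(c(NA_real_, NA_real_))
    unname(stats::quantile(x, pr))
  }
  n_undef <- sum(!is.finite(stats_mat["si", ])) +
    sum(!is.finite(stats_mat["reri", ])) + sum(!is.finite(stats_mat["ap", ]))
  list(ci_reri = qi(stats_mat["reri", ]), ci_ap = qi(stats_mat["ap", ]),
       ci_si = qi(stats_mat["si", ]),
       method = "bootstrap", level = level, reps = reps, seed = seed,
       n_undefined = n_undef,
       warning = sum(!is.finite(stats_mat["si", ])) > 0.1 * reps)
}

#' Interval estimates for the additive interaction measures
#'
#' Delta-method intervals (RERI on the natural scale with the
#' Hosmer-Lemeshow gradient, AP by the delta method on the log-odds
#' parameters, SI on the log scale), with the log-odds covariance taken
#' from the saturated two-exposure logistic model evaluated in closed
#' form on the table cells; or percentile-bootstrap intervals,
#' resampling cases and controls separately with replacement in
#' exposure-stratum space. Replicates on which a measure is undefined
#' (SI with a zero denominator) are dropped from that measure's
#' percentile interval and counted in \code{n_undefined}; if more than
#' 10\% of SI replicates are undefined the result carries
#' \code{warning = TRUE}.
#'
#' @param joint A \code{\link{joint_table}}. Tables containing a zero
#'   cell are Haldane-corrected (+0.5 to every cell) as a block.
#' @param method \code{"delta"} or \code{"bootstrap"}.
#' @param level Confidence level.
#' @param reps Bootstrap replicates (at least 1000).
#' @param seed Seed, mandatory for the bootstrap: the same seed gives
#'   identical intervals.
#' @return A list with elements \code{ci_reri}, \code{ci_ap},
#'   \code{ci_si} (each \code{c(low, high)}), plus method metadata.
#' @examples
#' interaction_ci(study_tables("table3"), method = "delta")
#' @export
interaction_ci <- function(joint, method = c("delta", "bootstrap"),
                           level = 0.95, reps = 1000L, seed = NULL) {
  stopifnot(inherits(joint, "joint_table"))
  assert_prob(level, "level")
  method <- match.arg(method)
  if (method == "delta") return(delta_interaction_ci(joint, level))
  if (is.null(seed)) {
    stop("bootstrap intervals require an explicit `seed`", call. = FALSE)
  }
  if (reps < 1000L) {
    stop("bootstrap requires `reps` >= 1000", call. = FALSE)
  }
  bootstrap_interaction_ci(joint, level, as.integer(reps), seed)
}

new_interaction_measures <- function(ors, ci, exposures, label = "") {
  o01 <- ors$or01$point; o10 <- ors$or10$point; o11 <- ors$or11$point
  dir <- classify_direction(o01, o10, o11)
  ap2 <- attributable_proportions(o01, o10, o11)
  structure(list(
    exposures = exposures, label = label,
    or01 = ors$or01, or10 = ors$or10, or11 = ors$or11,
    reri = reri(o01, o10, o11),
    si = synergy_index(o01, o10, o11),
    ap = ap2$ap, pap = ap2$pap,
    direction_sum_rule = dir$sum_rule,
    direction_reri = dir$reri_rule,
    ci = ci), class = "interaction_measures")
}

#' Full additive interaction analysis of two exposures
#'
#' Composes the whole pipeline on subject records: joint 2x2x2
#' tabulation, stratum odds ratios against the double-unexposed
#' reference, RERI / SI / AP / PAP, both direction classifications, and
#' interval estimates for the interaction measures.
#'
#' @param records Cohort data frame with both exposures dichotomized.
#' @param variable1,variable2 Distinct binary exposure columns.
#' @param level Confidence level.
#' @param ci_method \code{"delta"} or \code{"bootstrap"} (see
#'   \code{\link{interaction_ci}}).
#' @param reps,seed Bootstrap parameters.
#' @return An object of class \code{interaction_measures}.
#' @export
run_interaction_analysis <- function(records, variable1, variable2,
                                     level = 0.95,
                                     ci_method = c("delta", "bootstrap"),
                                     reps = 1000L, seed = NULL) {
  ci_method <- match.arg(ci_method)
  joint <- crosstab_joint(records, variable1, variable2)
  analyze_joint_table(joint, level = level, ci_method = ci_method,
                      reps = reps, seed = seed)
}

#' @rdname run_interaction_analysis
#' @param joint A prebuilt \code{\link{joint_table}} (count mode: the
#'   eight integers are the input, no subject records needed).
#' @export
analyze_joint_table <- function(joint, level = 0.95,
                                ci_method = c("delta", "bootstrap"),
                                reps = 1000L, seed = NULL) {
  ci_method <- match.arg(ci_method)
  ors <- joint_odds_ratios(joint, level)
  ci <- interaction_ci(joint, method = ci_method, level = level,
                       reps = reps, seed = seed)
  new_interaction_measures(ors, ci, joint$exposures, joint$label)
}

#' Interaction measures from three published odds ratios
#'
#' Computes RERI, SI, AP and PAP directly from a user-supplied OR
#' triple, with no counts involved — the mode used to re-derive a
#' published worked example from its printed (rounded) odds ratios.
#' With \code{footnote_literal = TRUE} the percentages follow the
#' arithmetic such worked examples print: the percent numerator is the
#' two-decimal RERI and the final percent digit is truncated rather
#' than rounded (published footnotes of this form round RERI first and
#' truncate the quotient; full-precision arithmetic differs in the last
#' digit).
#'
#' @inheritParams reri
#' @param footnote_literal Reproduce two-decimal footnote arithmetic
#'   (see Details).
#' @return An \code{interaction_measures} object without interval
#'   estimates (\code{ci = NULL}); with \code{footnote_literal} the
#'   components \code{ap_pct} and \code{pap_pct} carry the literal
#'   two-decimal percentages.
#' @examples
#' m <- interaction_from_ors(4.354, 4.505, 16.537, footnote_literal = TRUE)
#' c(round(m$reri, 2), round(m$si, 2), m$ap_pct, m$pap_pct)
#' @export
interaction_from_ors <- function(or01, or10, or11,
                                 footnote_literal = FALSE) {
  check_or_triple(or01, or10, or11)
  est <- function(p) structure(list(point = p, ci_low = NA_real_,
                                    ci_high = NA_real_, level = NA_real_,
                                    method = "printed", corrected = FALSE),
                               class = "or_estimate")
  m <- new_interaction_measures(list(or01 = est(or01), or10 = est(or10),
                                     or11 = est(or11)),
                                ci = NULL,
                                exposures = c("exposure1", "exposure2"),
                                label = "from printed ORs")
  if (footnote_literal) {
    r2 <- round(m$reri, 2)
    m$ap_pct <- trunc(100 * r2 / or11 * 100) / 100
    m$pap_pct <- if (or11 == 1) NA_real_
                 else trunc(100 * r2 / (or11 - 1) * 100) / 100
  }
  m
}

#' @export
print.interaction_measures <- function(x, ...) {
  cat(sprintf("Additive interaction: %s x %s%s\n", x$exposures[1],
              x$exposures[2],
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  fmt_ci <- function(e) {
    if (is.na(e$ci_low)) fmt_num(e$point, 3)
    else sprintf("%s (%s-%s)", fmt_num(e$point, 3), fmt_num(e$ci_low, 3),
                 fmt_num(e$ci_high, 3))
  }
  cat(sprintf("  OR10 %s   OR01 %s   OR11 %s\n",
              fmt_ci(x$or10), fmt_ci(x$or01), fmt_ci(x$or11)))
  cat(sprintf("  RERI %s   SI %s   AP %s%%   PAP %s%%\n",
              fmt_num(x$reri, 2),
              if (is.na(x$si)) "undefined (additive effects absent)"
              else fmt_num(x$si, 2),
              fmt_num(100 * x$ap, 2),
              if (is.na(x$pap)) "undefined" else fmt_num(100 * x$pap, 2)))
  cat(sprintf("  direction: sum rule %s, RERI sign %s\n",
              x$direction_sum_rule, x$direction_reri))
  if (!is.null(x$ci)) {
    cat(sprintf("  %d%% CI (%s): RERI %s to %s; AP %s to %s; SI %s to %s\n",
                round(100 * x$ci$level), x$ci$method,
                fmt_num(x$ci$ci_reri[1], 3), fmt_num(x$ci$ci_reri[2], 3),
                fmt_num(x$ci$ci_ap[1], 3), fmt_num(x$ci$ci_ap[2], 3),
                if (is.na(x$ci$ci_si[1])) "NA" else fmt_num(x$ci$ci_si[1], 3),
                if (is.na(x$ci$ci_si[2])) "NA" else fmt_num(x$ci$ci_si[2], 3)))
  }
  invisible(x)
}
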