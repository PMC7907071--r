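# interadd

Additive-scale interaction analysis for matched case-control studies.

Epidemiologists assessing whether two risk factors act synergistically —
e.g. whether a family history of hypertension and a diabetes history
together raise the odds of hypertension beyond the sum of their separate
effects — work on the *additive* scale: biologic interaction is a
departure from additivity of effects, not from multiplicativity.
`interadd` implements that analysis end to end for case-control data:

- 2×2 and 2×2×2 contingency tables from subject-level records, with a
  variable codebook and the standard three-level → binary lifestyle
  recodes (no/occasionally/regular drinking → no/yes, etc.);
- crude odds ratios with Woolf confidence intervals and the
  Haldane–Anscombe zero-cell correction, Pearson χ² and pooled t tests,
  and unconditional logistic regression fitted by iteratively
  reweighted least squares (one integer-scored coefficient per ordinal
  covariate, Wald statistics and OR intervals);
- the additive interaction measures, computed from the stratum odds
  ratios OR01, OR10, OR11 taken against the double-unexposed reference
  stratum:

  | measure | definition | value under additivity |
  |---|---|---|
  | RERI | OR11 − OR10 − OR01 + 1 | 0 |
  | SI   | (OR11 − 1) / ((OR10 − 1) + (OR01 − 1)) | 1 |
  | AP   | RERI / OR11 | 0 |
  | PAP  | RERI / (OR11 − 1) | 0 |

  with both direction rules reported side by side (the sum rule
  OR11 ≷ OR10 + OR01, equivalent to RERI ≷ 1, and the sign of RERI),
  delta-method intervals (Hosmer–Lemeshow covariances from the
  saturated two-factor logistic model) and a stratified case/control
  bootstrap;
- a seeded generator of 1:1 matched case-control cohorts whose control
  exposure distribution and stratum odds ratios — hence the true RERI,
  SI, AP and PAP — are specified exactly, so every stage can be
  validated against ground truth;
- packaged fixtures: the printed 2×2×2 counts of a published
  hypertension case-control study (342 case/control pairs; family
  history crossed with diabetes, drinking, sports, taste, smoking and
  work/life pressure), stored verbatim including their known internal
  inconsistencies, plus `reproduce_study()`, which recomputes every
  stratum OR from the printed counts and flags each discrepancy.

## Worked example

```r
library(interadd)

jt <- study_tables("table2")    # family history x diabetes, printed counts
m  <- analyze_joint_table(jt, ci_method = "delta")
m
#> Additive interaction: family_history x diabetes (table2)
#>   OR10 4.505 (2.814-7.215)   OR01 4.354 (2.029-9.345)   OR11 16.449 (9.549-28.335)
#>   RERI 8.59   SI 2.25   AP 52.22%   PAP 55.60%
#>   direction: sum rule positive, RERI sign positive
#>   95% CI (delta): RERI 1.304 to 15.875; AP 0.272 to 0.773; SI 1.254 to 4.045
```

Reading the output: subjects with both a family history and diabetes
have 16.4 times the odds of hypertension of the double-unexposed, far
above the 4.5 + 4.4 − 1 expected under additive effects; RERI 8.59
(95% CI 1.3–15.9) is the excess joint odds ratio attributable to the
interaction, and AP says 52% of the dual-exposure effect is due to it.
The joint OR printed in the source table itself (16.537) differs
slightly from the value its own counts give (16.449); the from-printed
mode re-derives the source's worked footnote exactly:

```r
interaction_from_ors(or01 = 4.354, or10 = 4.505, or11 = 16.537,
                     footnote_literal = TRUE)[c("ap_pct", "pap_pct")]
#> $ap_pct  52.48
#> $pap_pct 55.86
```

A ground-truth simulation round-trip:

```r
sp <- cohort_spec(control_dist = c(95, 16, 123, 36) / 270,
                  stratum_ors = c(or01 = 4.354, or10 = 4.505, or11 = 16.537),
                  n_cases = 342, n_controls = 342, seed = 20)
cohort <- generate_cohort(sp)      # 684 subjects, 1:1 matched pairs
run_interaction_analysis(cohort, "family_history", "diabetes",
                         ci_method = "bootstrap", reps = 2000, seed = 20)
#> Additive interaction: family_history x diabetes
#>   OR10 4.659 (2.850-7.617)   OR01 5.250 (2.315-11.908)   OR11 21.000 (12.028-36.665)
#>   RERI 12.09   SI 2.53   AP 57.57%   PAP 60.45%
#>   direction: sum rule positive, RERI sign positive
#>   95% CI (bootstrap): RERI 4.142 to 27.026; AP 0.264 to 0.756; SI 1.394 to 4.704
```

At 342 pairs the estimates scatter widely around the truth
(RERI 8.678); the recovery tests in `tests/testthat/` run the same
round trip at 100,000 per arm.

A command-line wrapper over the same functions is installed at
`inst/cli/interadd.R` (`effects`, `interact`, `simulate`, `reproduce`
subcommands), e.g.
`Rscript inst/cli/interadd.R interact --counts 30,22,175,187,95,16,123,36`.

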