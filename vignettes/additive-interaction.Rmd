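---
title: "Additive interaction in case-control data: methods and design"
author: "interadd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive interaction in case-control data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interadd)
```

## The model

Two binary exposures cross-classify a case-control cohort into four
strata; everything in this package is computed from the eight counts of
that 2×2×2 table. Taking the double-unexposed stratum (0,0) as
reference, the three stratum odds ratios are crude ORs of collapsed
fourfold tables:

OR10 = (cases10 · controls00) / (controls10 · cases00), and likewise
OR01 and OR11.

Biologic (additive) interaction is the departure of the joint effect
from the sum of the single-exposure effects. On the risk-difference
scale this is RR11 − RR10 − RR01 + 1; in a case-control design only
odds ratios are identified, so the conventional OR approximation is
used throughout (valid for rare outcomes, an approximation otherwise —
see Limitations):

- **RERI** = OR11 − OR10 − OR01 + 1 — zero under exact additivity;
- **SI** = (OR11 − 1) / ((OR10 − 1) + (OR01 − 1)) — the ratio of the
  joint excess to the summed single excesses, 1 under additivity;
- **AP** = RERI / OR11 — the fraction of the dual-exposure effect
  attributable to interaction;
- **PAP** = RERI / (OR11 − 1) — the same fraction relative to the
  excess (above-baseline) dual-exposure effect.

These satisfy the exact identities AP·OR11 = PAP·(OR11 − 1) = RERI, are
symmetric in the two exposure labels, and RERI is strictly increasing
in OR11 and decreasing in each single OR; the test suite asserts all of
this over randomized OR triples. SI is undefined when the summed
single excesses are zero; that is reported as an undefined-result
signal ("additive effects absent"), never as an infinity, so reports
stay finite.

### Two direction rules, reported side by side

Applied studies often call an interaction "positive" when
OR11 > OR10 + OR01 and "reverse" when OR11 < OR10 + OR01. That
threshold equals RERI > 1, which is *not* the additivity point
RERI > 0 used in the methodological literature; the two verdicts
disagree whenever 0 < RERI < 1. Silently picking either rule would
misrepresent one tradition, so `classify_direction()` always returns
both (`sum_rule` and `reri_rule`), and reports print them together.

## Estimation choices

**Crude OR intervals.** Woolf's log-normal interval,
exp(ln OR ∓ z·√(1/a + 1/b + 1/c + 1/d)) with z = 1.959964 at the
default 95% level. It is the standard large-sample choice for crude
fourfold tables. Tables containing a zero cell get the
Haldane–Anscombe correction (+0.5 to every cell) and the estimate is
flagged `corrected`; this keeps all estimates finite at the price of a
small bias toward the null in tiny tables.

**Interaction intervals.** Two methods are exposed through
`interaction_ci()`:

- *Delta method* (default): the three log stratum ORs are the
  non-intercept coefficients of the saturated two-exposure logistic
  model, whose covariance has the closed form var(b_k) = sum of the
  four reciprocal cells of the collapsed table and cov(b_j, b_k) =
  reciprocal reference cells only; the package evaluates that closed
  form directly (it *is* the saturated-fit covariance — a test asserts
  equality with the IRLS fit's vcov to 1e-5). RERI's interval uses the
  Hosmer–Lemeshow gradient (−e^{b1}, −e^{b2}, e^{b3}); AP's uses the
  delta method on the same parameters; SI's is built on the log scale,
  where its sampling distribution is closer to normal, and is
  undefined when either excess is non-positive.
- *Percentile bootstrap*: cases and controls are resampled separately
  with replacement in exposure-stratum space (multinomial draws of the
  observed arm totals), the measures recomputed per replicate, and
  percentile intervals taken over the defined replicates. Replicates
  with an undefined SI are counted and reported; more than 10%
  undefined raises a warning flag in the result metadata. The seed is
  mandatory and the same seed reproduces the intervals exactly.

Delta is the default for RERI (fast, closed-form, and its coverage is
verified empirically below); the bootstrap is the more defensible
choice for SI and AP, whose delta approximations degrade near the
additivity boundary. Both methods return all three intervals so the
choice stays with the analyst.

**Logistic regression.** `fit_logistic()` is a plain Newton/IRLS
maximum-likelihood fit: convergence when the largest score component
drops below 1e-8 or the largest parameter step below 1e-10, capped at
50 iterations. Ordinal covariates enter as integer scores over their
declared level order (0, 1, 2, …), one coefficient and 1 df per
variable — the structure used in published single-df risk-factor
tables. Wald statistics, OR = exp(B) and exp(B ∓ z·SE) intervals
follow by definition. Rank deficiency is a hard error naming the
collinear columns; fitted probabilities at the 0/1 boundary
((quasi-)separation, where the score vanishes as estimates diverge)
are detected and reported as a non-converged fit rather than a bogus
converged one. The matched design is analyzed *unconditionally*
throughout, mirroring crude/unconditional published analyses;
conditional (pair-likelihood) logistic regression is deliberately out
of scope.

**Other tests.** The 2×2 χ² uses the closed form
N(ad − bc)²/((a+b)(c+d)(a+c)(b+d)) without continuity correction; the
two-sample t test pools variances (Student, df = n1 + n2 − 2), the
natural choice for equal-sized matched arms.

## Rounding and the footnote-literal mode

Point measures are carried at full floating precision; rounding —
half-even, for deterministic cross-platform output — happens only at
rendering: ORs at 3 decimals, RERI and SI at 2, AP and PAP as
2-decimal percentages.

Published worked examples, however, chain *rounded* intermediate
values. `interaction_from_ors(..., footnote_literal = TRUE)`
reproduces that arithmetic for a printed OR triple: the percent
numerator is the two-decimal RERI (exactly as such footnotes write,
e.g. 100·8.68/16.537) and the final percent digit is truncated rather
than rounded — the only arithmetic consistent with every digit of the
packaged study's footnote (full-precision arithmetic differs in the
last PAP digit, 55.85 vs the printed 55.86). The default mode never
does this.

## The synthetic cohort generator

A case-control design identifies only the stratum odds ratios, so the
generator samples directly in exposure-stratum space rather than
simulating a latent disease model: controls are drawn from the
specified control stratum distribution p, cases from the distribution
proportional to p·OR per stratum. This makes the specified ORs exact
population values by construction, and the implied true RERI/SI/AP/PAP
exact in closed form (`true_interaction()`, `expected_tables()` — the
latter feeds the same OR arithmetic as tabulated counts and returns
the specified ORs to 1e-10, the simulation-free oracle used in tests).

Defaults emulate the packaged study's design: 1:1 pair matching with
shared sex and a within-pair age gap of at most 5 years, ages 28–87
(the study's stated range), equal sex ratio. Matching variables are
generated independently of the exposures, so matched and unmatched
analyses agree asymptotically. Determinism is strict: one master seed,
per-arm and per-variable substreams derived from it
(Mersenne-Twister), identical spec ⇒ byte-identical output file.

What the generator does *not* emulate: confounding between matching
variables and exposures, exposure misclassification and recall bias,
missing data mechanisms, correlated exposures beyond the specified
2×2×2 joint distribution, and overmatching. Tests passing on this
generator therefore validate the *estimators and their sampling
behavior under the stated design*, not robustness to those real-data
pathologies.

## Problem sizes and empirical verification

The test suite verifies, among others (sizes chosen to keep sampling
error well below the tolerance being asserted):

- delta-method 95% RERI intervals cover 0 in 93–97% of 1,000
  simulated additive-null cohorts (OR triple 1.5/2/2.5, RERI = 0,
  1,000 per arm) — observed ≈ 95–96%;
- with the packaged study's control distribution and stratum ORs
  (4.354, 4.505, 16.537) as truth, the median estimate over 20
  replicate cohorts of 100,000 per arm recovers OR11 and RERI within
  2% (the single-cohort sampling sd at this size is itself ≈ 1.6–2.2%,
  which is why recovery is assessed on the replicate median);
- a one-binary-covariate IRLS fit equals ln(crude OR) to 1e-6 across
  200 random tables, and recovers a true coefficient of 1.4 within
  ±0.05 at n = 50,000;
- the measure identities and symmetries hold across 1,000 random OR
  triples at 1e-9 or better.

## Degenerate inputs and tie-breaks

- All-zero fourfold table, empty cohort, identical exposure pair:
  domain errors.
- Zero cells anywhere in a joint table: block Haldane correction
  (+0.5 to all eight cells) before the delta method, per-collapsed-
  table correction inside `crude_or()`; both flagged.
- OR11 = 1: PAP undefined (signal, not error). Summed single excesses
  zero: SI undefined.
- Sum-rule ties (OR11 exactly OR10 + OR01) classify as `additive`;
  RERI exactly 0 classifies as `none`.
- Records missing a variable are excluded from analyses of that
  variable only, with exclusion counts logged; missingness is never
  imputed.

## Known limitations

- OR-based RERI approximates the risk-scale RERI; with control
  exposure prevalences as high as in the packaged tables the
  approximation is coarse. This is inherent to case-control data, not
  an implementation choice.
- The unconditional analysis of a matched design is valid here because
  the generator draws matching variables independently of exposures;
  on genuinely confounded matched data, conditional logistic
  regression (out of scope) would be required.
- Delta intervals for SI misbehave when an excess is near zero; use
  the bootstrap there.
- The packaged printed tables contain internal inconsistencies
  (`subset(study_tables(), !consistent)`); the package stores them
  verbatim, reproduces what is reproducible, and flags the rest —
  `reproduce_study()` documents each discrepancy instead of correcting
  it.
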