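---
title: "Operationalizing DSM-5 eating-disorder diagnoses: rules, cohort simulation, and the inferential protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operationalizing DSM-5 eating-disorder diagnoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edclassify)
```

## The problem

DSM-5 reorganized the eating disorders: thresholds for anorexia nervosa (AN)
and bulimia nervosa (BN) were lowered, binge eating disorder (BED) became a
formal diagnosis, and the old residual category EDNOS was replaced by named
"other specified" sub-syndromes — atypical anorexia (AAN), sub-threshold
BN/BED, purging disorder (PD) — plus an undefined "unspecified" remainder
(UFED). Whether these categories are clinically distinct is an empirical
question that can only be asked once the criteria are operationalized
against item-level clinical data: structured-interview symptom flags,
28-day questionnaire behavior counts, and anthropometry.

This package implements that operationalization as an auditable rule
engine, a synthetic cohort generator calibrated to a large Swedish
specialist-care cohort (2233 adult women, baseline and 12-month follow-up),
and the inferential battery used to compare the resulting groups. The
analyses under `analysis/` run the full sequence; everything they do is a
package function with tests.

## The diagnostic rules

`evaluate_criteria()` maps each record to a criteria table. Two data
sources feed it, with a strict priority:

* interview flags encode the DSM-IV convention — "regular" means at least
  twice weekly for three months;
* the questionnaire asks only about the last 28 days, so the lower DSM-5
  once-weekly criterion is granted by fallback when the 28-day count
  reaches 4 (4 weeks x once weekly) **and** the interview flag is absent.
  Provenance (`interview` / `edeq_fallback`) is recorded per criterion.

The duration half of the DSM-5 frequency criteria is unverifiable from a
28-day instrument; the fallback therefore establishes frequency only, which
is the honest ceiling of these data.

`diagnose_dsm5()` applies the eight formal category predicates in a
configurable precedence and assigns the first that passes; records passing
none are `UFED` if they meet the EDNOS-Other minimal-symptom rule (at least
one psychological symptom plus at least one behavioral or physical symptom)
and `NONE` otherwise. Key operationalization choices:

* **"Significantly low weight"** is BMI < 18.5 throughout, the same cut
  that excludes underweight patients from PD (BMI > 18.5 required there).
* **AAN's "significant weight loss"** is unobservable in cross-sectional
  records. The surrogate is: the AN psychological criteria, overt
  restrictive/compensatory behavior, and BMI >= 18.5. This makes a
  purge-only patient with anorexic psychopathology satisfy *both* the PD
  and AAN rules; the engine resolves the overlap purely by precedence. The
  default order puts PD before AAN because the PD definition is complete
  while the AAN surrogate is not; `precedence_sensitivity()` quantifies how
  the PD group drains (to near zero) when AAN is defined first.
* **DSM-IV rules** (`diagnose_dsm4()`) retain amenorrhea for AN and the
  twice-weekly interview threshold for BN. They exist for two jobs: gating
  the questionnaire fallback and defining remission.
* **Remission** at follow-up = no DSM-IV-level diagnosis *and* no
  EDNOS-Other residue. About a third of patients without a formal diagnosis
  still carry a symptom pair, so the second clause matters.

One property of the rules worth stating plainly: symptom monotonicity does
*not* hold in general. A BED-pattern record with no psychological symptom
that gains a regular compensatory flag loses BED (exclusion criterion),
fails BN (which requires undue influence of weight/shape on
self-evaluation), and fails EDNOS-Other (which requires a psychological
symptom) — it drops to `NONE`. This is a feature of the operationalization
itself, not an implementation accident; the property tests assert the
restricted form that does hold (adding a psychological symptom never
demotes a formal diagnosis to `NONE`).

The engine is verified against a brute-force truth-table oracle on all
2^14 interview-flag combinations at BMI levels 16, 20, and 31.

## The synthetic cohort generator

The generator's defaults are the reference cohort's published summaries:
the diagnosis mixture (16.3% restrictive AN ... 8.2% PD, 3.2% UFED),
per-group score means/SDs, per-group behavior report rates and mean 28-day
frequencies, Axis-I comorbidity rates, and the 12-month transition matrix
(row proportions of the stability/cross-over counts). Design choices where
the sources are silent:

* **Scores** are truncated normals per group, truncated to instrument
  ranges (questionnaire scales 0-6, impairment 0-48, psychiatric index
  0-3). Published per-group moments exist only for the global eating-
  pathology score; subscales inherit the global parameters. Scales are
  drawn independently given the label; real within-group correlations
  among scales are not emulated (and nothing downstream here depends on
  them).
* **Behavior counts** are Bernoulli presence at the group's report rate,
  with truncated-Poisson counts centered on the group's mean reporter
  frequency, hard-capped at 56 (about twice daily).
* **Defining vs free indicators.** Each label fixes the indicators its
  rule requires or forbids; everything else is free. Symptom noise
  (default 5%) flips only free indicators, and counts that would trip a
  higher-precedence rule through the weekly fallback are capped at 3 per
  28 days. Consequence: the engine recovers the latent label for 100% of
  records, with or without noise — the deliberate price is that, e.g., the
  PD group's generated binge counts sit below the (self-report-inflated)
  printed mean, since a PD record with 4+ objective binges per month would
  be reclassified as BN by the engine's own fallback rule. Ground-truth
  recoverability was chosen over matching those means.
* **Sub-threshold BED** has no published score/transition rows of its own
  and inherits BED's; blank frequency cells are filled with small positive
  rates.
* **Follow-up** draws each retained patient's state from their true
  label's transition row; remission produces a symptom-free record with
  restored weight (BMI >= 18.6) and sub-clinical scores, which by
  construction fails both the DSM-IV and EDNOS-Other rules. Attrition is
  completely at random at a configurable retention (default 23.7%, the
  reference cohort's complete-follow-up fraction); real attrition
  mechanisms are not modelled.

What passing generator-recovery tests shows: the rule engine and generator
agree on the criteria semantics, and empirical mixtures/transition rows
converge at binomial rates. What it does not show: fidelity of the
generator to real patients beyond the published group-level margins.

## The inferential protocol

* **Outliers** (`cap_and_gap_delete()`): frequency variables are first
  capped at a pre-defined plausible maximum, then z-transformed per
  diagnostic group; the top value (with ties) is deleted when it lies more
  than 1 SD above the next highest distinct value, repeating until no such
  gap remains. Groups under 3 observations or with zero variance are left
  alone.
* **Continuous comparisons**: classical one-way ANOVA with partial eta
  squared (anchors 0.01/0.06/0.14), or Welch's ANOVA when the
  Brown-Forsythe Levene test is significant at 0.05 *and* the smallest
  group has n < 30 (the trigger is configurable and can be forced either
  way). Post hocs are Scheffé (pooled error, conservative over all
  contrasts) or Games-Howell (pairwise variances, Welch-Satterthwaite df,
  studentized-range reference) respectively.
* **The dual gate**: a pairwise contrast is reported only when p < 0.01
  *and* |Cohen's d| >= 0.50 (pooled-SD d). With seven groups of the
  reference sizes under a global null, the familywise false-report rate of
  the whole gated pipeline is essentially zero — the d-threshold is the
  binding constraint at these ns.
* **Categorical data**: Pearson chi-square without continuity correction,
  standardized residuals (O-E)/sqrt(E), Cramér's V / phi with the
  Rea-Parker magnitude bins (<0.10 negligible up to >=0.80 very strong).
  Pairwise 2x2 decompositions run at alpha 0.001, substituting Fisher's
  exact test when any expected cell is below 5. Groups for which a
  behavior is itself criterion-relevant are omitted from that behavior's
  omnibus (binges: restrictive AN and PD; compensatory behaviors: BED and
  restrictive AN), which is why the reference chi-squares have 4 df.
* **Change**: residual gain scores — residuals of follow-up regressed on
  baseline, fitted on the pooled sample so group differences in change
  survive — then the ANOVA machinery above. **Reliability**: Cronbach's
  alpha.

Display percentages round half-up to integers (raw proportions are always
retained in machine output); the migration headline is the *unweighted*
mean of per-row percentages, the convention that reproduces the reference
arithmetic, with destinations UFED and AAN excluded by default as
partial-remission way-stations rather than true diagnostic change.

## Numerical and reproduction notes

* All randomness flows from the single config seed; identical config gives
  byte-identical cohorts and report bundles.
* The reference chi-squares (binges 133.94, vomiting 340.79, laxatives
  64.52, diuretics 17.11, mood 79.31, substance use 30.50) reproduce to
  two decimals from the printed counts with full-sample group denominators.
  The composition and follow-up arithmetic (PD = 8.2% of cohort, 32% of
  the residual group, PD+AAN+SubBED = 88%; PD remission 44%, cross-over
  41%; migration mean 14%, range 4-25%) reproduce under the half-up
  rounding convention. The residual-group denominator includes UFED —
  required to reproduce 32%/88%.
* Two printed figures do not reconcile exactly with their own table: the
  all-destinations migration mean computes to ~40% against a printed
  "on average 39%", and one anxiety row total prints 365 against cells
  summing to 356. The tables are taken as authoritative; nothing is forced.
* Problem sizes used by the checks: the truth-table oracle runs the full
  49,152-point grid; generator-recovery runs at n = 5000; the null
  calibration of the gated pipeline uses 1000 replicates at the reference
  group sizes (total n = 2222 per replicate).

## Limitations

The interview item dictionary is a reconstruction of a proprietary
instrument's content; the generator emulates published margins, not joint
distributions; attrition is random; and the sub-weekly duration criterion
for sub-threshold syndromes is not enforced (unverifiable at 28-day
horizon). Group means of the continuous scales on synthetic cohorts match
the reference only in structure — the real item-level database is not
public, and nothing here claims to reproduce its Table-level means beyond
the generative parameters it was given.
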