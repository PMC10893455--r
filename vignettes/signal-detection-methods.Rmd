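---
title: "Disproportionality signal detection for spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous-reporting systems collect individual case safety reports
(ICSRs): unsolicited reports that a patient taking certain drugs
experienced certain adverse events. Reporting is biased, denominators
(how many patients took the drug) are unknown, and events are coded, not
adjudicated. Disproportionality analysis works *within* the database: it
asks whether the drug of interest's reports mention an event more often
than the remaining reports do. A disproportion is a statistical alert — a
*signal* — not proof of causation.

`pvsignal` packages this workflow around a concrete case study: the risk
of acute central respiratory depression (ACRD) under tramadol, a weak
μ-opioid agonist widely perceived as safe. ACRD is defined by the
narrow scope of the corresponding Standardised MedDRA Query: 19 preferred
terms from "apnoea" to "respiratory rate decreased"
(`builtin_acrd_smq()`). A report is a case when it carries at least one
of these terms; a report carrying several still counts once.

## The model

For an index drug and an event definition (a single preferred term or a
whole SMQ), reports are cross-classified into the 2×2 table with cells
A (drug and event), B (drug, no event), C (event, no drug), D (neither).
Three conventions matter and are fixed throughout:

* the counting unit is the **report**, never the drug–event entry;
* the index drug's reports are those listing it with role *suspected* or
  *interacting* — concomitant mentions do not make a report a drug
  report;
* the comparator (C and D) is either every remaining report
  (`scope = "full_database"`) or, to benchmark a weak opioid against the
  class, the remaining reports containing a drug with ATC code `N02A*`
  or `N01AH*` (`scope = "opioids"`). The index drug's own entries are
  excluded when deciding comparator membership, the standard case/non-case
  practice; the source study does not state its choice, so this default
  is ours and is switchable (`exclude_index_from_comparator`).

The statistics are the three in routine regulatory use:

* `PRR = [A/(A+B)] / [C/(C+D)]`, the ratio of event shares;
* `ROR = (A/B) / (C/D)`, the ratio of reporting odds — in large sparse
  databases numerically almost identical to the PRR (the reconstruction
  tests assert `|ROR − PRR| < 0.02` at the published scale);
* `IC = log2((A + 0.5)/(E + 0.5))`, `E = Ndrug·Neffect/Ntotal`, the
  Bayesian information component. The 0.5 offsets keep IC finite at
  A = 0 (and make `IC = 0` exactly when nothing is observed and nothing
  expected).

Interval bounds: PRR and ROR get 95% log-scale Wald intervals with the
usual standard errors; when a cell is zero the ROR interval uses the
Haldane +0.5 correction and the point estimate is reported missing. For
the IC's lower 95% credibility bound we default to the published
closed-form approximation `IC − 3.3(A+0.5)^{−1/2} − 2.0(A+0.5)^{−3/2}`;
an exact gamma-quantile bound (2.5% quantile of the
`Gamma(A+0.5, E+0.5)` posterior on the observed-to-expected ratio) is
selectable. On tables reconstructed from the published study the
approximation agrees with the printed IC025 to at most 0.06 bits, which
is the tolerance the consistency tests assert.

A pair is flagged as a signal only when **all** criteria hold:
`A ≥ 3`, `PRR ≥ 2`, `ROR ≥ 2`, `IC025 ≥ 0` (`signal_criteria()`). Pairs
with fewer than three reports are listed but can never be signals.
Age-stratified screens (`stratified_signals()`) re-run the identical
computation on the sub-database of an age stratum, always excluding
unknown-age reports from the stratum.

## Reconstruction of published tables

The real database (23.8 million reports) is access-restricted, so exact
reproduction of the published comparator cells is impossible. The
package instead ships the printed summary tables
(`reference_totals()`, `reference_demographics()`, `reference_disprop()`,
`reference_factors()`) and back-solves the one unknown cell: given the
printed report count A and PRR, `C = round(A/Ndrug · (Ntotal−Ndrug)/PRR)`
(`reconstruct_contingency()`). Re-running the full statistics on the
reconstructed tables reproduces every printed PRR exactly at display
precision, ROR within ±0.01, IC025 within ±0.06 bits, and — decisive for
the study's conclusion — flags exactly the five published signal terms
for tramadol (respiratory arrest, respiratory depression, bradypnoea,
hypoventilation, respiratory rate decreased; 882 reports in total) and
only bradypnoea for the tramadol/paracetamol combination.

Two verbatim inconsistencies of the source are preserved and documented
rather than silently corrected: the reporter counts of the demographic
table do not sum to the report total (their percentages do sum to 100,
and the preset uses the percentages), and the non-case reporter
percentages of the factor table use the before-exclusion denominator
while the case column uses the after-exclusion one. The printed
opioid-scope columns cannot be reconstructed at all because the size of
the opioid report universe is not given; the opioid scope is therefore
validated against synthetic data instead.

## Factor analysis

`build_factor_table()` restricts the database to the index drug's
suspect/interacting reports, splits them into SMQ cases and non-cases
and cross-tabulates against a covariate: sex, the three collapsed age
strata (≤17, 18–64, ≥65), region, reporter, death, an event-defined flag
(drug abuse via the "drug abuse and dependence" SMQ), or concomitant use
of a drug class. Reports with an unknown demographic category are
excluded before testing and their count is retained. Association is
tested by Pearson chi-square without continuity correction; for factors
with at least three categories a post hoc step computes adjusted
standardized Pearson residuals per category and flags them two-sided at
a Bonferroni-corrected level `α/(2k)`. The residual method is our
choice — the source names the post hoc step but not the method — and it
is cross-checked in tests against the standard `chisq.test()$stdres`.
For two-level factors the chi-square already localizes the effect, so
post hoc is marked not applicable; we apply it at k ≥ 3, which includes
the three-level age factor.

Effect sizes are summarized as proportion ratios (case share divided by
non-case share, the convention of the source's discussion: mortality
20.7% vs 2.4% gives the "8.6 times" figure) and, for binary factors, as
odds ratios with Wald intervals.

Concomitant-medication factors are restricted to class members
co-reported with the index drug in **strictly more than** `min_cases`
reports (default 20, a verbatim reading of the source's "more than 20
cases"). The CYP2D6-inhibitor, benzodiazepine, opioid and antidepressant
class lists, like the abuse SMQ, are configuration files with documented
defaults (`default_drug_classes()`, `default_abuse_smq()`): MedDRA and
WHODrug license restrictions mean the exact study lists cannot be
shipped, so the defaults cover the commonly cited members and are
user-replaceable (`read_drug_class_file()`, `read_term_file()`). The
abuse flag requires the abuse term on the same report as the index drug;
spontaneous reports carry no patient linkage, so a patient-level
definition is not expressible.

## The synthetic-report generator

`generate_reports()` draws reports independently under a transparent
generative model: per-drug Bernoulli exposures, per-term Bernoulli
events whose probability on reports carrying an injected drug is
multiplied by a configured relative risk (capped at 1), categorical
demographics, optional co-medication (extra conditional probability of a
co-drug given the index drug, combined by union with the marginal draw),
per-drug role distributions, and death from a multiplicative odds model
over the report's terms, with fatal reports forced to serious.
Two pragmatic guarantees shape the marginals slightly: every report gets
at least one drug and one event (a fallback entry sampled proportionally
to the catalog when the Bernoulli draws leave a report empty — realistic
catalogs with a common background drug/event make this rare), and
seriousness is post-adjusted by death, so the calibration tests check
the directly sampled fields.

Design choices: sampling is fully vectorised from a single seeded stream
with a fixed draw order (demographics, drugs, co-medication, events,
roles, death), which makes generation a pure function of the
configuration and seed — the determinism tests assert byte-identical
line listings — and is far faster in R than per-report sub-streams.
Events are conditionally independent given the drugs; no within-report
event correlation exists beyond the injections. This is deliberately the
simplest model that exercises 2×2 counting, and it is also the model's
main limitation: real reporting databases have duplicate reports,
correlated event clusters, reporting-delay dynamics and
drug-demographic confounding that the generator does not emulate, so
passing calibration tests validates the *estimators*, not the realism of
any particular synthetic database.

`tramadol_study_preset()` encodes the study conditions at reduced scale:
100,000 reports by default, tramadol on ≈0.6% of them (the published
exposure share), demographic marginals equal to the published strata of
the tramadol report population (60.9% female, 61.3% from Asia, …),
background rates for the 19 ACRD terms derived from the published
comparator counts, relative risks on the tramadol–ACRD pairs set to the
published disproportionality levels (so all five signal terms have
RR ≥ 2), stronger injected risks on the comparator opioids (so the
opioid scope correctly shows no tramadol signal), co-medication for the
four factor classes, elevated abuse-term reporting on tramadol, an
under-18 multiplier of 3 on the respiratory terms (the paediatric
enrichment), and death-odds multipliers concentrated on the respiratory
terms. Seriousness is a free marginal (0.45) because the published
percentage has no stated denominator. At this scale the per-term ACRD
counts on tramadol reports are small — single digits for most terms —
so a preset run typically recovers only the strongest association;
recovery guarantees are tested with dedicated configurations where the
expected cell count is ≥ 20.

## Numerical conventions and problem sizes

Computation is in full double precision; display rounds half-up, two
decimals for ratios, one for percentages (the convention of regulatory
tables — base R's `round()` rounds half to even, hence
`round_half_up()`). Degenerate inputs are defined, not fatal, wherever a
value is reportable: a drug absent from the database yields a zero
table with missing ratio estimates, `IC(0 observed, 0 expected) = 0`, a
zero comparator cell reports a missing PRR; hard errors are reserved for
undefined inputs (no drug reports at all, zero chi-square margins,
factors with fewer than two non-empty categories) and for malformed
line listings (conflicting demographics for a report, unknown enum
tokens), which abort with the offending report or row named.

The validation suite sizes are chosen to keep the full run in tens of
seconds on one core while leaving comfortable statistical margins:
brute-force oracle equivalence on twenty databases of 1,000–2,000
reports; null calibration and recovery on twenty seeds of 20,000
reports (≈840 null pairs with expected counts ≥ 3; sixty injected pairs
with expected counts ≥ 20); chi-square size on 200 null tables of 2,000
reports; goodness-of-fit of the generator marginals at 50,000 reports
per seed. The acceptance script re-runs the same checks from scratch
plus the full reconstruction of the published tables.
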