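---
title: "Disproportionality screening for drug-associated acute kidney disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening for drug-associated acute kidney disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(akdsignal)
```

## The problem

Spontaneous adverse-drug-reaction (ADR) reporting systems collect millions of
notifications, each naming one or more suspected drugs and one or more reaction
terms. For a phenotype such as acute kidney disease (AKD) — an acute functional
or structural kidney insult arising within about three months of exposure —
the screening question is: *which drugs appear in AKD reports more often than
their overall reporting volume would predict?* This package implements that
workflow end to end: a notification data model, a preferred-term case
definition, report-level 2×2 contingency tables, two disproportionality
statistics with a two-stage screen, a bibliographic nephrotoxicity score, the
descriptive tables such studies publish, and a synthetic report generator that
makes every stage testable without access to a proprietary database.

## The data model

A notification is one deduplicated report: a unique id, receipt year, sex, an
ordered age bin (`r paste(AGE_GROUPS, collapse = ", ")`), at least one drug
entry (normalized active-ingredient name, optional first-level ATC letters,
suspected/concomitant role), at least one reaction term, a possibly-empty set
of regulatory seriousness criteria, and a fatal-outcome flag.

Two modelling choices deserve comment:

* **Combination products are single entities.** A fixed-dose combination such
  as *emtricitabine + tenofovir disoproxil* is analyzed as one ingredient
  string, with components sorted lexicographically so that spellings in either
  order compare equal. Attributing component-level risk is a different study
  design and out of scope.
* **Fatal is not "death-serious".** The fatal-outcome flag and the `death`
  seriousness criterion are distinct fields on real report forms, and their
  counts genuinely differ; the model therefore permits `fatal = TRUE` without
  the `death` criterion, and fatal-subset tables use the fatal-outcome count
  as their denominator.

Deduplication is exact content equality on all fields except the report id
(first occurrence kept). Probabilistic record linkage is deliberately not
attempted: without access to the source database's linkage keys any fuzzier
rule would be a guess, so the key is exposed as configuration instead.

## The case definition

A report is an AKD case when at least one of its reaction terms matches, after
lower-casing and whitespace collapsing, one of ten preferred terms: acute
kidney injury, renal failure, renal impairment, blood creatinine increased,
renal injury, blood urea increased, tubulointerstitial nephritis, glomerular
filtration rate decreased, oliguria, anuria. Matching is flat string equality —
no dictionary hierarchy traversal, since the licensed terminology is not
shipped and published case lists name preferred terms directly. Frequently
co-reported terms (dehydration, hypotension, nausea, ...) are descriptive
context and are tabulated separately, never used for case inclusion.

## Disproportionality statistics

For each drug the whole-report 2×2 table is

|            | case event | no case event |
|------------|-----------:|--------------:|
| drug       | a          | b             |
| no drug    | c          | d             |

with N = a+b+c+d. A report "has the drug" when any entry matches the
ingredient under the role filter (default: suspected entries only; including
concomitant medication is a flag). The comparator population is *all reports
in the supplied set* — against a full database extract this reproduces the
classical design, and on a filtered subset the interpretation changes
accordingly and is the user's responsibility.

**Reporting odds ratio.** ROR = ad / bc, with the Woolf (log-normal) interval
$\exp(\ln \mathrm{ROR} \pm z_{1-\alpha/2}\sqrt{1/a + 1/b + 1/c + 1/d})$.
If any cell is zero, 0.5 is added to all four cells (Haldane–Anscombe); with
the correction disabled a zero cell raises an error rather than returning an
unusable estimate.

**Information component.** With expected count E = (a+b)(a+c)/N,

$$\mathrm{IC} = \log_2 \frac{a + 0.5}{E + 0.5},$$

the 0.5 shrinkage damping small-count noise. The screening statistic is the
lower 95% credibility bound
$$\mathrm{IC}_{025} = \mathrm{IC} - 3.3\,(a+0.5)^{-1/2} - 2\,(a+0.5)^{-3/2},$$
the standard closed-form approximation. An exact mode computes the 2.5%
quantile of the posterior Gamma(a+0.5, E+0.5) instead. The deviation between
the two depends only on a; it peaks just below 0.05 log₂ units near a = 20 and
decays slowly, so the modes can disagree about IC₀₂₅ > 0 only for
associations within ~0.05 of the boundary. The approximation is the default
because it is the form most screening pipelines publish. Expected counts are
crude (unstratified); stratification by age, sex or year is a known
refinement not implemented here.

**Two-stage screen.** A drug is flagged when IC₀₂₅ > 0 (strict) *and*
ROR > 1 — the Bayesian bound as the gate, the odds ratio as confirmation.
Results failing the gate are retained with `screened_in = FALSE`: negative
associations are informative and are reported, not hidden. `run_disproportionality()`
drops drugs with a < 3 drug-and-event reports (configurable) to avoid
vacuous signals, and ranks by IC₀₂₅, ties by ROR then name, so output order
is deterministic.

## Bibliographic nephrotoxicity score

Independently of reporting data, each drug can be scored 0–5 by counting in
how many of five predetermined literature sources (two databases, one
website, two reference books) nephrotoxicity evidence is found, and classed
as non-nephrotoxic (0), potentially nephrotoxic (1–2) or known nephrotoxic
(≥3). The package takes the five indicators (or a precomputed score) as user
input — it does not scrape literature — and ships, as reference data, the
scores of 24 drugs prominent in a published worldwide AKD pharmacovigilance
analysis, of which 75.0% class as known nephrotoxic, 16.7% as potentially
nephrotoxic and 8.3% as non-nephrotoxic.

## Percentage conventions

Published tables round percentages half away from zero to one decimal (whole
percentages where the source table prints integers); `pct()` reproduces this
exactly, since validation includes recomputing printed percentages from
printed counts. Single-membership tables (sex, age) sum to 100 within
rounding; multi-membership tables (ATC classes, terms — a report counts once
per class or term it mentions) can sum above 100 and are documented as such.

## The synthetic generator

`generate_reports()` emulates the *structure* of a spontaneous-reporting
database: multi-drug multi-reaction reports, configurable drug/term
catalogs, demographics, seriousness, fatal outcomes, and planted drug–event
associations of known strength.

**Generative model.** Each report includes every catalog drug independently
with its marginal probability, and every catalog term independently with its
marginal probability; draws with no drug or no term are redrawn, i.e. the
report is conditioned on being nonempty. A planted signal multiplies the
*odds* of each of its event terms by λ in reports containing its ingredient.
Independent-inclusion-with-odds-multiplication was chosen over drawing
per-report item counts from an explicit distribution because it makes the
truth analytic: the implied report-level odds ratio of a single-term signal
equals λ exactly up to the nonemptiness conditioning (a <0.1% effect at
default intensities), and `true_tables()` returns exact cell probabilities by
enumerating the joint presence states of all signal drugs. Per-report item
counts then follow a conditioned Poisson–binomial law controlled through the
catalog marginals — at the default intensities reports average roughly 1–2
drugs and 1–2 reactions, resembling real notification tables. The
conditioning means *realized* per-item marginals are the configured ones
scaled by 1/(1 − P(empty)); tests compare empirical frequencies against
these implied values in closed form.

**Defaults.** The default catalog holds 20 drugs (proton-pump inhibitors,
antivirals, antibiotics, diuretics, NSAIDs, immunosuppressants; inclusion
probabilities 0.008–0.05) and 18 terms (the ten AKD terms at 0.001–0.02 and
eight common co-reported reactions at 0.07–0.12, so kidney terms are a small
minority of the background, as in real systems). Sex, age-bin, year,
seriousness and fatal-outcome distributions default to values resembling
published AKD case series (e.g. 49.5% male, fatal share 13.7%, a 2019
reporting peak). These defaults were fixed once when the generator was
designed.

**Reproducibility.** One integer seed controls the whole draw; the draw
order (drug matrix, term matrix, then demographics, seriousness, fatal) is
part of the contract, and the same seed gives bit-identical serialized
output. `simulate_contingency()` re-runs only the matrix stage of the same
draw to tabulate 2×2 cells cheaply in replicate studies; on a shared seed it
is cell-for-cell identical to `build_table()` applied to the assembled
report set, and a test asserts that equality.

**What passing tests do and do not show.** The generator has no
co-prescription structure, no term–term correlation beyond shared marginals,
no reporting-trend dynamics beyond the year marginal, and no duplicate
mechanism other than coincidental identity. Calibration and power results on
this background therefore validate the *statistical machinery* —
formulas, counting, gating, determinism — not robustness to confounding,
masking or reporting biases of real pharmacovigilance data.

## Operating characteristics

The test suite measures, on the synthetic background:

* **Null calibration** — with all λ = 1 at n = 50,000, the IC₀₂₅ > 0 gate
  fires for at most 5% of drugs with expected count ≥ 5 (200 replicates).
* **Power** — a λ = 10 signal on a drug with marginal 0.01 and an event term
  with marginal 0.02 is screened in at n = 20,000 in ≥95% of 100 replicates.
* **Recovery** — the median estimated ROR is within 10% of λ for
  λ ∈ {2, 5, 10} at n = 50,000.

The analysis scripts under `analysis/` run the same studies at reduced
replicate counts as a narrated walkthrough; these problem sizes are the
package's chosen validation scale.

## Numerical and degenerate-input choices

* Zero cells: ROR applies the 0.5 correction (or errors if disabled); IC
  needs no correction for a = 0 but errors on a zero margin (n_drug, n_event
  or N), where it is undefined.
* An ingredient absent from the report set yields a valid a = b = 0 table;
  downstream statistics then refuse the zero margin rather than silently
  producing infinities.
* Rounding is half away from zero, implemented with a 10⁻⁹ nudge so that
  binary-float representations of exact halves (e.g. 6.25 stored a hair low)
  still round up.
* Ties in every ranked table break lexicographically, making all outputs
  deterministic.
* `read_reports()` maps unrecognized sex/age values to `"unknown"`, drops
  unrecognized ATC letters with a warning, and treats a missing mandatory
  column as a schema error but an empty file as an empty set with a warning.

## Known limitations

Crude (unstratified) expected counts; exact-match deduplication only; no
dictionary hierarchy (term lists are flat); single-database comparator
semantics (the background is whatever report set you supply); the
bibliographic score is user-supplied evidence, not automated literature
search. Printed disproportionality values from proprietary-database studies
cannot be reproduced without that database and are shipped only as reference
data for formatting and classification.
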