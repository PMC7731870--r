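# csqca — crisp-set configurational analysis of implementation conditions

`csqca` is an R package for crisp-set qualitative comparative analysis
(QCA) and coincidence-analysis style workflows in small-N implementation
research. It answers questions of the form: *across a couple of dozen
sites, which combinations of implementation conditions link to a
successful outcome?* — where "link" is Boolean, not correlational. It is
aimed at health-services and implementation-science researchers working
with case-level condition/outcome tables.

The packaged worked example is the analytic dataset of a nursing-facility
demonstration project: 19 facilities, their all-cause hospitalization
rates per 1,000 eligible resident days before and during a multicomponent
clinical intervention, two binary improvement outcomes (relative decline
≥ 10% and ≥ 20%), and four crisp implementation conditions (director-of-
nursing turnover, senior-management support, low-baseline-rate quartile
membership, resident acuity).

## What it computes

For a condition or model X and outcome Y over the case set:

* consistency `n(X ∧ Y) / n(X)` (consistency 1 ⇔ X sufficient for Y),
* coverage `n(X ∧ Y) / n(Y)` (coverage 1 ⇔ X necessary for Y),

and on top of these: enumeration of **minimally sufficient conditions**
(all 1–4-literal conjunctions instantiated in the data, under a
consistency cutoff stepping down from 100% in 5% decrements), **truth
tables** over crisp factor subsets, **Quine–McCluskey minimization** with
exhaustive irredundant-cover (Petrick) enumeration — parsimonious
(remainders as don't-cares) or conservative — **unique-coverage pruning**
of solution paths, dual-outcome **selection criteria** (consistency ≥ 80%,
coverage ≥ 80%, unique coverage ≥ 15% per path, no model ambiguity, same
factor set across outcomes), path-partition summaries, and a
**synthetic-data generator** with a planted Boolean ground truth for
validating the whole pipeline.

## Worked example

```r
library(csqca)
ct <- optimistic_facilities()

consistency(conjunction(don_turnover = 1), ct, "decline10")
#> [1] 1                       # all 9 facilities with DON turnover improved

report <- develop_models(
  ct, c("decline10", "decline20"),
  list(decline10 = c("don_turnover", "support", "low_baseline"),
       decline20 = c("don_turnover", "support", "low_baseline", "chess")))
cat(render_report(report, "text"))
```

prints, for the 10% outcome:

```
  solution: ~low_baseline*support + don_turnover -> decline10
  in plain language: not LOW_BASELINE AND SUPPORT; OR DON_TURNOVER
  consistency 13/13 = 100%; coverage 13/15 = 87%
  partition of the 15 outcome cases: 4 / 5 / 4 with 2 uncovered (10, 13)
```

i.e. two solution paths — senior-management support combined with a
higher-rate baseline, or turnover in the director of nursing — jointly
account for 13 of the 15 improving facilities (87% coverage) with no
covered facility failing to improve (100% consistency); 4 facilities are
on the first path only, 5 on the second only, 4 on both, and 2 are
unexplained. For the 20% outcome the same run prints the four-condition
solution `~low_baseline*support + chess*don_turnover` with consistency
11/11 = 100%, coverage 11/13 = 85% and partition 6 / 3 / 2 with 2
uncovered.

The numbered scripts under `analysis/` narrate the full workflow —
`01_outcomes.R` (derive the binary outcomes from the raw rate pairs),
`02_data_reduction.R` (msc enumeration and candidate factors),
`03_models.R` (model development and reporting), `04_synthetic_validation.R`
(planted-model recovery) — and write their tables under `results/`.

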