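---
title: "Crisp-set configurational analysis with csqca: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crisp-set configurational analysis with csqca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csqca)
```

## The problem and the model

`csqca` implements crisp-set configurational analysis for small-N
cross-case studies: given a handful of cases (here, 19 nursing facilities
in a hospitalization-reduction demonstration project), each described by
binary ("crisp") implementation conditions and one or more binary
improvement outcomes, it searches for Boolean combinations of conditions
whose joint presence links to the outcome. The search target is a *minimal
theory*: a disjunction of non-redundant conjunctions (solution paths) such
that each path is sufficient for the outcome and no literal can be dropped.
This is Boolean algebra, not linear algebra — the result is a statement like

    support * ~low_baseline  +  don_turnover  ->  decline10

("senior-management support AND not in the low-baseline quartile; OR
turnover in the director of nursing"), not a coefficient vector.

Two set-theoretic quantities grade any candidate condition or model against
the data. For a condition (or model) X and outcome Y:

* **consistency** = n(X ∧ Y) / n(X) — of the cases exhibiting X, the share
  that exhibit Y. Consistency 1 operationalizes sufficiency.
* **coverage** = n(X ∧ Y) / n(Y) — of the outcome cases, the share that
  exhibit X. Coverage 1 operationalizes necessity.

Per solution path we additionally report **raw coverage** (outcome cases on
that path) and **unique coverage** (outcome cases on that path and on no
other), whose counts form the path-partition summary (the numbers a
solution Venn diagram would display).

## The two-stage procedure

**Stage 1 — data reduction** (`enumerate_msc()`, `reduce_factors()`).
Every conjunction of 1–4 literals over the declared factors that is
instantiated in the data is tested against a consistency cutoff that starts
at 100% and drops in 5% decrements until at least one conjunction
qualifies. A qualifying conjunction is kept only if *minimally* sufficient
— no proper sub-conjunction also meets the cutoff — and survivors are
ranked by coverage. Crisp factors contribute presence and negation
literals; multivalue factors one literal per level. The substantive
narrowing of candidate factors ("logic, theory, and prior knowledge" in the
original studies) is deliberately not automated: `reduce_factors()` derives
candidates from the top-ranked configurations but accepts an explicit
allow-list, which is how the packaged analysis pins the published subsets.

**Stage 2 — model development** (`build_truth_table()`, `minimize()`,
`prune_terms_by_unique_coverage()`, `develop_models()`). Cases are grouped
into truth-table rows by their exact configuration over the chosen factor
subset. A row is output 1 when its own consistency meets the row threshold,
output 0 otherwise, and unobserved configurations are *remainders*. The
output-1 rows are then minimized by classic two-level logic minimization:
prime implicants via iterated adjacent merging (Quine–McCluskey), followed
by exhaustive enumeration of the irredundant covers (Petrick's method).
All covers with the fewest terms, then the fewest total literals, are
returned; more than one is *model ambiguity*. Terms whose unique coverage
falls below 15% are pruned and the metrics recomputed; models that coincide
after pruning merge, which is also how the packaged 20%-outcome analysis
resolves its pre-pruning ambiguity into the single published model. A model
qualifies when it meets the selection criteria (defaults: consistency ≥
80%, coverage ≥ 80%, unique coverage ≥ 15% per term, no ambiguity), and a
two-outcome run additionally requires the two models' factor sets to agree.

## Design choices that were genuinely open

* **Contradictory rows are output 0, never don't-cares.** A row observed
  with both positive and negative cases is evidence against sufficiency; on
  the packaged data this is what correctly excludes the configuration
  shared by facilities 13 and 19 from the 20% solution.
* **Parsimonious is the default strategy.** Parsimonious minimization may
  use remainders as don't-cares; conservative minimization merges output-1
  rows only and therefore never implies an unobserved configuration. The
  packaged 20% solution's acuity path implies one unobserved configuration
  and so is reachable only parsimoniously; which variant the original
  analysis used is not recorded, so both are exposed and the default is the
  one that reproduces both published models.
* **The threshold schedule lowers only while the truth table is
  unworkable** (no output-1 row, or a tautological solution). A model that
  exists but fails the selection criteria is a terminal rejection: lowering
  the consistency demanded of rows in order to rescue a rejected model
  would conflate two different analytic decisions, and the recorded
  attempts make the rejection auditable instead.
* **Dual-outcome factor agreement is nested by default.** The published
  pair uses three factors for the 10% outcome and those three plus acuity
  for the 20% outcome; `same_factors = "nested"` accepts exactly this,
  `"exact"` is available for stricter designs.
* **Deterministic presentation order.** Within a model, paths are ordered
  by literal count (more specific first), then raw coverage, then formula;
  msc rankings break coverage ties by fewer literals, then alphabetically.
  These tie-breaks are conventions of this implementation, chosen once so
  that reports are byte-stable.
* **Decline thresholds are inclusive** (≥ 10%, ≥ 20%): a facility whose
  rate fell by exactly the threshold achieves the outcome, which is the
  coding the analytic table itself uses (e.g. the facility with a 10.8%
  decline is coded as achieving the 10% outcome).
* **Quantile dichotomization interpolates at rank (n−1)q + 1** (R's
  default type-7 quantile). On the 19 baseline rates this cutoff (1.4305
  per 1,000 resident days) reproduces the printed low-baseline-quartile
  column exactly; a count-based floor(n/4) rule would not.

## Numerical conventions

Fractions are carried exactly as counts and only rounded for display (87%
is 13/15). Threshold comparisons use a 1e−9 tolerance so that a row with
consistency 0.8 passes a 0.80 cutoff regardless of floating-point
representation. Missing cells, out-of-domain levels and duplicate case ids
are hard errors with classed conditions (`csqca_schema_error`, …); there is
no imputation. Degenerate situations — a constant series sent to
dichotomization, a conjunction satisfied by no case, a truth table whose
minimization is a tautology — raise classed errors rather than returning a
misleading 0 or 1, and the pipeline records them as rejection reasons.

## What the synthetic generator emulates — and what it does not

`generator_spec()`/`generate_case_table()` produce tables with the
structure the analysis assumes: a planted DNF ground truth over crisp
factors, inert noise factors topping the mix up to the original roster of
six dichotomous plus five multivalue factors (three levels each, a choice
made once for realism at this scale), and around 19–24 cases. Outcome
noise is an independent flip of the outcome label with probability ε —
condition values stay exact, matching the crisp-set setting in which
measurement error manifests as outcome misclassification. Optional rate
emission draws baseline rates from a lognormal spread matching the packaged
data (≈0.7–4.4 events per 1,000 resident days) and encodes the outcome in
the relative decline, so the outcome-derivation path is exercised end to
end. Sampling is uniform, weighted, or "balanced" (every planted-factor
configuration observed at least once), and everything is reproducible from
the seed.

`recovery_experiment()` wraps this into a validation harness: with ε = 0
and full configuration coverage the parsimonious pipeline provably returns
a model logically equivalent to the planted one (no remainders, no
contradictions, and two-level minimization preserves the function), and the
suite verifies exact recovery across replicates; with growing ε the
exact-recovery rate must not increase. The replication counts used by the
packaged validation (20 noiseless replicates; 100 replicates per noise
level at ε ∈ {0, 0.1, 0.2}; 200 random tables for the brute-force msc
cross-check; 500 random truth tables for the minimization check) were
chosen as comfortable for a desk-scale analysis of this size.

What the generator does *not* emulate: correlated conditions, systematic
(non-independent) misclassification, case weights, time structure, or any
clinical content of the intervention. Passing recovery tests therefore
show the *engine* is sound, not that a real 19-case analysis is immune to
confounding or omitted conditions — with 19 cases and four factors several
configurations are necessarily unobserved, and the parsimonious strategy's
don't-care assumptions about them are untestable from the data alone.

## Known limitations

* Truth tables and minimization require crisp factors; multivalue factors
  must be dichotomized first (multivalue minimization is out of scope).
* Fuzzy-set calibration, PRI/RoN scores and directional expectations /
  intermediate solutions are not implemented.
* Configuration–outcome connections are not causal claims; the package
  reports set-theoretic regularities and leaves interpretation, as it must
  be, to design and replication.

## The packaged analysis at a glance

```{r example, eval = FALSE}
ct <- optimistic_facilities()
report <- develop_models(
  ct, c("decline10", "decline20"),
  list(decline10 = c("don_turnover", "support", "low_baseline"),
       decline20 = c("don_turnover", "support", "low_baseline", "chess")))
cat(render_report(report, "text"))
```

The numbered scripts under `analysis/` run the same steps as a narrated
workflow (outcome derivation, data reduction, model development, synthetic
validation) and write their tables under `results/`.
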