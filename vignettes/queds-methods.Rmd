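---
title: "Formal Psychological Assessment with the QuEDS instrument"
author: "queds package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formal Psychological Assessment with the QuEDS instrument}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(queds)
```

## The problem

Conventional depression questionnaires reduce a respondent to a single sum
score. Two patients scoring, say, 31 out of 41 may nevertheless present very
different symptomatology — one dominated by psychomotor retardation and loss
of energy (an *inhibited* depressive picture), the other by insomnia,
agitation, irritability and suicidal ideation (an *agitated* picture) — a
distinction with direct treatment consequences. Formal Psychological
Assessment (FPA) addresses this by making the item–symptom relationship
explicit and computable.

The QuEDS (Qualitative-quantitative Evaluation of Depressive Symptomatology)
is a 41-item dichotomous questionnaire for major depressive episode built on
23 clinical criteria: the DSM-5 symptom set (depressed mood through suicidal
ideation, criteria A1–A15), two criteria from Beck's cognitive triad (negative
view of the world A16, negative expectation of the future A17), Seligman's
learned helplessness (A18), and five further criteria recurrent in the
clinical literature (irritability, apathy, health concern, somatic disorders,
diurnal mood variation; A19–A23).

## The formal model

**Clinical context.** The instrument is a Boolean matrix with items in rows
and criteria in columns; cell (q, a) is 1 exactly when item q investigates
criterion a. `queds_context()` returns this 41 × 23 structure;
`validate_context()` checks the content-validity invariants (no empty row —
every item investigates something; no empty column — every criterion is
investigated).

**Derivations and concepts.** For an item set Q', `derive_items()` yields the
criteria common to all its items; for a criterion set S, `derive_attrs()`
yields the items demanding no criterion outside S's complement — the two maps
form a Galois connection, and their closed pairs are the formal concepts
enumerated by `formal_concepts()` (NextClosure, lectic order, so output order
is deterministic).

**Prerequisites.** Item i is a *prerequisite* of item j when intent(i) ⊆
intent(j): whoever can affirm j, whose criteria include all of i's, should
also affirm i. `prerequisites()` returns this reflexive, transitive relation.

**Delineated clinical structure.** We adopt the conjunctive attribution
model: endorsing an item is evidence for *all* of its criteria, so a
respondent characterised by criterion set S endorses exactly
K(S) = { q : intent(q) ⊆ S }. The family { K(S) : S ⊆ criteria } is the
clinical structure (`delineate()`). It contains ∅ and the full domain, is
closed under intersection, and each member is a down-set of the prerequisite
relation. Rather than enumerating all 2^23 criterion subsets, `delineate()`
walks the union-closure of item intents: every state is K(U) for U a union of
its members' intents, so a breadth-first expansion that adds one item's
intent at a time visits each state exactly once. A configurable cap
(`max_states`, default 5 × 10^6) guards against pathological contexts; the
per-factor subcontexts delineate to 612 (cognitive), 408 (somatic) and 160
(affective) states.

The disjunctive reading (an endorsement requires only *some* of the item's
criteria) is deliberately not implemented: the instrument's response rule is
that an affirmative answer attests to every symptom the item carries.

## Scoring and the clinical state

`score()` is the plain count of endorsed items (0–41); `subscale_scores()`
splits it over the cognitive (15 items), somatic (14) and affective (12)
factors, which partition the domain. The qualitative output is
`clinical_state()`: the endorsed set together with its *attribute profile*,
the union of the endorsed items' intents, with no weighting or thresholding.
`compare_states()` decomposes two profiles into shared and patient-specific
criteria — the "same score, different state" analysis. `pattern_consistency()`
reports whether an observed pattern is an admissible state and its symmetric-
difference distance to the nearest one (ties resolved toward the
lexicographically smallest state, so the empty state wins a tie).

One transcription subtlety: the published item–criterion table, the published
per-factor subcontexts, and one printed worked example disagree about item 27
("To make choices is hard for me"). We treat the full item–criterion table as
the single source of truth (item 27 investigates A12, A13 and A20), and
*derive* the factor subcontexts by restriction. Consequently the cognitive
subcontext retains A20, and criterion A20 is covered by all three factors —
whereas the published coverage summary lists it under somatic and affective
only. Similarly, the printed affective subcontext omits item 12 although the
factor listing assigns it there, and one patient's printed subscale count
(7/12 affective) disagrees with that patient's own printed item list (which
yields 8, and makes the subscales sum to the printed total of 31). In every
such case the item-level data win.

## Adaptive administration

The prerequisite structure makes many of the 2^41 response patterns
inadmissible, which an adaptive procedure exploits. `run_session()` keeps the
set of candidate states, repeatedly asks the unasked item that splits the
candidates most evenly (`next_question()`, half-split; ties to the smallest
item id), eliminates the candidates inconsistent with each answer, and stops
when a single candidate remains; unasked items are then inferred from it.
The procedure is deterministic, recovers every state exactly under an
error-free responder, and never asks more questions than there are items.

Because every informative question leaves a non-empty candidate set, a
responder who follows no admissible state cannot be detected by elimination
alone; `run_session(..., verify = TRUE)` therefore optionally administers the
remaining items after convergence and flags the transcript (falling back to
the fully observed answer set) if any inferred answer is contradicted. No
probabilistic error model (careless errors / lucky guesses) is included;
sessions are intended per factor, where the structures are small.

`savings_report()` quantifies the benefit: it simulates sessions for every
state (or a seeded sample when the family exceeds `max_exhaustive`) and
summarizes the number of questions asked.

## Psychometric battery

The validation statistics operate on plain 0/1 response tables:

* `cronbach_alpha()` — k/(k−1) · (1 − Σ item variances / total variance);
  with dichotomous items this is KR-20 (the n−1 variance convention cancels).
* `average_interitem_correlation()` — mean pairwise product-moment
  correlation, constant columns excluded with a warning.
* `test_retest()` — product-moment correlation of paired totals.
* `known_groups_ttest()` — pooled-variance two-sample t (df = n1 + n2 − 2),
  signed as non-clinical minus clinical so a valid instrument yields a
  negative t.
* `roc_analysis()` — positivity rule score ≥ threshold; AUC by the
  pair-counting/rank statistic with ties counted ½; the "optimal" threshold
  maximizes Youden's J, ties resolved toward the smallest threshold (the
  published cutoff of 19 is reported without its selection criterion, so
  Youden is our choice).
* `compare_dependent_correlations()` — the Fisher-transform test for two
  dependent correlations sharing one variable, with the
  Meng–Rosenthal–Rubin covariance adjustment; `compare_independent_
  correlations()` — the classical Fisher z for independent samples. Both are
  offered because the published comparison procedure is unnamed; applied to
  the published rounded correlation matrix neither reproduces the published
  z values exactly (e.g. we obtain z = 4.12 where 3.32 is printed), so no
  test asserts those.

`validation_report()` bundles the battery (alpha total and per factor,
average inter-item correlations, known-groups t, ROC, optional retest) for a
response table, and the `queds validate` subcommand emits it as JSON.

## The synthetic-respondent generator

No raw study data accompany the instrument, so the battery is exercised on
synthetic cohorts whose generative model mirrors the instrument's reported
hierarchical factor structure:

* severity g ~ N(0, 1) for non-clinical respondents, N(μ, 1) for clinical;
* factor scores f_k = γ_k g + √(1 − γ_k²) η_k with the reported second-order
  links γ = 0.77 (cognitive), 0.70 (somatic), 0.91 (affective);
* latent item responses y_i = λ_i f_k(i) + √(1 − λ_i²) ε_i with the reported
  standardized loadings λ (0.26–0.76 cognitive, 0.32–0.71 somatic, 0.33–0.70
  affective), all noise independent standard normal (the reported solution
  had no double loadings and no correlated residuals);
* dichotomization y_i > τ at a single common threshold.

Every y_i is marginally standard normal, so expected totals are available in
closed form. `calibrate()` sets τ analytically from the non-clinical target
mean (6.5 of 41) and finds μ by bisection for the clinical target (28.5);
with the default targets τ ≈ 1.0005 and μ ≈ 4.10. A single common τ is the
minimal assumption: only score-level moments are reported, so per-item base
rates are unidentifiable. Group standard deviations are *not* matched by the
latent model; where exact moment matching matters (the ROC known-groups
checks) `generate_score_surrogate()` draws integer totals directly from the
reported group moments — clinical N(28.5, 6.5), non-clinical N(6.5, 6.0),
rounded and clipped to [0, 41]. Clipping raises the realized non-clinical
mean to about 6.93 and leaves about 14% of non-clinical draws at 0; it
barely affects the separation statistics (analytically AUC ≈ 0.993 and
specificity at threshold 19 ≈ 0.977).

Retest administrations mix the original latent responses with fresh noise,
y′ = ρ y + √(1 − ρ²) e; `calibrate_retest()` bisects ρ against the achieved
total-score correlation of a fixed calibration draw (common random numbers
make the objective deterministic and monotone), targeting the reported
stability of 0.74.

**What the generator does not emulate.** Dichotomizing latent normal items at
τ ≈ 1 attenuates inter-item correlations (phi well below the latent
correlation), so the calibrated generator yields Cronbach's alpha of about
0.79–0.80 on a non-clinical cohort — clearly below the 0.948 reported for the
real data. The real responses are evidently more strongly clustered than a
single-threshold normal-ogive model with these standardized loadings implies
(higher variance, skew, and local dependence all push observed alpha up). We
keep the published parameters rather than inflating loadings to chase alpha;
tests on the generator therefore demonstrate the *pipeline* (formulas,
calibration, reproducibility, parameter recovery), not the instrument's real
reliability. Likewise passing adaptive and structural tests show algorithmic
correctness on admissible states, not robustness to careless real-world
responding.

## Numerical and design choices

* Problem sizes: structural oracles compare against exhaustive 2^|attributes|
  enumeration on the three factor subcontexts (2^8–2^12 subsets) and on
  randomized contexts up to 12 items × 8 attributes; adaptive recovery is
  exercised exhaustively over all 1,180 factor states; generator recovery
  uses cohorts of 2,000–10,000 with 3-standard-error Monte-Carlo bands; the
  surrogate separation statistic averages 200 replicates of the published
  design (265 + 38).
* Calibration tolerances: τ is closed-form; μ bisected to 10⁻⁹ (expected
  clinical total accurate to ~10⁻⁴); ρ bisected to 10⁻⁴.
* Determinism: every stochastic function takes an explicit seed; identical
  seeds give identical cohorts, sessions and reports.
* Degenerate inputs: zero total-score variance makes alpha and correlations
  undefined (NaN with a warning, not an error); chance agreement of 1 makes
  kappa undefined likewise; empty item sets derive to the full opposite set
  by the standard convention.
* Expert agreement: Cohen's kappa between expert matrices is computed
  cell-wise over all 41 × 23 cells — the only reading that uses the whole
  matrix, the unit of agreement being unstated in the source material.

## Known limitations

* The delineation cap makes the full 41-item structure available only when
  it fits in memory; the intended unit of adaptive administration is the
  factor subcontext.
* The generator's alpha shortfall discussed above; its group variances are
  only approximately reproduced by the latent model.
* No item-response-theory machinery (no probabilistic knowledge-structure
  model, no CAT with error tolerance) — the adaptive procedure assumes an
  error-free responder unless verification is requested.
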