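# queds

Formal Psychological Assessment (FPA) engine for the **QuEDS**, a 41-item
dichotomous questionnaire for major depressive episode (MDE) built on 23
clinical criteria (DSM-5 symptoms, Beck's cognitive triad, Seligman's
learned helplessness, and five literature criteria such as irritability and
diurnal mood variation).

The package is for clinical researchers and psychometricians who want the
*qualitative* output FPA promises — a patient's **clinical state**, not just
a sum score — together with the machinery to study and validate it:

* the **clinical context**: the Boolean items × criteria incidence matrix,
  with validation (no empty rows or columns), serialization (CSV/JSON) and
  expert-agreement statistics (cell-wise Cohen's kappa);
* a Formal Concept Analysis / Knowledge Space Theory core: Galois
  derivations, formal concepts (NextClosure), the prerequisite quasi-order
  (item *i* precedes *j* when intent(i) ⊆ intent(j)), and the **delineated
  clinical structure** under the conjunctive model
  K(S) = { q : intent(q) ⊆ S };
* scoring, subscale scores (cognitive 15 / somatic 14 / affective 12 items),
  attribute profiles, and state-to-state comparison ("same score, different
  symptoms");
* deterministic **adaptive administration** (half-split elimination over the
  state family);
* a psychometric battery (KR-20/Cronbach alpha, average inter-item
  correlation, test-retest, pooled known-groups t, ROC with Youden-J
  threshold, dependent/independent correlation comparisons);
* a calibrated **synthetic-respondent generator** (hierarchical second-order
  factor model dichotomized at a calibrated threshold) so the whole pipeline
  runs without patient data.

## Worked example: two patients, one score

```r
library(queds)
ctx <- queds_context()

sc <- response_pattern(c(1,3,5,6,10,12,13,14,15,16,17,18,20,22,23,24,25,26,
                         27,28,29,30,31,32,33,34,35,36,39,40,41), "SC")
fg <- response_pattern(c(2,4,5,6,7,8,9,10,11,12,13,14,15,16,18,19,20,21,24,
                         25,26,27,29,32,33,34,36,37,38,40,41), "FG")
score(sc); score(fg)
#> [1] 31
#> [1] 31
subscale_scores(sc)
#> cognitive   somatic affective
#>        12        11         8
compare_states(clinical_state(ctx, sc), clinical_state(ctx, fg))
#> State comparison: SC vs FG
#>   shared:      A1, A2, A3, A5, A10, A11, A12, A13, A14, A16, A17, A18, A20, A23
#>   only SC :  A4, A8, A9
#>   only FG :  A6, A7, A15, A19, A21, A22
```

Both patients score 31/41, yet their states differ clinically: SC uniquely
reports weight change (A4), psychomotor retardation (A8) and loss of energy
(A9) — an inhibited picture — while FG uniquely reports insomnia (A6),
agitation (A7), suicidal ideation (A15), irritability (A19), health concern
(A21) and somatic disorders (A22) — an agitated picture.

Adaptive administration exploits the prerequisite structure. The affective
factor delineates to 160 admissible states over 12 items, and a session
localizes a respondent without asking everything:

```r
st <- delineate(subcontext(ctx, queds_factors()$affective))
st
#> Clinical structure: 160 states over 12 items
run_session(st, c(12, 15, 17, 18, 29, 34, 36))
#> Adaptive session: 7 questions asked, 5 answers inferred
#>   final state (7 items): 12, 15, 17, 18, 29, 34, 36
```

The synthetic generator calibrates a single dichotomization threshold and a
clinical severity shift to the reported group means (6.5 non-clinical, 28.5
clinical of 41):

```r
cfg <- calibrate(default_config())
c(tau = cfg$tau, mu = cfg$mu)
#>      tau       mu
#> 1.000491 4.104656
sur <- generate_score_surrogate(38, 265, seed = 1)
roc <- roc_analysis(sur$scores, sur$labels)
roc
#> ROC analysis: AUC = 0.994 | optimal threshold 19 (Youden J = 0.917)
roc_at(roc, 19)
#> sensitivity specificity
#>   0.9473684   0.9698113
```

A command-line wrapper (`exec/queds`) exposes the same functionality as
subcommands (`score`, `state`, `compare`, `context-validate`, `structure`,
`adapt`, `validate`, `simulate`) with `--seed`, `--format` and `--out`
flags; machine output goes to stdout, logs to stderr.

See `vignettes/queds-methods.Rmd` for the model, its assumptions, the
calibration details, and what the synthetic cohorts do and do not emulate.

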