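---
title: "Scoring and recommending antipsychotic treatment from admission histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and recommending antipsychotic treatment from admission histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schizrec)
```

`schizrec` builds a medication recommender for hospital in-patients with
schizophrenia spectrum disorders from three ingredients: a composite
treatment-outcome score computed from routine utilisation signals, a
K-nearest-neighbour collaborative filter over patient similarity, and an
evaluation harness whose first design goal is that no information can leak
from the future or from test patients into a prediction. This vignette
explains the model, the assumptions behind each design decision, the
numerical edge cases, and what the synthetic-cohort experiments do and do
not demonstrate.

## The cohort and its cleaning rules

The unit of analysis is a *consultation*: one (patient, admission) decision
point at which a treatment arm is chosen. Arms are the 15 antipsychotics
observed in the development setting plus an explicit `NONE` arm; an
admission with no antipsychotic prescription initiates `NONE`, which is
scored, ranked and evaluated like any drug. Cleaning retains patients aged
18–40 with a schizophrenia-spectrum diagnosis (ICD-9 `295.x` codes are
mapped to ICD-10 `F2x`; only the first code of a comma-separated field is
used), consolidates source-dialect ethnicity labels into four categories
(dropping small groups), drops patients whose record starts at a second
visit, and caps admissions at the third visit. Every exclusion is counted
by reason, and the counts must sum to the number of dropped patients — a
cheap invariant that catches double-filtering bugs.

Each consultation's feature vector contains only information available at
its admission: gender, ethnicity, age, and the current admission's
comorbidity count, plus — for second and third visits — the earlier
visits' length of stay, inter-admission gap, prescribed arm and a switch
indicator. Feature construction takes the history explicitly and raises a
classed error if any supplied visit is not strictly earlier; the maximum
history index used is stored per consultation so the evaluation audit can
re-verify the constraint after the fact. Two points the data model leaves
open were resolved as follows: comorbidity is treated as a per-visit count
(the current admission's count is baseline information a clinician has),
and "number of visits" counts all visits observed up to the evaluation
point.

## The affinity score

For each patient–drug instance, four raw quantities — total days between
admissions, days between medication switches, total length of stay, and
visit count — are min–max normalised against bounds fitted on the training
fold, oriented so larger is better (`t`, `s`, `ℓ = 1 − norm(LOS)`,
`v = 1 − norm(visits)`), averaged with equal weights, and a fixed switch
penalty is subtracted before clipping to `[0, 1]`:
`A = clip((t + s + ℓ + v)/4 − P, 0, 1)` with `P = −0.05` (no switch — a
bonus), `0.10` (first switch), `0.20` (second). Switches are initiations
of a further antipsychotic *after* the scored drug, capped at two; for the
`NONE` arm, starting any drug later counts as its first switch.

Numerical choices:

* **Out-of-range values clip** rather than extrapolate. External
  populations routinely exceed development-fold extrema, and a bounded
  score is worth more than a linear tail.
* **Degenerate bounds** (`max == min`, e.g. a tiny external fold in which
  every patient has one visit) map to the uninformative midpoint 0.5
  rather than an arbitrary extreme.
* **Missing components**: a single-visit patient has no inter-admission
  gap and an unswitched instance no inter-switch time. The default policy
  scores these components 1 — no readmission and no switch are the best
  outcomes the data can express. The alternative (`renormalize`) drops the
  component and renormalises the remaining weights; it is a configuration
  switch because neither choice is derivable from first principles.
* The equal-weight path reproduces the quarter-sum formula exactly (tested
  to 1e-12 against an independently coded one-expression oracle).

Two sensitivity variants ship with the package: a stability-heavy scheme
(weights 0.35/0.35/0.15/0.15 on `t`/`s`/`ℓ`/`v`) and a burden-heavy scheme
(0.15/0.15/0.35/0.35 with halved penalties). The descriptions constrain
only the ordering of the weights, so the exact values are configuration
defaults, overridable via `affinity_scheme()`.

## Similarity engines and preprocessing

Five engines share one train-fitted preprocessing contract: one-hot
encoding with category levels recorded on the training fold (an unseen or
missing level encodes as an all-zero block — external dialects introduce
new levels and must not crash a frozen model) and standardisation with
training means and standard deviations (missing numerics map to the
training mean). Transformation is a pure function; fitting twice on the
same data is idempotent.

* **CF-cosine** — cosine similarity on the encoded vectors. After
  standardisation cosine can dip below zero; values are clipped at 0 so
  downstream weighted averages have non-negative weights.
* **CF-Euclidean** — `1 / (1 + d + 1e-9)`.
* **DR-RBA** — weighted Gower similarity on the raw mixed-type records
  (categorical: equality; numeric: `1 − |u − v|/range` with training-fold
  ranges; weighted mean over features both records have), with per-feature
  weights from ReliefF run on binary labels `1{A > 0.5}`. ReliefF uses the
  same Gower-style per-feature differences for its neighbour search, so
  the weights live in the geometry they will be used in. Scores are
  floored at 0 and rescaled to mean 1; a constant feature keeps weight 0.
  All features are weighted (an optional top-m selection exists, since
  "attribute weighting for feature selection" can be read either way).
* **DR-RBF** — `exp(−γ‖x − y‖²)` with default `γ = 1/n_features`.
* **DR-NCA** — a square linear map maximising the softmax leave-one-out
  class probability of the same binary labels, optimised by L-BFGS from an
  identity start (hence deterministic); similarities are Euclidean in the
  mapped space. On large folds the objective is quadratic in the sample,
  so the fit uses a deterministic, seed-controlled subsample (default
  200 rows) and applies the learned map to everything. Zero iterations
  return the identity map, under which the method reduces exactly to
  CF-Euclidean — a useful regression anchor.

ReliefF's neighbour count (10), NCA's iteration cap and seed, and the RBF
bandwidth are configuration values: the methods are named requirements,
their constants are not.

Pairwise distances are computed by an explicit per-row sweep rather than
the usual `‖x‖² + ‖y‖² − 2x·y` expansion; the expansion loses ~1e-6 of
precision near zero distance, which is visible where identical records
must score `1/(1 + 1e-9)` essentially exactly.

## Prediction and ranking

For a test consultation, the `K` most similar training *patients* form the
neighbourhood (a patient's similarity is the best similarity over their
treatment instances). Each arm is predicted as the similarity-weighted
mean of the neighbours' observed affinities for it — a convex combination,
so predictions inherit the `[0, 1]` range. An unweighted mean is available
for comparison, since the averaging rule is not fully pinned down by the
method's description.

Arms none of the neighbours has an outcome for are filled by a logged
fallback chain (drug training mean, then global training mean) so the
actually-prescribed arm can always be scored for error measurement, but
they are withheld from the ranked list. This is the one place the package
deviates from its original design sketch (per-arm neighbourhoods: the K
nearest among patients with an outcome on that specific arm), and the
reason is instructive: under a realistic prevalence profile, most arms are
rare, and a per-arm neighbourhood gives an arm with one or two historical
instances a full-confidence extreme prediction. In experiments such arms
entered the top-3 of essentially every consultation, turning the list into
a lottery over cold arms. Restricting recommendations to arms with
evidence among the K similar patients is the standard user-based top-N
formulation, keeps neighbourhood sizes like `K ≈ 7` meaningful, and makes
the support count an honest confidence signal. Rankings are total and
bit-reproducible: predicted affinity descending, ties broken by larger
neighbour support, then lexicographic arm name; similarity ties at the
neighbourhood boundary break on a (patient, drug) key so results are
invariant to training-pool row order.

## Evaluation protocol

The harness runs nested patient-grouped cross-validation: five outer folds
split by patient (~20% test each); within each outer training set, five
inner patient-grouped folds select `K ∈ {5, 10, …, 60}` by minimising the
RMSE between predicted and observed affinity of each validation
consultation's actually prescribed arm; numerical ties break toward the
smallest `K`. Everything downstream of the raw tables — normalisation
bounds, observed affinities, encoders, scalers, ReliefF weights, NCA maps
— is fitted on the fold's training patients only; test-fold observed
affinities are computed with *training* bounds. Temporal discipline is
visit-based: visit-1 queries use only other patients; visit-2/3 queries
additionally carry the patient's own earlier-visit features. Every run
emits a leakage audit (per-fold train/test patient sets, their
intersection, and the count of future-visit feature reads), and the test
suite asserts both are zero across all folds.

Metrics follow the standard definitions: RMSE on the actually prescribed
arm; MAP@3 with relevance = arms the patient actually received with
observed affinity above 0.5 (consultations with an empty relevant set are
skipped and counted — average precision is undefined there); overlap = the
fraction of consultations whose actual therapy is in the top 3, with
coverage its exact complement. All are reported as mean ± sd over outer
folds, overall and per visit index; both consultation counts and
patient–drug instance counts are reported because "samples" is ambiguous
between them.

The disagreement analysis restricts to consultations whose actual therapy
is absent from the top 3 and compares the system's predicted affinity for
its own top arm with the affinity the clinician's choice achieved: paired
differences, `t = mean(d)/(sd(d)/√n)` with `n − 1` degrees of freedom
(two-sided), and Cohen's d for paired data `mean(d)/sd(d)`. A negative
mean difference means clinicians outperformed the system. When all
differences are identical the statistic is defined as 0 (or ±∞ for a
non-zero constant difference) rather than NaN.

External validation freezes a model (bounds, preprocessing, similarity
state, `K`) on the development cohort and applies it unchanged — `K` is
never re-selected, unseen categorical levels encode as zeros with a
warning, and by default the development bounds normalise the external
affinities (refitting bounds on the external population is a documented
option, as the original protocol is silent on this point). Sensitivity
re-runs repeat the whole nested CV per affinity scheme on a shared fold
plan, so metric differences are attributable to the outcome definition
alone.

## The synthetic cohort generator

The generator emits only raw fields — admission and discharge timestamps,
comorbidity counts, prescription start times — so the full cleaning and
scoring pipeline runs on its output exactly as on a real extract. Its
defaults emulate the development cohort's published profile: 1,152
patients, age 27.9 ± 6.4 truncated to 18–40, 65.8% male, ethnicity mix
44.4/39.6/8.1/7.9%, visit counts 57.3/21.8/20.9%, length of stay
6.6 ± 10.5 days (log-normal, matching the heavy right skew), and the
printed arm-prevalence profile with the rare-drug mass split evenly
(interpreted as the visit-1 arm distribution after renormalisation, since
the printed per-drug percentages sum to more than one across multi-drug
patients). `validate_marginals()` z-tests every generated marginal against
its target (|z| ≤ 4), pooling the ten rare antipsychotics whose expected
counts are single digits.

The planted structure works as follows. Each arm is a good match
(response `0.5 + 0.4·effect_size`) for exactly one latent subgroup and a
poor match (`0.5 − 0.2·effect_size`) elsewhere, with arms cycled over
subgroups in *descending prevalence* order so every subgroup's primary
good match is a treatment patients actually receive — relevance in MAP@3
can only accrue on received arms, so structure planted on never-prescribed
arms would be invisible by construction. Responses drive the record
through four channels: inter-admission gaps (gamma, mean `20 + 350r`
days), length of stay (log-normal mean shifted by match quality),
medication switches (probability rising as response falls; switch targets
are drawn from the prevalence profile so an arm's instance mix is not
skewed merely because it is rare at first line), and readmission itself —
the single-visit probability is centred on the marginal target but shifted
by the visit-1 response, because "a well-matched treatment means no
readmission" is precisely the planted mechanism taken to its limit, and
with a purely marginal visit-count draw most outcome variance would be
unpredictable noise.

Subgroups must be *visible* to the similarity engines or nothing can
recover them. Rather than tilting feature distributions per subgroup
(which distorts the marginals as the coupling grows), demographics are
drawn exactly from the specified marginals and the subgroup is then
assigned as a mostly deterministic function of the features — ethnicity
group crossed with age band, with 15% random reassignment at the default
`subgroup_sep = 1` and a fully random assignment at 0 — plus a
subgroup-conditional comorbidity burden, which no published marginal
constrains. The truth (subgroup assignment and response matrix) is written
to a separate sidecar that the pipeline never reads; deleting it changes
no output.

What passing the synthetic experiments shows — and what it does not. The
recovery check (800 patients, 4 subgroups, strong effect) demonstrates
that the pipeline's plumbing is sound end to end: with structure planted,
CF-cosine's visit-1 MAP@3 exceeds the 97.5th percentile of a 200-replicate
label-permutation null and its RMSE beats the predict-the-global-mean
baseline (the check uses `K = 40`, broad enough that the neighbourhood
covers the arm set; the nested harness still selects `K` itself); with
`effect_size = 0` the same comparison shows no separation. It does *not*
show that real cohorts contain subgroups this legible: real patient
similarity is far weaker, outcomes are confounded by everything the record
omits, and treatment assignment is not random. Synthetic results bound the
machinery, not the clinical value.

## Problem sizes and reproducibility

The test suite exercises the full nested protocol on cohorts of 60–200
patients, the recovery check on 800, and the acceptance script runs a
300-patient development analysis — sizes chosen so the whole suite
completes in about a minute while every code path (all five engines, all
fold levels, the audit, the CLI) runs for real. All randomness flows
through explicit integer seeds (`withr::with_seed`), generation is
byte-deterministic, and two CLI runs with the same config and seed produce
byte-identical outputs — which the test suite also asserts.

## Known limitations

The affinity score is a proxy built from utilisation, blind to symptom
scales, side-effect burden, dosage and formulation. Collaborative
filtering estimates correlations in observed outcomes, not causal
treatment effects, and inherits whatever selection bias produced the
prescriptions it learns from. The `NONE` arm's outcomes are particularly
confounded (not being medicated is both a choice and a signal). The
disagreement analysis compares against the aggregate of many clinicians
and says nothing about any individual decision. None of the package's
outputs is prescriptive.
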