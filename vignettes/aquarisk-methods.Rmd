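---
title: "Methods: AHP-based introduction-risk assessment for aquatic animals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AHP-based introduction-risk assessment for aquatic animals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

## The assessment problem

Importing a non-native aquatic animal — for aquaculture, the ornamental
trade, or research — carries two coupled risks: the ecological risk of
the species itself (establishment, competition with indigenous fauna,
habitat alteration) and the epidemiological risk of the pathogens it may
carry. `aquarisk` implements a quantitative model that scores both on a
common scale and aggregates them into a single, gradeable risk value,
so that introduction decisions can rest on a number with an explicit,
auditable derivation rather than on a qualitative narrative.

## Model structure

The model is a three-layer weighted index hierarchy beneath a single
total value $R$:

* 4 **primary indices** $R_1..R_4$ — hazard of the species itself,
  entry assessment, exposure assessment, consequence assessment (the
  classical import-risk-analysis decomposition, extended with a
  species-hazard branch);
* 12 **secondary indices** $P_1..P_{12}$ grouping related concerns
  (e.g. $P_4$ "diseases carried by the introduced species", $P_{10}$
  "detection and control measures");
* 60 **tertiary indices** $p_{11}..p_{126}$ — the empirically scorable
  quantities.

Each tertiary index receives an integer score $s \in \{0,\dots,5\}$
(0 negligible ... 5 extremely high risk) against a written rubric.
Values propagate upward by *cumulative* weighted aggregation — each
parent is the weight-sum of its children,

$$P_j = \sum_k w_{jk}\, p_{jk}, \qquad
  R_i = \sum_j w_{ij} P_j, \qquad
  R = \sum_i w_i R_i,$$

with every sibling weight group summing to 1. Aggregates are therefore
convex combinations: every $P$, $R_i$ and $R$ stays inside $[0,5]$, a
constant sheet maps to that constant at every level, and raising any
single score can only raise every ancestor (all weights are strictly
positive). The cumulative form assumes sibling indices contribute
independently; the model family also names multiplicative and
substitution relationships between indices, but no aggregation rule is
defined for them, so this package implements the cumulative case only.

The bundled default model (`default_model()`) carries published weight
coefficients rounded to four decimal places; `sibling_weight_groups()`
exposes all 17 groups and their sums. Arbitrary user models — any
4-level tree, any branching — are accepted through the same YAML
configuration format, documented by the bundled file itself
(`system.file("extdata", "aquarisk_model.yaml", package = "aquarisk")`).

## Weight derivation (AHP)

Weights come from Saaty's analytic hierarchy process: for each sibling
group an expert panel fills a pairwise comparison matrix $A$ with
relative importances $a_{ij}$ on the 1–9 scale, $a_{ji} = 1/a_{ij}$.
The weight vector is the principal right eigenvector of $A$, normalized
to sum 1 (`derive_weights()`); by Perron–Frobenius it is unique and
strictly positive for any positive matrix.

Judgment quality is screened with the standard diagnostics
(`consistency_report()`):

$$CI = \frac{\lambda_{max} - n}{n - 1}, \qquad CR = \frac{CI}{RI(n)},$$

with judgments acceptable when $CR < 0.1$. Numerical choices:

* **Eigen method** — deterministic power iteration from the uniform
  start vector, tolerance $10^{-12}$ on the eigenvector in sup norm,
  capped at 10,000 iterations. Matrices here are tiny ($n \le 9$), so
  this converges in tens of iterations; the test suite cross-checks it
  against a dense `eigen()` decomposition to $10^{-8}$ on thousands of
  seeded matrices.
* **$\lambda_{max}$** — recovered as $\sum_i (Aw)_i$ at the converged,
  sum-1 eigenvector.
* **Degenerate orders** — $n = 1$ and $n = 2$ reciprocal matrices are
  always consistent; $CI$ and $CR$ are defined as 0 there (the defining
  formulas divide by $n-1$ and by $RI = 0$), and the verdict follows
  $CI$ alone.
* **RI table** — the model configuration carries Saaty's standard
  random indices $RI(1..9) = (0, 0, 0.58, 0.90, 1.12, 1.24, 1.32,
  1.41, 1.45)$; order 9 suffices because the largest sibling group in
  the default model has nine children. Larger custom models must
  supply their own extended table (`ri_table` argument / config key).
* **Reciprocity** — enforced to a relative $10^{-9}$; hand-entered
  matrices with small asymmetries can be repaired by geometric-mean
  symmetrization (`symmetrize = TRUE`, off by default so that silent
  data correction never happens unasked).
* Entries beyond the Saaty range $[1/9, 9]$ warn but do not error:
  ratio matrices built from continuous weight vectors are legitimate
  inputs.

The expert comparison matrices behind the default model's coefficients
were never published, so the engine is validated by its mathematical
properties (exact recovery of generating weight vectors from consistent
matrices, agreement with a dense eigendecomposition on perturbed ones)
and the default weights are taken verbatim from the published
coefficient expressions rather than re-derived.

## Scoring rubric

Every tertiary index has a rubric entry (`default_model()$rubric`).
Enumerated entries give a distinct criterion per level; discussion
entries give one guidance paragraph and rely on the general six-level
evaluation rules stored alongside (`$discussion_rules`). Scores are
whole levels only — the published scoring practice assigns integers
throughout — and `validate_score_sheet()` reports (never throws) any
out-of-range, fractional, missing or unknown entries.

A handful of indices print criteria for levels 1–5 only (e.g. `p44`,
`p61`, `p83`, `p121`, `p126`). The global scoring rule nevertheless
gives every index the same 0–5 range, so both readings are preserved:
a score on an undefined level is always *valid*, and `strict = TRUE`
additionally surfaces it as an advisory warning. Two quirks of the
source rubric are kept as printed rather than edited: `p44` repeats
the same text for levels 4 and 5, and the level-0 texts missing from
those indices are reported as a defined absence (`NA`) by
`rubric_lookup()`.

## Aggregation, rounding and grading

`assess()` propagates full-precision values: secondaries from tertiary
scores, primaries from *unrounded* secondaries, $R$ from *unrounded*
primaries. Rounding to four decimals (round-half-even, matching the
printed precision of the coefficients) happens only in the `rounded`
matrix and the CSV report; machine-readable JSON output keeps full
precision. Subjects are ranked by descending unrounded $R$; ties —
possible for identical sheets — break alphabetically by subject id,
a deterministic choice the source procedure leaves open. For the tie
comparison only, $R$ is snapped to nine decimals first: optimized
linear-algebra kernels can return column-position-dependent results at
the last bit, and identical sheets must rank as exact ties.

The grade intervals on $R$ are lower-open, upper-closed:
negligible $(0,1]$, low $(1,2]$, medium $(2,3]$, high $(3,4]$,
extremely high $(4,5]$, each carrying a policy recommendation from
"can be carried out" to "cannot take place". $R = 0$, attainable for an
all-zero sheet, is graded negligible by closure. Boundary behaviour is
tested exactly at $R \in \{1,2,3,4,5\}$.

## The embedded case study and a known erratum

The package embeds its validation surface: scores for five introduced
aquatic animals (*Pterygoplichthys pardalis*, *Macrobrachium
rosenbergii*, *Crassostrea gigas*, *Trachemys scripta elegans*,
*Ambystoma mexicanum*) across all 60 indices, plus the published
results table (12 secondary + 4 primary + 1 total value per species,
and five risk grades). Expected values are stored as the literal
printed four-decimal strings, so regression tests compare against the
published figures, not against a re-derivation.

```{r case-study}
cs <- builtin_case_study()
a <- assess(cs$score_sheet)
a$rounded["R", ]
a$grades
```

Re-running the assessment reproduces 84 of the 85 published values
within the printing tolerance of $\pm 5\times 10^{-4}$ and all five
grades exactly. The one exception is the consequence assessment of
*P. pardalis*: the published table prints $R_4 = 3.8843$, while its own
published coefficients give $0.8000 \times 3.7002 + 0.2000 \times
4.6164 = 3.88344$ under every propagation order — rounded or unrounded
children alike — i.e. 3.8834. The printed value is a digit
transposition. Tellingly, propagating the published *rounded* primary
values including 3.8843 reproduces the published total $R = 3.6973$
for that species exactly, so the transposed figure entered the
published total as well; the package's unrounded total, 3.6971, agrees
with the printed one within the four-decimal tolerance. The fixture
keeps the value as printed, the regression suite asserts the corrected
arithmetic for that cell, and the full-table tolerance check is left
failing on exactly that cell rather than widened.

## Synthetic score sheets

`random_score_sheet()` draws independent uniform integer scores in
$\{0..5\}$ for every tertiary index — uniform because no empirical
score distribution is assumed by the model; the generator exists to
exercise the aggregation algebra, not to mimic expert behaviour. Real
score sheets are strongly structured (policy indices score low and
nearly constant across species, pathogen indices cluster high and
correlate within a branch), so property tests on uniform sheets
demonstrate correctness of the arithmetic — oracle agreement to
$10^{-12}$, monotonicity, linearity, convexity — and nothing about the
ecological validity of any particular model's weights. Sheets are
seeded and leave the caller's RNG state untouched.

Problem sizes used by the shipped suite: 1,000 consistent and 1,000
perturbed comparison matrices of orders 2–9 for the eigen-engine
properties, 100 random sheets for the aggregation oracle, and the
5 × 60 case study for the end-to-end regression — all chosen to give
dense coverage of the tiny matrix orders the model actually uses while
keeping a full test run comfortably fast on a laptop.

## Limitations

* Only the cumulative aggregation relationship is implemented (see
  above); hierarchies are fixed at three criterion layers below the
  total node.
* The rubric is metadata: the package validates and documents scores
  but does not automate the expert discussions behind them, and no
  multi-expert reconciliation or uncertainty propagation over scores
  is attempted.
* Grades and weights are exactly as configured; the package takes no
  view on their ecological calibration beyond the embedded case study.
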