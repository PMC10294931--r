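# aquarisk

Quantitative risk assessment of non-native **aquatic animal
introductions**, built on the analytic hierarchy process (AHP).

Agencies and researchers who must decide whether a fish, crustacean,
shellfish or amphibian may be imported need a number, not a narrative:
something reproducible, comparable across species, and decomposable
into the concerns that drove it. `aquarisk` implements a three-layer
weighted index model that delivers exactly that — it scores 60
empirically assessable **tertiary indices** on an integer 0–5 risk
scale against a written rubric, aggregates them through 12 **secondary**
and 4 **primary** indices (species hazard, entry, exposure and
consequence assessment) into a single total risk value *R*, and grades
*R* on a five-level scale with a policy recommendation attached.

## The model

Aggregation is cumulative (each parent is the weight-sum of its
children; every sibling weight group sums to 1):

```
P_j = Σ_k w_jk · p_jk        (secondary from tertiary scores)
R_i = Σ_j w_ij · P_j         (primary from unrounded secondaries)
R   = Σ_i w_i  · R_i         (total from unrounded primaries)
```

so every aggregate is a convex combination and stays in [0, 5]. The
weights come from AHP: pairwise comparison matrices on the Saaty 1–9
scale, the principal-eigenvector weight vector, and the standard
consistency screen *CI* = (λmax − n)/(n − 1), *CR* = *CI*/*RI*(n),
accepted when *CR* < 0.1. Risk grades partition *R* into lower-open,
upper-closed intervals: negligible (0,1], low (1,2], medium (2,3],
high (3,4], extremely high (4,5].

The bundled default model (4/12/60 indices, published four-decimal
coefficients, full scoring rubric, grade thresholds) is a YAML document
under `inst/extdata/` that also serves as the template for custom
models — any three-layer hierarchy with any branching is accepted.

## Worked example

The package embeds the five-species case study the default model was
validated on. Assessing it end to end:

```r
library(aquarisk)
cs <- builtin_case_study()      # 60 tertiary scores x 5 species
a  <- assess(cs$score_sheet)    # uses default_model()
a$rounded["R", ]
#> Pterygoplichthys pardalis Macrobrachium rosenbergii         Crassostrea gigas
#>                    3.6971                    2.9622                    2.7073
#> Trachemys scripta elegans       Ambystoma mexicanum
#>                    2.5947                    1.9742
a$grades
#> Pterygoplichthys pardalis Macrobrachium rosenbergii         Crassostrea gigas
#>                    "high"                  "medium"                  "medium"
#> Trachemys scripta elegans       Ambystoma mexicanum
#>                  "medium"                     "low"
rank_subjects(a)
#> [1] "Pterygoplichthys pardalis" "Macrobrachium rosenbergii"
#> [3] "Crassostrea gigas"         "Trachemys scripta elegans"
#> [5] "Ambystoma mexicanum"
```

Reading: the armored catfish *P. pardalis* lands in the **high** grade
(3 < R ≤ 4 — introduction not recommended without strict controls),
three species are **medium** (limited introduction under strict
management), and the axolotl *A. mexicanum* is **low** (may be
introduced where national policy allows). `print(a)` shows the full
results table (P1–P12, R1–R4, R, grade per species), and
`grade_recommendation()` returns the policy text for each grade.

Deriving weights for a new sibling group from an expert comparison
matrix:

```r
m <- pairwise_matrix(rbind(c(1, 3, 5), c(1/3, 1, 2), c(1/5, 1/2, 1)))
consistency_report(m)
#> <consistency_report> n = 3
#>   lambda_max = 3.0037   CI = 0.0018   RI = 0.5800   CR = 0.0032
#>   verdict: consistent (CR < 0.1)
#>   weights: 0.6483 0.2297 0.1220
```

A command-line wrapper with `assess`, `validate`, `weights`,
`check-consistency` and `demo` subcommands is installed at
`system.file("cli", "aquarisk", package = "aquarisk")`.

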