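Package: aquarisk
Title: Quantitative Introduction-Risk Assessment for Aquatic Animals via
    the Analytic Hierarchy Process
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative risk assessment of non-native aquatic
    animal introductions built on the analytic hierarchy process (AHP).
    Derives criterion weights from pairwise comparison matrices via the
    principal eigenvector with Saaty consistency diagnostics (lambda_max,
    CI, RI, CR), ships a three-layer weighted index model (4 primary, 12
    secondary and 60 tertiary indices) with a rubric-constrained 0-5
    scoring scale, aggregates scores cumulatively into a total risk value
    R, assigns one of five risk grades with policy recommendations, and
    embeds a five-species case study as the regression surface. Custom
    index hierarchies, rubrics and grade thresholds are supported through
    a versioned YAML model configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
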