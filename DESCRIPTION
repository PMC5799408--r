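Package: lickstruct
Title: Lick Microstructure Analysis for Sucrose Anhedonia Assays
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing rodent lickometer recordings from
    single-bottle sucrose drinking tests. Parses MED-PC style event files
    and plain CSV lick tables, segments lick trains into clusters by an
    interbout-interval rule (default 250 ms), computes per-session and
    per-animal microstructure and consumption summaries, and provides a
    from-scratch statistical battery (balanced mixed-design repeated
    measures ANOVA with Bonferroni pairwise comparisons, Mann-Whitney U
    with exact enumeration, pooled-variance t tests, binary logistic
    regression). A synthetic experiment generator simulates rhythmic
    within-cluster licking and pause structure for a two-group,
    two-concentration counterbalanced crossover, so every pipeline stage
    is testable and power and type-I error can be assessed by simulation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
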