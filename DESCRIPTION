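Package: tailTE
Title: Poly(A)-Tail Length and Translational Efficiency Analysis for
    Oocyte and Early-Embryo Profiling Data
Version: 0.1.0
Authors@R:
    person("Maintainer", "tailTE", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the coupling between mRNA poly(A)-tail
    length and translational efficiency (TE) across developmental stages,
    as measured by poly(A)-tag sequencing (e.g. PAL-seq), ribosome
    footprint profiling, and RNA-seq. Implements representative gene-model
    selection and 3'-end re-annotation from poly(A)-anchored tags,
    per-gene tail summaries, RPM/RPKM and median-centred log2 TE with the
    standard read cutoffs and pseudocount rules, per-stage and
    between-stage tail/TE coupling statistics, short time-series model
    profile clustering with permutation-based enrichment, and
    genotype-contrast analyses (global tail shortening, dependent
    regulated-set definition, gene-set shift tests). Includes a
    synthetic-data generator that emulates multi-stage, multi-genotype
    cohorts with known ground truth so that every analysis stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
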