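Package: panelcover
Title: Per-Base Coverage QC, Mutation Discoverability and Validation
    Statistics for Amplicon Sequencing Panels
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Clinical-grade coverage auditing for amplicon-based targeted
    resequencing panels. Computes per-base read depth from aligned reads or
    depth tables, determines the "discoverability" of every known mutation
    in a catalogue (whether each base of its footprint reaches a minimum
    depth), aggregates per gene, per sample and per run, and renders QC
    reports. Also implements a clinical variant filter cascade with a
    three-tier pathogenicity classification, diagnostic-yield accounting,
    concordance statistics against orthogonal truth sets with Wilson and
    Clopper-Pearson binomial confidence intervals, and a seed-controlled
    synthetic fixture generator (panels, catalogues, reads with amplicon
    dropout and strand-imbalance artifacts, call sets, cohorts) so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    IRanges,
    Rsamtools,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
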