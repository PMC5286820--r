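Package: rootskew
Title: Root Skewing Morphometrics and Transcriptome Candidate-Gene Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies Arabidopsis root skewing and waving phenotypes from
    traced root coordinates (arc length, horizontal growth index,
    straightness, wave density) with group summaries, two-way Type-II ANOVA
    and Scheffe post hoc letters, and screens microarray transcriptomes for
    skew gene candidates: per-contrast moderated t-statistics with
    Benjamini-Hochberg FDR, a seven-contrast within/between-ecotype
    comparison matrix across growth-plate angles, an inherent-difference
    filter, six-category expression-pattern classification, and
    Venn-intersection selection of highly probable skew gene candidates
    (HPSGC). Includes seeded synthetic-data generators with planted ground
    truth for end-to-end verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    car,
    jsonlite,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'ExpressionStudy-methods.R'
    'RootTraceSet-methods.R'
    'diffexpr.R'
    'patterns.R'
    'synthetic-data.R'
    'io.R'
    'config.R'
    'cli.R'
    'morphometrics.R'
    'group-stats.R'
    'reference-fixture.R'
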