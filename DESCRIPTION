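Package: laciMEV
Title: Post-Quantification Analysis of iTRAQ Plasma Extracellular-Vesicle
    Proteomes for Stroke Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for 4-plex iTRAQ quantitative proteomics of
    plasma medium-sized extracellular vesicles (MEVs) from lacunar-infarction
    outcome cohorts. Provides peptide-to-protein ratio rollup, volcano-style
    differential-abundance calling against a healthy-control channel,
    seven-region Venn decomposition of per-group altered sets into
    outcome-taxonomy classes, Spearman rank-correlation profiling within and
    across vesicle fractions, MISEV2018 marker-category quality control,
    GO-concept enrichment via string matching and chi-square tests of
    independence, a five-rule prognostic-biomarker shortlist engine with
    per-protein rule provenance, and a synthetic iTRAQ cohort generator with
    planted effects for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
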