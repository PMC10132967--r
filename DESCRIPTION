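Package: ecamplicon
Title: Detection and Cohort Analysis of Extrachromosomal DNA Focal Amplifications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing focal amplifications in cancer and
    pre-cancer whole-genome sequencing cohorts, with an emphasis on
    extrachromosomal DNA (ecDNA). Parses breakpoint-graph and
    cycle-decomposition files, filters copy-number segments into
    amplification seed regions, classifies amplicons (ecDNA,
    breakage-fusion-bridge, complex non-cyclic, linear), scores amplicon
    similarity to call clonal ecDNA across biopsies, computes structural
    complexity from cycle decompositions, annotates amplicon-borne genes,
    pairs sequencing biopsies with histology records, and runs
    contingency-table association statistics (one-sided Fisher tests,
    Haldane-corrected odds ratios, Mann-Whitney, Levene). Includes a
    synthetic-cohort generator emulating longitudinal Barrett's oesophagus
    surveillance designs so the full pipeline is testable without access to
    protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
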