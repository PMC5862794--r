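Package: herdqc
Title: Genotype and Animal Quality Control for National Cattle SNP Databases
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quality control and parentage tooling for large bovine SNP
    genotype collections. Implements a genotype-level QC pipeline (call
    rate, missing or mixed genotype classes, genotype-class frequency),
    two-stage SNP parentage validation and fast whole-database parent
    prediction on a high-MAF 800-SNP panel using opposing-homozygote
    Mendelian conflicts, trio mating validation, duplicate-sample
    discovery via exact block string matching, sex prediction from
    chromosome Y call counts and chromosome X heterozygosity with
    pseudoautosomal-region determination, supervised breed-composition
    estimation against purebred references, animal-level invalidation
    logic, parentage-panel construction utilities, and a seeded
    multi-breed herd simulator with a complete truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: SNP, QualityControl, Genetics
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'thresholds.R'
    'io.R'
    'genotype_qc.R'
    'parentage.R'
    'duplicates.R'
    'sexcheck.R'
    'breedcomp.R'
    'panel_tools.R'
    'animal_qc.R'
    'simulate.R'
    'pipeline.R'
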