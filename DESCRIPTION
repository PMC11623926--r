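Package: CHIPburden
Title: Clonal Hematopoiesis Variant Filtering, Burden Statistics, Detection
    Power and Inflammatory-Signature Enrichment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls clonal hematopoiesis of indeterminate potential (CHIP)
    from annotated somatic variant calls in blood using a stepwise,
    auditable multi-criterion filter cascade (VAF window, site depth,
    per-strand read-pair support, gnomAD/COSMIC population filter,
    cohort-recurrence filter, homopolymer-context filter, protein-altering
    consequence), classifies passing variants as CHIP or CHIP with putative
    drivers, stratifies samples by clonal burden and computes cohort
    prevalence statistics (conditional exact 2x2 test, age-adjusted
    logistic regression, Benjamini-Hochberg adjustment, pre/post VAF
    concordance). Includes the exclusive-detection power model for
    group-restricted variant detection (minimum carrier and cohort sizes,
    Poisson-binomial engine) and a Wilcoxon-AUC preranked gene set
    enrichment stage with a permutation null for single-cell
    inflammatory-signature analysis. A synthetic-data generator emulates
    cohorts of annotated variant calls with ground truth and expression
    matrices with planted pathway effects, so every stage is testable
    without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
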