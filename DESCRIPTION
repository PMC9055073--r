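Package: crcprofiler
Title: Genomic Profiling and Subtyping Pipeline for Colorectal Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for cohort-scale somatic genomic profiling of
    colorectal cancer: variant hard-filtering and tumor mutational burden (TMB)
    with hypermutation gating, LASSO-based refitting of 96-context mutational
    signatures against a reference catalog, consensus non-negative matrix
    factorization (NMF) subtyping of non-hypermutated samples with a
    10q11.21-amplification rule separating high- and low-risk chromosomal
    instability, a neoantigen immunoediting score with HLA loss-of-heterozygosity
    and immunogenicity-reduction calls, and a purity/ploidy-corrected
    mitochondrial copy-number score (mScore) with a qPCR transfer path.
    Includes a synthetic-cohort generator so every stage is testable without
    access to restricted patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
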