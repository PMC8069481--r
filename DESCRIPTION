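Package: relapseEvo
Title: Genomic Scar Scores, Clonal Architecture and Actionability for
    Paired Primary/Relapse Tumors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream genomic analysis of paired primary/relapse tumor
    lesions from allele-specific copy-number segments, somatic/germline
    mutation tables and clone trees with per-sample cancer cell fractions.
    Implements the three homologous-recombination-deficiency (HRD) scar
    scores (HRD-LOH, telomeric allelic imbalance, large-scale state
    transitions), chromosomal-instability and whole-genome-doubling calls,
    bi-allelic HR-gene alteration classification, clone-tree diversity
    indices and evolution-model classification, de novo mutational
    signature extraction by non-negative matrix factorization with cosine
    catalog matching, and an actionability report. A synthetic-cohort
    generator with a full ground-truth ledger makes every stage testable
    without access to protected sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
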