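Package: snpcons
Title: Conservation-Based Pathogenicity and Phenotype Classification of Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline classification of non-synonymous single nucleotide
    polymorphisms (nsSNPs) from locally supplied per-gene resources.
    Implements a weighted protein conservation (WPC) score over combined
    ortholog and paralog alignments, a PSIC-style positional profile score,
    BLOSUM62 substitution scoring, protein/CDS codon coordinate mapping with
    a nonsense-mediated-decay stop-gain rule, functional-hotspot detection
    and phenotype prediction from a curated known-variant table, a stepwise
    pathogenicity decision pipeline, and the cutpoint-training machinery
    (ROC curves, balanced accuracy, gene-grouped cross-validation) used to
    calibrate the pipeline thresholds. A seeded synthetic-fixture generator
    provides a fully offline test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
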