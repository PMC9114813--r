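Package: orphanforge
Title: Orphan Gene Discovery and Characterization from Comparative Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for identifying orphan genes (lineage-specific
    genes with no detectable homolog outside their own species) from genome
    packages, and for characterizing them. Provides a sequential
    homology-filter cascade over an ordered panel of reference databases
    backed by a seed-and-extend local aligner with Karlin-Altschul E-values;
    gene-structure statistics and group contrasts; origin-mechanism
    classification (five duplication modes via paralog detection and
    collinearity chaining, gene overlap, transposable-element exaptation,
    and de novo birth) with Nei-Gojobori Ks dating under a molecular clock;
    and expression-based function inference (FPKM, differential expression,
    SPM tissue specificity, fuzzy c-means trend clustering, weighted
    co-expression modules, and hypergeometric pathway enrichment). A
    synthetic-data module generates genome packages, reference panels and
    count matrices with planted ground truth so the whole pipeline is
    testable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
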