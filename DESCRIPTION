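Package: mbrobust
Title: Host Decontamination of Microbial Reference Databases and
    Robustness Checks for Microbiome Classifiers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for auditing host contamination in metagenomic
    reference databases and the robustness of downstream analyses. Provides
    an exhaustive sliding-window algorithm that locates and masks
    host-derived sequence in microbial reference databases; a paired-end
    read simulation harness that estimates how many host-only reads leak
    through a host-depletion and database-mapping pipeline as false-positive
    microbial signal; conservative two-step taxon filtering
    (human-association whitelists, read and unique-k-mer thresholds,
    aggregate genome-coverage thresholds); and a feature-concordance
    statistical framework (Fisher exact tests on used/unused feature sets,
    Kendall rank correlation with unused features tied at rank k+1, Fisher's
    method across batches, Benjamini-Hochberg adjustment, and AUROC/AUPR
    confidence-interval equivalence) for comparing machine-learning
    classifiers trained on variants of the same data. A synthetic-fixture
    module generates every input with known ground truth so the full
    toolkit is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    IRanges,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
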