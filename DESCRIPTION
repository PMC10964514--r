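Package: glicomix
Title: Genotype Demultiplexing and Microenvironment Analysis for Tumor-Organoid Co-Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the growth of a minor tumor genotype inside cerebral
    organoid co-cultures from single-cell and bulk sequencing. Provides a
    synthetic-data generator for two-genotype droplet experiments with known
    ground truth; quality control, normalization, variable-gene selection and
    marker detection for single-cell counts; a reference-free two-genotype EM
    demultiplexer over expressed SNP allele counts with inferred-CNV component
    labeling and nearest-neighbor rescue; mutually exclusive germline SNP
    fingerprint panels and bulk mixture detection; bin-matched gene-signature
    scoring with exact rank tests; pseudo-bulk developmental staging against an
    age-graded reference with cluster specificity scores; and a permutation
    test for receptor-ligand crosstalk between cell-type clusters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
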