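Package: clonephene
Title: Longitudinal Tumor Subclone Reconstruction and Phenotype-Targeted
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the clonal evolution of serially sampled tumors
    and links it to drug-targetable phenotypes. Adjusts variant allele
    frequencies for normal-cell contamination by copy-number peak matching,
    clusters copy-neutral somatic mutations by cross-timepoint presence,
    derives cancer cell fractions by kernel density estimation, and
    enumerates and merges subclone trees under the sum rule. Builds
    96-channel trinucleotide mutation spectra and deconvolves them against
    a signature catalog by greedy forward selection. Infers large-scale
    copy-number alterations in single cells from windowed expression
    averages, assigns cells to survivor or disappearing subclones, screens
    single cells against gene-set collections with ssGSEA, and assesses
    drug-combination synergy by Bliss independence. A synthetic-data
    generator with known ground truth makes every stage testable without
    controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    Matrix,
    mclust,
    minpack.lm,
    Rsamtools,
    stats,
    utils,
    vcfR
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
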