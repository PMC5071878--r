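Package: rankimpute
Title: Genotype Imputation by Low-Rank Matrix Completion and Co-Clustering Factorization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fills missing entries of sample-by-SNP genotype (0/1/2) or
    haplotype (0/1) matrices by exploiting their approximate low rank.
    Two solver families are provided: nuclear-norm matrix completion via
    fixed-point continuation with singular-value soft-thresholding,
    including a sliding-window variant for long SNP panels, and a matrix
    co-clustering factorization A ~ Y1 X Y2' optimized by four
    block-coordinate-update schemes (BCU-1, BCU-2, BCU-3 and a
    maximum-block-improvement variant). Utilities cover stacking of
    reference and study panels typed on heterogeneous SNP chips, uniform
    and systematic (chip-mismatch) masking, rounding of raw output to
    genotype codes, allelic-imputation error evaluation, and a mosaic
    haplotype simulator that realizes the linkage-disequilibrium low-rank
    structure the solvers assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
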