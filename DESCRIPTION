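Package: PeakHamming
Title: Hamming-Distance Clustering and Cell-Type Classification of
    Chromatin Accessibility Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Systematic clustering of genome-wide chromatin accessibility
    (ATAC-seq) samples from their peak calls alone. Each sample's genome is
    binarized from its top-ranked peaks (ranked by peak-calling p-value,
    truncated at a rank threshold M_cut), pairwise sample differences are
    quantified by the Hamming distance between binary tracks computed
    exactly on interval representations, and samples are clustered by
    agglomerative hierarchical clustering with explicitly defined
    set-distance functions (UPGMA and Ward, plus WPGMA/UPGMC/WPGMC
    variants). Labeled dendrograms are scored with a type/global penalty
    cost function, the (M_cut, p_G) parameter pair is optimized by grid
    search with a plateau-midpoint rule, and new samples (for example
    leukemic cells) are classified by their closest reference cell type
    under the Ward set distance, with full type rankings and rank gaps.
    Also included: read-downsampling robustness analysis, ChromHMM-style
    functional annotation profiles of ranked peaks, and a seeded synthetic
    cohort generator with a toy peak caller for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'PeakHamming-package.R'
    'annotation.R'
    'classification.R'
    'clustering.R'
    'genome-layout.R'
    'hamming.R'
    'io-peaks.R'
    'macs2.R'
    'optimization.R'
    'penalty.R'
    'ranking.R'
    'segmentation.R'
    'synthetic.R'
    'utils.R'
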