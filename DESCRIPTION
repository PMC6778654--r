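Package: ascnclone
Title: Allele-Specific Copy Number, Ploidy, Purity, and Clonality from
    Matched Tumor/Normal Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes segmented copy-number profiles and SNP pileups from
    matched tumor/normal DNA sequencing experiments. Estimates the
    per-segment fraction of allelically neutral reads (beta) from
    heterozygous germline SNPs with a folded binomial mixture likelihood,
    derives sample ploidy from the logR shift of allelically balanced
    segments, quantifies DNA admixture from the most clonal hemizygous
    deletions, converts (beta, logR) pairs into fractional and integer
    allele-specific copy numbers, and scores the clonality of somatic
    copy-number aberrations and single-nucleotide variants. A synthetic
    tumor simulator with known ground truth supports calibration and
    validation, and diagnostic beta-vs-logR lattice plots help interpret
    ploidy and admixture estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    parallel,
    ggplot2,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
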