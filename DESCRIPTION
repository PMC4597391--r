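Package: remreg
Title: Prediction of Remotely Acting Gene-Regulatory Elements from Hi-C
    and Epigenomic Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a six-step in silico procedure for locating
    remotely acting gene-regulatory elements. Binned intra-chromosomal
    Hi-C contact counts are ranked around a gene of interest; the most
    strongly interacting fragments are refined to a search region bounded
    by CTCF insulator binding sites; the region is intersected with
    epigenomic evidence tracks (H3K4me1, H3K4me3 and H3K27ac histone
    marks, DNaseI hypersensitivity, transcription-factor binding sites,
    enhancer and chromatin-state calls) to emit classified candidate
    regulatory regions; and candidates are validated against chromatin
    loop calls linking them to the gene promoter. Patient variants
    falling inside predicted regions are annotated with containment,
    feature overlap, evolutionary conservation and cohort allele
    frequencies, alongside small utilities for bisulphite methylation
    summaries. A synthetic-locus generator builds a fully worked example
    locus as well as randomized loci with planted regulatory elements for
    benchmarking, so the whole pipeline runs without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    vcfR,
    withr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
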