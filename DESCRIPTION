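Package: fldsr
Title: Strand-Specific Recovery of Complete RNA Viral Genomes from dsRNA
    Sequencing Libraries
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Informatics workflow for fragmented and primer-ligated dsRNA
    sequencing (FLDS) libraries: clean-read processing (sliding-window quality
    trimming, cDNA-synthesis adaptor trimming, adaptor-dimer detection, PCR
    duplicate and low-complexity removal, fixed-depth downsampling), strand
    orientation of reads from ligated adaptor signatures, identification of
    viral genome and genome-segment termini by adaptor-junction position
    counting with a one-sided Smirnov-Grubbs outlier test, depth and breadth
    of coverage summaries, contig assembly statistics, and dsRNA
    quantification by linear standard curve. Includes a synthetic FLDS
    library simulator (segmented viral communities with shared terminal
    sequences, fragmentation, adaptor ligation, PCR artifacts, paired-end
    reads with a per-base error model) that provides full ground truth for
    end-to-end validation without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
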