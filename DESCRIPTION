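Package: metaprof
Title: Reference-Based Metagenome Profiling and Sample Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns untargeted shotgun sequencing reads aligned to an
    arbitrary reference contig set into per-sample "metagenome profiles"
    (vectors of read counts per contig) and compares samples on that basis.
    Provides FASTQ quality trimming by mean Phred score, SAM/BAM alignment
    counting, library normalisation by subsampling, hierarchical clustering
    of profiles (Canberra and presence/absence distances, Ward linkage) with
    multiscale-bootstrap edge support (bootstrap probability and
    approximately unbiased p-values), crossed random-effects
    variance-component analysis of profile counts, per-contig
    differential-representation tests with an empirical false discovery
    rate, sequencing-depth sufficiency analysis, and a synthetic-community
    simulator that generates count matrices, reads and truth alignments for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    S4Vectors,
    Rsamtools,
    ape,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
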