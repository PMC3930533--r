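Package: matephase
Title: Read-Backed Gene Phasing from Mate-Pair and Paired-End Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves the cis/trans configuration of heterozygous variants
    within a gene from mate-pair and paired-end sequencing reads. Fragments
    whose reads cover two heterozygous positions vote in a 4x4 base-call
    association matrix; row-wise multinomial bootstrap resampling with an
    injected error mass yields phase probabilities with percentile
    confidence intervals, and matrices over successive sites are chained,
    Markov-style, into whole-amplicon haplotypes with cumulative
    probabilities and a confidence-interval overlap verdict. Includes a
    diploid amplicon read simulator (PCR-chimera and base-call error
    models, SAM plus truth output), linked-coverage profiling, and
    recombinant/random error decomposition.
License: MIT
Encoding: UTF-8
Imports:
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Biostrings,
    Rsamtools,
    S4Vectors,
    vcfR,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
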