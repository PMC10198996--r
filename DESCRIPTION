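Package: startscan
Title: Discovery and Evolutionary Analysis of Novel Start Codons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for discovering novel translation start codons in a
    reference genome, at two evolutionary depths. At the population level it
    identifies start-gain single-nucleotide variants: 5'UTR variants that
    convert a non-AUG triplet into an in-frame upstream AUG with no
    intervening stop codon before the annotated start. At the species level
    it identifies fixed, lineage-specific start codons from pairwise
    whole-genome alignments against three outgroup genomes, with a
    population-fixation check. Translation initiation activity at novel and
    ancestral start codons is quantified from ribosome-profiling footprints
    via fixed P-site offsets, reads-per-million normalisation, per-codon
    occupancy and metagene profiles. Selection on the novel coding
    sequences is tested with Goldman-Yang style codon substitution branch
    models fitted by maximum likelihood and compared by likelihood-ratio
    tests. A synthetic-data generator emulates every input format at toy
    scale with planted ground truth, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    vcfR,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
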