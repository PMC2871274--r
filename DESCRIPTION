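Package: methylMapR
Title: Three-Letter Alignment and Methylation Calling for Bisulfite
    Sequencing Reads
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps bisulfite-converted short reads to a reference genome by
    collapsing reads and genome to a three-letter alphabet (C-to-T on the
    forward strands, G-to-A on the reverse complements), aligning across the
    four logical reference spaces with a complete pigeonhole seed-and-extend
    aligner, retaining only unique best alignments, recounting mismatches
    with the asymmetric bisulfite rule, and deriving per-cytosine methylation
    calls in CG, CHG and CHH contexts. Supports both the tagged
    (non-directional, four read forms) and directional (two read forms)
    library protocols. Includes a bisulfite read simulator with per-cytosine
    ground truth and an evaluator for mapability, accuracy and inferred
    methylation rates, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Alignment, DNAMethylation, Epigenetics, MethylSeq, Sequencing
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'RcppExports.R'
    'aligner.R'
    'cli.R'
    'io.R'
    'methcall.R'
    'methylMapR-package.R'
    'postprocess.R'
    'readprep.R'
    'refprep.R'
    'simulator.R'
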