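Package: ednabar
Title: Marine eDNA Metabarcoding with COI Minibarcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for environmental-DNA (eDNA) metabarcoding of marine
    metazoan communities with degenerate COI minibarcode and 18S rDNA (V8)
    primers. Implements IUPAC-degenerate in silico PCR and primer evaluation
    against barcode reference libraries, MID-tag design and validation,
    paired-end read merging with quality consensus, exact-tag demultiplexing,
    abundance-ratio graph denoising of dereplicated amplicons
    (head/internal/singleton classification), identity-threshold taxonomic
    assignment with lowest-common-ancestor tie resolution, and permutation
    community statistics (Mantel, PERMANOVA, PERMDISP, non-metric
    multidimensional scaling, rarefaction). A synthetic-data module emulates
    reference libraries, mock communities and error-prone tagged paired-end
    reads so the whole chain can be exercised without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
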