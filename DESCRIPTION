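Package: coitiler
Title: Tiled-Amplicon COI Barcode Recovery and Taxonomic Assignment for
    Museum Specimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for recovering cytochrome c oxidase subunit I (COI) DNA
    barcodes from degraded natural-history-collection specimens sequenced
    with tiled short-amplicon protocols. Implements sample-indexed (UMI)
    demultiplexing of pooled amplicon reads, quality and taxonomy
    filtering, alignment-free positional consensus assembly with
    ambiguity (N) fill between non-overlapping fragments, distance
    threshold taxonomic assignment against a reference barcode library
    (cluster taxonomy match and nearest-match identification rules), a
    96-well plate specimen data model, a synthetic degraded-read
    simulator for end-to-end testing, and success/reporting statistics
    including age-versus-recovered-length regression.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
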