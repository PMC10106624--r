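Package: chrysexer
Title: Sexing Cattle Samples from RNA-Seq Counts or In-Silico Multiplex PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring the sex of cattle samples (embryos,
    tissues) from bulk or low-input RNA-sequencing count data, using the
    cumulative counts-per-million (CPM) of a panel of chromosome-Y marker
    genes, together with the marker-discovery pipeline that identifies such
    panels (TMM normalization implemented from its published definition,
    abundance filtering, and negative-binomial two-group scoring). Also
    provides an in-silico twin of the companion multiplex PCR assay: primer
    site search with mismatch tolerance, amplicon enumeration, and band
    pattern interpretation (male-specific-Y amplicon plus autosomal
    control). A synthetic-data module generates negative-binomial count
    matrices with planted sex-specific chromosome-Y genes and synthetic
    male/female genomes with planted primer sites, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
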