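Package: barcoderef
Title: Build Clean, Taxonomically Harmonized DNA Barcode Reference Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assemble curated CO1 (cytochrome c oxidase subunit I)
    reference databases for DNA metabarcoding from heterogeneous source
    snapshots (GenBank flat files, BOLD data-package TSV, GBOL release CSV).
    Provides backbone-taxonomy import (GBIF- and NCBI-style dumps) with
    synonym and homonym resolution, open-nomenclature name cleaning,
    taxonomic harmonization with higher-rank fallback, sequence-quality,
    translation and geographic filtering, taxonomy-aware dereplication with
    lowest-common-ancestor tie-breaking, writers for classifier formats
    (SINTAX, dada2, qiime2, kraken2), a top-hit identity distribution
    benchmark with dense-rank summaries and subsample cross-coverage, and a
    deterministic synthetic fixture generator with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
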