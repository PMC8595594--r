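Package: eqtlpath
Title: Tissue-Specific eQTL Pathway Enrichment for Trait-Associated
    Genomic Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links trait-associated genomic intervals to biological
    pathways through tissue-specific eQTL catalogs instead of physical
    proximity. Query regions are built by flanking GWAS variants and
    merging overlaps; eQTLs falling inside the regions are mapped to
    their target genes (eGenes), and every pathway in a gene-set
    collection is tested for eGene over-representation with a one-sided
    Fisher's exact test, adjusted by the Benjamini-Hochberg procedure.
    Ships readers for GMT gene-set collections, per-tissue eQTL tables
    and gene-identifier maps; exporters for tissue-by-pathway
    significance matrices, heatmaps and gene-hit reports; and a seeded
    synthetic-data generator with planted tissue-pathway signals for
    power and type-I-error validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
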