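# Small in-code fixtures shared across test files.

tiny_catalog <- function(tissue = "amygdala",
                         variant_id = sprintf("snp%02d", seq_along(pos)),
                         chrom = rep("chr1", length(pos)),
                         pos, egene, pvalue = rep(1e-6, length(pos)),
                         p_threshold = 1e-4) {
  eqtlpath:::new_eqtl_catalog(
    tissue = tissue,
    records = data.frame(variant_id = variant_id, chrom = chrom,
                         pos = as.integer(pos), egene = egene,
                         pvalue = pvalue, stringsAsFactors = FALSE),
    p_threshold = p_threshold
  )
}

tiny_collection <- function(sets, name = "TESTDB", source = name) {
  urls <- stats::setNames(rep("http://example.org", length(sets)), names(sets))
  eqtlpath:::new_geneset_collection(name = name, source = source,
                                    sets = sets, urls = urls)
}

tiny_regions <- function(chrom = "chr1", start = 0L, end = 1000L,
                         trait = "test_trait") {
  structure(list(trait = trait,
                 intervals = genomic_intervals(chrom, start, end),
                 flank_bp = 0L),
            class = "query_region_set")
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
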