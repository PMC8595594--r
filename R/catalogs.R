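#' Read a GMT gene-set collection
#'
#' Parses the MSigDB GMT dialect: one gene set per line, tab-separated as
#' `name<TAB>description/URL<TAB>member1<TAB>member2...`. Duplicate member
#' ids within a line are deduplicated; empty member lists and duplicate set
#' names are rejected.
#'
#' @param path Path to the GMT file.
#' @param name Collection label (default: file name without extension).
#' @param source Database label attached to every set (e.g. `"KEGG"`,
#'   `"REACTOME"`); defaults to the collection label.
#' @return A `geneset_collection`: list with `name`, `source`, `sets`
#'   (named list of character vectors), `url` (named character) and
#'   `universe` (sorted union of all members).
#' @export
read_gmt <- function(path,
                     name = toupper(tools::file_path_sans_ext(basename(path))),
                     source = name) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  urls <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, " in ", path,
           ": expected >= 3 tab-separated fields")
    }
    set_name <- fields[[1L]]
    if (set_name %in% names(sets)) {
      stop("duplicate gene-set name '", set_name, "' at GMT line ", i)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop("empty member list for gene set '", set_name, "' at GMT line ", i)
    }
    sets[[set_name]] <- members
    urls[[set_name]] <- fields[[2L]]
  }
  new_geneset_collection(name = name, source = source, sets = sets, urls = urls)
}

new_geneset_collection <- function(name, source, sets, urls) {
  stopifnot(is.list(sets))
  if (anyDuplicated(names(sets))) stop("gene-set names must be unique")
  if (any(vapply(sets, length, 0L) == 0L)) stop("gene sets must be non-empty")
  urls <- urls[names(sets)]
  names(urls) <- names(sets)
  structure(
    list(name = name, source = source, sets = sets, url = urls,
         universe = sort(unique(unlist(sets, use.names = FALSE)))),
    class = "geneset_collection"
  )
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection '%s' (%s): %d set(s), %d gene(s) in universe\n",
              x$name, x$source, length(x$sets), length(x$universe)))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param coll A `geneset_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "geneset_collection"))
  url <- coll$url
  url[is.na(url)] <- ""
  lines <- vapply(names(coll$sets), function(nm) {
    paste(c(nm, url[[nm]], coll$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene-set collection as a two-file bundle
#'
#' Splits a collection into two tab-separated text documents: a links file
#' (`<name>_links.tsv`: set name, description URL) and a members file
#' (`<name>_members.tsv`: set name followed by its member gene ids). The
#' pair round-trips through [read_geneset_bundle()].
#'
#' @param coll A `geneset_collection`.
#' @param dir Output directory (created if absent).
#' @return Character vector of the two paths written (links, members).
#' @export
write_geneset_bundle <- function(coll, dir) {
  stopifnot(inherits(coll, "geneset_collection"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  links_path <- file.path(dir, paste0(coll$name, "_links.tsv"))
  members_path <- file.path(dir, paste0(coll$name, "_members.tsv"))
  url <- coll$url
  url[is.na(url)] <- ""
  writeLines(paste(names(coll$sets), url[names(coll$sets)], sep = "\t"),
             links_path)
  writeLines(vapply(names(coll$sets), function(nm) {
    paste(c(nm, coll$sets[[nm]]), collapse = "\t")
  }, character(1)), members_path)
  invisible(c(links = links_path, members = members_path))
}

#' Read a two-file gene-set bundle
#'
#' @param links_path Path to the links file (set name, URL).
#' @param members_path Path to the members file (set name, member ids).
#' @param name Collection label (default: inferred from the members file
#'   name).
#' @param source Database label (default: the collection label).
#' @return A `geneset_collection`.
#' @export
read_geneset_bundle <- function(links_path, members_path,
                                name = sub("_members$", "",
                                           tools::file_path_sans_ext(basename(members_path))),
                                source = name) {
  link_lines <- readLines(links_path)
  link_lines <- link_lines[nzchar(trimws(link_lines))]
  urls <- character(0)
  for (ln in link_lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    urls[[fields[[1L]]]] <- if (length(fields) >= 2L) fields[[2L]] else ""
  }
  member_lines <- readLines(members_path)
  member_lines <- member_lines[nzchar(trimws(member_lines))]
  sets <- list()
  for (i in seq_along(member_lines)) {
    fields <- strsplit(member_lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) {
      stop("malformed bundle members line ", i, " in ", members_path)
    }
    if (fields[[1L]] %in% names(sets)) {
      stop("duplicate gene-set name '", fields[[1L]], "' at members line ", i)
    }
    sets[[fields[[1L]]]] <- unique(fields[-1L])
  }
  new_geneset_collection(name = name, source = source, sets = sets, urls = urls)
}

#' Read a canonical per-tissue eQTL table
#'
#' The ingestion contract is a long-format TSV with header columns
#' `variant_id`, `chrom`, `pos_1based`, `gene_id`, `tissue`, `pvalue` —
#' one row per (variant, eGene, tissue) association with its nominal
#' p-value. Records are filtered at `pvalue <= p_threshold` (inclusive,
#' matching the convention of retaining significance *at* the threshold),
#' optionally remapped to a canonical gene namespace, and duplicate
#' (variant, eGene) rows within a tissue are collapsed to the smallest
#' p-value. Counts of excluded records are logged via [message()].
#'
#' @param path Path to the TSV (gz-transparent).
#' @param p_threshold Nominal p-value filter applied at load
#'   (default `1e-4`).
#' @param gene_map Optional `gene_id_map` (see [read_gene_map()]); when
#'   given, `gene_id` values are mapped to `target` ids and unmapped
#'   records are dropped with a logged count.
#' @param target Gene namespace to map into when `gene_map` is supplied
#'   (default `"entrez"`, the engine's canonical namespace).
#' @return A named list of `eqtl_catalog` objects, one per tissue, sorted
#'   by tissue name. Each catalog carries `tissue`, `records` (a
#'   `data.frame` with `variant_id`, `chrom`, `pos`, `egene`, `pvalue`),
#'   `p_threshold` and `egene_universe`.
#' @export
read_eqtl_table <- function(path, p_threshold = 1e-4, gene_map = NULL,
                            target = "entrez") {
  stopifnot(length(p_threshold) == 1L, p_threshold > 0, p_threshold <= 1)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("variant_id", "chrom", "pos_1based", "gene_id", "tissue", "pvalue")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("eQTL table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  n_total <- nrow(df)
  p <- suppressWarnings(as.numeric(df$pvalue))
  bad <- is.na(p) | p < 0 | p > 1
  if (any(bad)) {
    message("read_eqtl_table: dropped ", sum(bad),
            " record(s) with unparseable or out-of-range p-values")
    df <- df[!bad, , drop = FALSE]
    p <- p[!bad]
  }
  gene <- as.character(df$gene_id)
  if (!is.null(gene_map)) {
    mapped <- map_gene_ids(gene, gene_map, target = target, from = "ensembl")$mapped
    unmapped <- is.na(mapped)
    if (any(unmapped)) {
      message("read_eqtl_table: dropped ", sum(unmapped),
              " record(s) with unmappable gene ids")
    }
    df <- df[!unmapped, , drop = FALSE]
    p <- p[!unmapped]
    gene <- mapped[!unmapped]
  }
  keep <- p <= p_threshold
  message("read_eqtl_table: retained ", sum(keep), "/", n_total,
          " record(s) at p <= ", format(p_threshold))
  df <- df[keep, , drop = FALSE]
  p <- p[keep]
  gene <- gene[keep]
  rec <- data.frame(
    variant_id = as.character(df$variant_id),
    chrom = as.character(df$chrom),
    pos = as.integer(df$pos_1based),
    egene = gene,
    pvalue = p,
    tissue = as.character(df$tissue),
    stringsAsFactors = FALSE
  )
  # collapse duplicate (variant, egene) pairs within a tissue to the min p
  key <- paste(rec$tissue, rec$variant_id, rec$egene, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, rec$pvalue)
    rec <- rec[ord, , drop = FALSE]
    dup <- duplicated(key[ord])
    message("read_eqtl_table: collapsed ", sum(dup),
            " duplicate (variant, eGene, tissue) record(s) to the smallest p")
    rec <- rec[!dup, , drop = FALSE]
  }
  tissues <- sort(unique(rec$tissue))
  out <- lapply(tissues, function(t) {
    r <- rec[rec$tissue == t, c("variant_id", "chrom", "pos", "egene", "pvalue")]
    rownames(r) <- NULL
    new_eqtl_catalog(tissue = t, records = r, p_threshold = p_threshold)
  })
  stats::setNames(out, tissues)
}

new_eqtl_catalog <- function(tissue, records, p_threshold) {
  stopifnot(is.data.frame(records),
            all(c("variant_id", "chrom", "pos", "egene", "pvalue") %in% names(records)))
  if (nrow(records) > 0L) {
    stopifnot(all(records$pvalue >= 0), all(records$pvalue <= p_threshold),
              all(records$pos >= 1L))
  }
  structure(
    list(tissue = tissue, records = records, p_threshold = p_threshold,
         egene_universe = sort(unique(records$egene))),
    class = "eqtl_catalog"
  )
}

#' @export
print.eqtl_catalog <- function(x, ...) {
  cat(sprintf("eqtl_catalog '%s': %d record(s), %d eGene(s), p <= %s\n",
              x$tissue, nrow(x$records), length(x$egene_universe),
              format(x$p_threshold)))
  invisible(x)
}

#' Read a gene-identifier mapping table
#'
#' An offline replacement for live annotation queries: a TSV with header
#' columns `ensembl_id`, `entrez_id`, `symbol`. Rows whose Ensembl id maps
#' to more than one Entrez id are ambiguous and dropped with a logged
#' count.
#'
#' @param path Path to the TSV.
#' @return A `gene_id_map` data.frame.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("ensembl_id", "entrez_id", "symbol")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("gene map ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[, need]
  df <- unique(df)
  amb <- df$ensembl_id %in% df$ensembl_id[duplicated(df$ensembl_id)]
  if (any(amb)) {
    message("read_gene_map: dropped ", sum(amb),
            " ambiguous row(s) (ensembl id with multiple entrez ids)")
    df <- df[!amb, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("gene_id_map", "data.frame")
  df
}

#' Map gene identifiers between namespaces
#'
#' Looks identifiers up in an offline mapping table. Ensembl version
#' suffixes (`".N"`) are stripped before lookup. Unmapped ids are reported
#' as `NA`, never silently dropped.
#'
#' @param ids Character vector of input identifiers.
#' @param map A `gene_id_map` (see [read_gene_map()]).
#' @param target Target namespace: `"entrez"`, `"symbol"` or `"ensembl"`.
#' @param from Input namespace (default `"ensembl"`).
#' @return A `data.frame` with columns `input` and `mapped`
#'   (`NA` = missing).
#' @export
map_gene_ids <- function(ids, map, target = c("entrez", "symbol", "ensembl"),
                         from = c("ensembl", "entrez", "symbol")) {
  target <- match.arg(target)
  from <- match.arg(from)
  stopifnot(inherits(map, "gene_id_map"))
  col <- c(entrez = "entrez_id", symbol = "symbol", ensembl = "ensembl_id")
  key <- as.character(ids)
  if (from == "ensembl") key <- sub("\\.\\d+$", "", key)
  idx <- match(key, map[[col[[from]]]])
  data.frame(input = as.character(ids), mapped = map[[col[[target]]]][idx],
             stringsAsFactors = FALSE)
}

#' Read a cytoband annotation table
#'
#' @param path TSV with header columns `chrom`, `start`, `end`, `band`
#'   (0-based half-open; band like `"p12.3"`).
#' @return A `data.frame` of bands.
#' @export
read_cytobands <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "band")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("cytoband table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  data.frame(chrom = as.character(df$chrom), start = as.integer(df$start),
             end = as.integer(df$end), band = as.character(df$band),
             stringsAsFactors = FALSE)
}
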