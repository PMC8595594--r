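#' Filter enrichment results by significance
#'
#' @param results An `enrichment_results` data.frame.
#' @param threshold Significance threshold in `(0, 1]` (default `1e-4`,
#'   the shipped result filter); the comparison is inclusive (`<=`).
#' @param on `"adjusted"` (default: filter on BH-adjusted p, which is what
#'   the result tables and heatmaps display) or `"raw"`.
#' @return The retained rows, sorted ascending by the filtered p-value.
#' @export
filter_results <- function(results, threshold = 1e-4,
                           on = c("adjusted", "raw")) {
  on <- match.arg(on)
  stopifnot(length(threshold) == 1L, threshold > 0, threshold <= 1)
  p <- if (on == "adjusted") results$p_adj else results$p_raw
  out <- results[p <= threshold, , drop = FALSE]
  p <- p[p <= threshold]
  out <- out[order(p, out$pathway, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the tissue-by-pathway significance matrix
#'
#' Rows are tissues, columns are pathways (prefixed by their source
#' database), values are `-log10(p_adj)` with `p_adj` floored at `1e-300`
#' so every value is finite. Cells for which no test was performed are
#' `NA` (masked).
#'
#' @param results An `enrichment_results` data.frame.
#' @param filter_columns Keep only pathways with at least one cell passing
#'   `threshold` (default `FALSE`).
#' @param threshold Column filter threshold on `p_adj` (default `1e-4`).
#' @return A `result_matrix`: list with `values` (numeric matrix with
#'   dimnames), `row_labels`, `col_labels` and `mask` (logical matrix,
#'   `TRUE` = untested).
#' @export
build_result_matrix <- function(results, filter_columns = FALSE,
                                threshold = 1e-4) {
  if (is.null(results) || nrow(results) == 0L) {
    warning("no results; returning empty matrix")
    v <- matrix(numeric(0), nrow = 0, ncol = 0)
    return(structure(list(values = v, row_labels = character(0),
                          col_labels = character(0),
                          mask = matrix(logical(0), 0, 0)),
                     class = "result_matrix"))
  }
  rows <- sort(unique(results$tissue))
  colkey <- paste(results$source, results$pathway, sep = ":")
  cols <- sort(unique(colkey))
  v <- matrix(NA_real_, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  v[cbind(match(results$tissue, rows), match(colkey, cols))] <-
    -log10(pmax(results$p_adj, 1e-300))
  if (filter_columns) {
    keep <- apply(v, 2L, function(x) any(x >= -log10(threshold), na.rm = TRUE))
    v <- v[, keep, drop = FALSE]
  }
  structure(list(values = v, row_labels = rownames(v),
                 col_labels = colnames(v), mask = is.na(v)),
            class = "result_matrix")
}

#' @export
print.result_matrix <- function(x, ...) {
  cat(sprintf("result_matrix: %d tissue(s) x %d pathway(s), %d masked cell(s)\n",
              nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

#' Export a significance matrix as TSV (and optionally a heatmap image)
#'
#' The TSV is the contract: header row of pathway labels, one data row per
#' tissue, full float precision, masked cells empty. Re-reading with
#' [read_result_matrix()] reproduces the matrix exactly. The optional
#' image renders the matrix with a blue (low) to red (high) palette —
#' strong enrichments show red; it is cosmetic, not part of the contract.
#'
#' @param matrix A `result_matrix`.
#' @param path Output TSV path.
#' @param image Also render a PNG heatmap (default `FALSE`).
#' @param image_path PNG path (default: `path` with extension `.png`).
#' @return Invisibly, the TSV path.
#' @export
export_heatmap <- function(matrix, path, image = FALSE,
                           image_path = paste0(tools::file_path_sans_ext(path), ".png")) {
  stopifnot(inherits(matrix, "result_matrix"))
  v <- matrix$values
  if (length(v) == 0L && nrow(v) == 0L) stop("cannot export an empty matrix")
  cells <- apply(v, c(1L, 2L), function(x) {
    if (is.na(x)) "" else sprintf("%.17g", x)
  })
  header <- paste(c("tissue", colnames(v)), collapse = "\t")
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], cells[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  if (image) {
    grDevices::png(image_path, width = 520 + 24 * ncol(v),
                   height = 420 + 24 * nrow(v))
    op <- graphics::par(mar = c(9, 11, 2, 2))
    pal <- grDevices::colorRampPalette(c("blue3", "white", "red3"))(101)
    z <- t(v[rev(seq_len(nrow(v))), , drop = FALSE])
    graphics::image(x = seq_len(ncol(v)), y = seq_len(nrow(v)), z = z,
                    col = pal, axes = FALSE, xlab = "", ylab = "")
    graphics::axis(1, at = seq_len(ncol(v)), labels = colnames(v), las = 2,
                   cex.axis = 0.7)
    graphics::axis(2, at = seq_len(nrow(v)), labels = rev(rownames(v)),
                   las = 2, cex.axis = 0.7)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(path)
}

#' Read back a significance-matrix TSV
#'
#' @param path TSV written by [export_heatmap()].
#' @return A `result_matrix`.
#' @export
read_result_matrix <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  cols <- header[-1L]
  rows <- character(0)
  v <- matrix(NA_real_, nrow = length(lines) - 1L, ncol = length(cols))
  for (i in seq_along(lines)[-1L]) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- c(fields, rep("", length(cols) + 1L - length(fields)))
    rows[i - 1L] <- fields[[1L]]
    vals <- fields[-1L]
    v[i - 1L, nzchar(vals)] <- as.numeric(vals[nzchar(vals)])
  }
  dimnames(v) <- list(rows, cols)
  structure(list(values = v, row_labels = rows, col_labels = cols,
                 mask = is.na(v)),
            class = "result_matrix")
}

# band label for 0-based positions: "12p12.3" style (chrom sans "chr" + band)
cytoband_label <- function(chrom, pos, bands) {
  hit <- bands$chrom == chrom & bands$start <= pos & pos < bands$end
  if (!any(hit)) return(NA_character_)
  paste0(sub("^chr", "", chrom), bands$band[which(hit)[1L]])
}

#' Gene-hit report for significant tissue-pathway pairs
#'
#' One row per result, listing the hit genes (ordered by descending
#' in-region eQTL count, ties by name) and their genomic locations:
#' cytoband labels when a band table is supplied (a gene is located by the
#' band of its first in-region eQTL position), otherwise the
#' `chrom:start-end` of the containing query interval. Locations are
#' deduplicated in gene order. Genes with no resolvable location get
#' `"NA"` with a logged count.
#'
#' @param results An `enrichment_results` data.frame (typically after
#'   [filter_results()]).
#' @param catalogs Named list of `eqtl_catalog` objects (to locate hit
#'   genes via their in-region eQTLs).
#' @param regions A `query_region_set`.
#' @param bands Optional cytoband table (see [read_cytobands()]).
#' @param gene_map Optional `gene_id_map` for rendering gene symbols
#'   instead of canonical ids.
#' @return A `data.frame` with columns `tissue`, `pathway`, `hit_genes`,
#'   `locations`, `p_adj`.
#' @export
gene_hit_report <- function(results, catalogs, regions, bands = NULL,
                            gene_map = NULL) {
  idx <- build_interval_index(regions)
  iv <- if (inherits(regions, "query_region_set")) regions$intervals else regions
  # cache per-tissue in-region record tables
  tissue_cache <- new.env(parent = emptyenv())
  in_region_records <- function(tissue) {
    if (!exists(tissue, envir = tissue_cache)) {
      rec <- catalogs[[tissue]]$records
      rec <- rec[region_contains(idx, rec$chrom, rec$pos - 1L), , drop = FALSE]
      assign(tissue, rec, envir = tissue_cache)
    }
    get(tissue, envir = tissue_cache)
  }
  n_unlocated <- 0L
  rows <- lapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    genes <- strsplit(r$hit_genes, ";", fixed = TRUE)[[1L]]
    genes <- genes[nzchar(genes)]
    rec <- in_region_records(r$tissue)
    counts <- vapply(genes, function(g) sum(rec$egene == g), 0L)
    genes <- genes[order(-counts, genes)]
    locs <- vapply(genes, function(g) {
      grec <- rec[rec$egene == g, , drop = FALSE]
      if (nrow(grec) == 0L) return(NA_character_)
      pos0 <- grec$pos[1L] - 1L
      if (!is.null(bands)) {
        lab <- cytoband_label(grec$chrom[1L], pos0, bands)
        if (!is.na(lab)) return(lab)
      }
      cover <- iv$chrom == grec$chrom[1L] & iv$start <= pos0 & pos0 < iv$end
      if (!any(cover)) return(NA_character_)
      j <- which(cover)[1L]
      sprintf("%s:%d-%d", iv$chrom[j], iv$start[j] + 1L, iv$end[j])
    }, character(1))
    n_unlocated <<- n_unlocated + sum(is.na(locs))
    locs[is.na(locs)] <- "NA"
    shown <- genes
    if (!is.null(gene_map)) {
      sym <- map_gene_ids(genes, gene_map, target = "symbol", from = "entrez")$mapped
      shown <- ifelse(is.na(sym), genes, sym)
    }
    data.frame(
      tissue = r$tissue,
      pathway = paste(r$source, r$pathway, sep = " "),
      hit_genes = paste(shown, collapse = ";"),
      locations = paste(unique(locs), collapse = ", "),
      p_adj = r$p_adj,
      stringsAsFactors = FALSE
    )
  })
  if (n_unlocated > 0L) {
    message("gene_hit_report: ", n_unlocated, " gene(s) with no resolvable location")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tissue = character(0), pathway = character(0),
                      hit_genes = character(0), locations = character(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write enrichment results as TSV
#'
#' Columns: `tissue`, `source`, `pathway`, `a`, `b`, `c`, `d`,
#' `universe_size`, `p_raw`, `p_adj`, `hit_genes`, `hit_eqtl_count`.
#'
#' @param results An `enrichment_results` data.frame.
#' @param path Output path.
#' @export
write_results_tsv <- function(results, path) {
  out <- results
  out$p_raw <- sprintf("%.17g", out$p_raw)
  out$p_adj <- sprintf("%.17g", out$p_adj)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back an enrichment-results TSV
#'
#' @param path TSV written by [write_results_tsv()].
#' @return An `enrichment_results` data.frame.
#' @export
read_results_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("tissue", "source", "pathway", "hit_genes")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  class(df) <- c("enrichment_results", "data.frame")
  df
}
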