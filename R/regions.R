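#' Construct a table of genomic intervals
#'
#' Intervals use 0-based half-open coordinates (`[start, end)`), the same
#' convention as BED. All user-facing inputs with 1-based positions (variant
#' tables, eQTL tables) are converted at the read boundary.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector of 0-based inclusive start coordinates.
#' @param end Integer vector of 0-based exclusive end coordinates.
#' @param label Optional character vector of free-text provenance labels
#'   (e.g. source variant ids).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `label`.
#' @export
genomic_intervals <- function(chrom, start, end, label = NA_character_) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    label = rep_len(as.character(label), length(chrom)),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (anyNA(df$chrom) || any(!nzchar(df$chrom))) {
    stop("interval chromosome names must be non-empty")
  }
  if (anyNA(df$start) || anyNA(df$end)) stop("interval coordinates must not be NA")
  if (any(df$start < 0L)) stop("interval start must be >= 0")
  if (any(df$end <= df$start)) stop("interval end must be > start")
  invisible(df)
}

empty_intervals <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             label = character(0), stringsAsFactors = FALSE)
}

# 0-based half-open data.frame -> 1-based closed GRanges with sorted seqlevels
intervals_to_granges <- function(df) {
  lev <- sort(unique(df$chrom))
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = lev),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

granges_to_intervals <- function(gr, label = NA_character_) {
  df <- as.data.frame(gr)
  data.frame(
    chrom = as.character(df$seqnames),
    start = df$start - 1L,
    end = df$end,
    label = rep_len(as.character(label), nrow(df)),
    stringsAsFactors = FALSE
  )
}

#' Flank variants into symmetric query intervals
#'
#' Each variant (1-based position) becomes the half-open interval
#' `[max(0, pos - 1 - flank_bp), pos + flank_bp)`: the variant base plus
#' `flank_bp` on each side, clamped at the chromosome start. The unclamped
#' length is `2 * flank_bp + 1` bp.
#'
#' @param variants A `data.frame` with columns `chrom` and `pos` (1-based);
#'   an `id` column, if present, is carried into the interval labels.
#' @param flank_bp Non-negative flank size in bp on each side (default
#'   50,000, the standard GWAS-locus flanking window).
#' @return An interval `data.frame` (see [genomic_intervals()]), one row per
#'   variant, in input order.
#' @export
flank_variants <- function(variants, flank_bp = 50000L) {
  stopifnot(is.data.frame(variants), all(c("chrom", "pos") %in% names(variants)))
  flank_bp <- as.integer(flank_bp)
  if (length(flank_bp) != 1L || is.na(flank_bp) || flank_bp < 0L) {
    stop("'flank_bp' must be a single non-negative integer")
  }
  if (nrow(variants) == 0L) return(empty_intervals())
  pos <- as.integer(variants$pos)
  if (anyNA(pos) || any(pos < 1L)) stop("variant positions must be positive (1-based)")
  label <- if ("id" %in% names(variants)) as.character(variants$id) else NA_character_
  genomic_intervals(
    chrom = variants$chrom,
    start = pmax(0L, pos - 1L - flank_bp),
    end = pos + flank_bp,
    label = label
  )
}

#' Merge overlapping or abutting intervals
#'
#' Coalesces intervals per chromosome into the minimal sorted set of disjoint
#' intervals. Abutting half-open intervals (`end_i == start_j`) are merged.
#' Labels of merged inputs are concatenated with `","`. Total covered bp is
#' preserved.
#'
#' @param ivals An interval `data.frame` (see [genomic_intervals()]).
#' @return A sorted interval `data.frame` with pairwise-disjoint,
#'   non-abutting rows per chromosome.
#' @export
merge_intervals <- function(ivals) {
  if (!("label" %in% names(ivals))) ivals$label <- NA_character_
  if (nrow(ivals) == 0L) return(empty_intervals())
  validate_intervals(ivals)
  gr <- intervals_to_granges(ivals)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  red <- sort(red)
  revmap <- S4Vectors::mcols(red)$revmap
  labels <- vapply(as.list(revmap), function(i) {
    lab <- unique(ivals$label[i])
    lab <- lab[!is.na(lab) & nzchar(lab)]
    if (length(lab) == 0L) NA_character_ else paste(lab, collapse = ",")
  }, character(1))
  granges_to_intervals(red, label = labels)
}

#' Build merged query regions for one trait
#'
#' Flanks every variant of a trait by `flank_bp` on each side and merges the
#' resulting intervals ([flank_variants()] then [merge_intervals()]). The
#' number of output intervals is at most the number of variants.
#'
#' @param variants A `data.frame` with columns `chrom`, `pos` (1-based) and
#'   optionally `id` and `trait`; all rows must belong to a single trait.
#' @param flank_bp Flank size in bp per side (default 50,000).
#' @param chrom_sizes Optional `data.frame` with columns `chrom`, `size`
#'   enabling right clamping at chromosome ends; without it the right edge
#'   is not clamped (chromosome lengths unknown).
#' @return A `query_region_set`: list with elements `trait`, `intervals`
#'   (sorted, disjoint) and `flank_bp`.
#' @export
build_query_regions <- function(variants, flank_bp = 50000L, chrom_sizes = NULL) {
  trait <- NA_character_
  if (is.data.frame(variants) && "trait" %in% names(variants) && nrow(variants) > 0L) {
    tr <- unique(as.character(variants$trait))
    if (length(tr) > 1L) {
      stop("all variants must share one trait; got: ", paste(tr, collapse = ", "))
    }
    trait <- tr
  }
  if (nrow(variants) == 0L) {
    warning("empty variant list; returning empty query region set")
    return(structure(list(trait = trait, intervals = empty_intervals(),
                          flank_bp = as.integer(flank_bp)),
                     class = "query_region_set"))
  }
  iv <- flank_variants(variants, flank_bp = flank_bp)
  if (!is.null(chrom_sizes)) {
    stopifnot(all(c("chrom", "size") %in% names(chrom_sizes)))
    sz <- stats::setNames(as.integer(chrom_sizes$size), chrom_sizes$chrom)
    hit <- iv$chrom %in% names(sz)
    iv$end[hit] <- pmin(iv$end[hit], sz[iv$chrom[hit]])
    bad <- iv$end <= iv$start
    if (any(bad)) {
      message("dropped ", sum(bad), " interval(s) beyond chromosome ends")
      iv <- iv[!bad, , drop = FALSE]
    }
  }
  structure(
    list(trait = trait, intervals = merge_intervals(iv),
         flank_bp = as.integer(flank_bp)),
    class = "query_region_set"
  )
}

#' @export
print.query_region_set <- function(x, ...) {
  cat(sprintf("query_region_set: trait=%s, %d interval(s), flank=%d bp, %.0f bp covered\n",
              x$trait, nrow(x$intervals), x$flank_bp,
              sum(as.numeric(x$intervals$end - x$intervals$start))))
  invisible(x)
}

#' Build a fast interval-membership index over query regions
#'
#' Merges the input intervals, then stores per-chromosome sorted boundary
#' vectors so point and range queries reduce to a binary search
#' (`findInterval`), with answers identical to a linear scan.
#'
#' @param regions A `query_region_set` or interval `data.frame`.
#' @return An `interval_index` answering [region_contains()] and
#'   [region_overlaps()] queries.
#' @export
build_interval_index <- function(regions) {
  iv <- if (inherits(regions, "query_region_set")) regions$intervals else regions
  validate_intervals(iv)
  merged <- merge_intervals(iv)
  by_chrom <- lapply(split(merged[c("start", "end")], merged$chrom),
                     function(d) list(starts = d$start, ends = d$end))
  structure(list(by_chrom = by_chrom, intervals = merged),
            class = "interval_index")
}

# dispatch a per-chromosome query function over grouped query vectors
query_by_chrom <- function(idx, chrom, fun) {
  out <- logical(length(chrom))
  grp <- split(seq_along(chrom), chrom)
  for (ch in names(grp)) {
    tab <- idx$by_chrom[[ch]]
    if (!is.null(tab)) out[grp[[ch]]] <- fun(tab, grp[[ch]])
  }
  out
}

#' Point-membership query against an interval index
#'
#' @param idx An `interval_index` from [build_interval_index()].
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based positions.
#' @return Logical vector: `TRUE` where the position lies inside any indexed
#'   interval (`start <= pos < end`).
#' @export
region_contains <- function(idx, chrom, pos) {
  stopifnot(inherits(idx, "interval_index"), length(chrom) == length(pos))
  if (length(pos) == 0L) return(logical(0))
  query_by_chrom(idx, chrom, function(tab, i) {
    j <- findInterval(pos[i], tab$starts)
    j > 0L & pos[i] < tab$ends[pmax(j, 1L)]
  })
}

#' Range-overlap query against an interval index
#'
#' @param idx An `interval_index`.
#' @param chrom,start,end Vectors describing 0-based half-open query ranges.
#' @return Logical vector: `TRUE` where the range overlaps any indexed
#'   interval by at least 1 bp.
#' @export
region_overlaps <- function(idx, chrom, start, end) {
  stopifnot(inherits(idx, "interval_index"),
            length(chrom) == length(start), length(start) == length(end))
  if (any(end <= start)) stop("query ranges must satisfy end > start")
  if (length(start) == 0L) return(logical(0))
  query_by_chrom(idx, chrom, function(tab, i) {
    # intervals are disjoint and sorted: an overlap, if any, involves the
    # last interval starting at/before the query start or the one after it
    j <- findInterval(start[i], tab$starts)
    hit_left <- j > 0L & start[i] < tab$ends[pmax(j, 1L)]
    j2 <- pmin(j + 1L, length(tab$starts))
    hit_right <- j + 1L <= length(tab$starts) & tab$starts[j2] < end[i]
    hit_left | hit_right
  })
}

#' Read a trait-associated variant table
#'
#' Expects a tab-separated file with a header containing at least the columns
#' `trait`, `snp_id`, `chrom`, `pos_1based` (a PheGenI-export-compatible
#' subset); extra columns are ignored. Rows with missing or non-positive
#' chromosome/position are dropped with a logged count.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `trait`, `id`, `chrom`, `pos`.
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("trait", "snp_id", "chrom", "pos_1based")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("variant table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(df$pos_1based))
  bad <- is.na(df$chrom) | !nzchar(as.character(df$chrom)) | is.na(pos) | pos < 1L
  if (any(bad)) {
    message("read_variants: dropped ", sum(bad),
            " row(s) with unknown chromosome/position")
  }
  data.frame(
    trait = as.character(df$trait)[!bad],
    id = as.character(df$snp_id)[!bad],
    chrom = as.character(df$chrom)[!bad],
    pos = pos[!bad],
    stringsAsFactors = FALSE
  )
}

#' Write intervals as BED (0-based half-open)
#'
#' @param regions A `query_region_set` or interval `data.frame`.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  iv <- if (inherits(regions, "query_region_set")) regions$intervals else regions
  validate_intervals(iv)
  name <- iv$label
  name[is.na(name) | !nzchar(name)] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s", iv$chrom, iv$start, iv$end, name)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file into an interval table
#'
#' @param path Path to a BED file (first three or four columns used).
#' @return An interval `data.frame` with `label` taken from the BED name
#'   column when present.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file ", path, " must have >= 3 columns")
  label <- if (ncol(df) >= 4L) as.character(df[[4L]]) else NA_character_
  label[label == "."] <- NA_character_
  genomic_intervals(df[[1L]], df[[2L]], df[[3L]], label)
}

#' Read a two-column chrom.sizes table
#'
#' @param path Path to a headerless TSV with columns chromosome, length.
#' @return A `data.frame` with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("chrom.sizes file must have 2 columns")
  data.frame(chrom = as.character(df[[1L]]), size = as.integer(df[[2L]]),
             stringsAsFactors = FALSE)
}
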