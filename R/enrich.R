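#' Select eGenes whose eQTLs fall inside the query regions
#'
#' Scans a tissue catalog against an interval index and returns the distinct
#' eGenes of all records whose position lies inside any query interval.
#' Deduplication is essential: linkage disequilibrium makes many eQTLs
#' target the same eGene, so the enrichment test counts genes, not records.
#'
#' @param cat An `eqtl_catalog`.
#' @param idx An `interval_index` over the query regions.
#' @return List with `egenes` (sorted distinct in-region eGene ids) and
#'   `counts` (named integer: in-region eQTL records per eGene).
#' @export
select_in_region_egenes <- function(cat, idx) {
  stopifnot(inherits(cat, "eqtl_catalog"), inherits(idx, "interval_index"))
  rec <- cat$records
  if (nrow(rec) == 0L) {
    return(list(egenes = character(0), counts = integer(0)))
  }
  inreg <- region_contains(idx, rec$chrom, rec$pos - 1L)
  egenes <- sort(unique(rec$egene[inreg]))
  if (length(egenes) == 0L) {
    return(list(egenes = character(0), counts = integer(0)))
  }
  counts <- table(rec$egene[inreg])
  list(egenes = egenes,
       counts = stats::setNames(as.integer(counts[egenes]), egenes))
}

#' Build the 2x2 contingency table for one pathway
#'
#' Classifies every gene of the universe by (hit in regions?, member of
#' pathway?): `a` = hit and member, `b` = hit only, `c` = member only,
#' `d` = neither. Pathway members outside the universe are excluded from
#' the margins.
#'
#' @param hits Character vector of in-region eGene ids.
#' @param pathway Character vector of pathway member gene ids.
#' @param universe Character vector: the background gene universe.
#' @return A `contingency_table` list with fields `a`, `b`, `c`, `d` and
#'   `universe_size`.
#' @export
build_contingency <- function(hits, pathway, universe) {
  if (length(universe) == 0L) stop("empty gene universe")
  u <- unique(universe)
  h <- intersect(unique(hits), u)
  p <- intersect(unique(pathway), u)
  a <- length(intersect(h, p))
  b <- length(h) - a
  cc <- length(p) - a
  d <- length(u) - a - b - cc
  structure(list(a = a, b = b, c = cc, d = d, universe_size = length(u)),
            class = "contingency_table")
}

#' One-sided Fisher's exact test for enrichment
#'
#' Computes `P(A >= a)` under the hypergeometric null with the table's
#' margins fixed (alternative = "greater", i.e. over-representation).
#' Degenerate margins (no pathway genes in the universe, or no hits)
#' return `p = 1`.
#'
#' @param table A `contingency_table`, or the cell `a` when `b`, `c`, `d`
#'   are given separately.
#' @param b,c,d Optional cell counts when `table` is the scalar `a`.
#' @return The one-sided p-value in `[0, 1]`.
#' @export
fisher_one_sided_p <- function(table, b = NULL, c = NULL, d = NULL) {
  if (inherits(table, "contingency_table")) {
    a <- table$a; b <- table$b; c <- table$c; d <- table$d
  } else {
    a <- table
    stopifnot(!is.null(b), !is.null(c), !is.null(d))
  }
  fisher_one_sided_p_vec(a, b, c, d)
}

# vectorized workhorse: P(A >= a) with margins (a+b hits, a+c pathway genes)
fisher_one_sided_p_vec <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("contingency cells must be non-negative")
  p <- stats::phyper(a - 1, m = a + c, n = b + d, k = a + b,
                     lower.tail = FALSE)
  degenerate <- (a + c) == 0 | (a + b) == 0
  p[degenerate] <- 1
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Applies the step-up formula literally: with `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the
#' original input order (a suffix running minimum over the scaled sorted
#' p-values). Agrees with `stats::p.adjust(method = "BH")` to within
#' floating-point rounding of the scaling step.
#'
#' @param pvals Numeric vector of raw p-values, all in `[0, 1]`.
#' @return Adjusted p-values in the original input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must all lie in [0, 1]")
  }
  m <- length(pvals)
  o <- order(pvals)
  scaled <- pvals[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(scaled))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Enrichment scan of one tissue against one gene-set collection
#'
#' Identifies in-region eGenes once for the tissue, then tests every
#' pathway of the collection for eGene over-representation. The gene
#' universe is the tissue's eGene universe intersected with the
#' collection's gene universe: genes that can never be hit in the tissue,
#' or that belong to no pathway of the collection, carry no information
#' for the margins. BH adjustment is applied across the pathways of this
#' (tissue, collection) pair.
#'
#' @param cat An `eqtl_catalog`.
#' @param idx An `interval_index` over the query regions.
#' @param coll A `geneset_collection`.
#' @param counting_unit `"egene"` (default: distinct eGenes are the
#'   counting unit) or `"eqtl"` (raw eQTL records; exposed for
#'   comparison, inflated by linkage disequilibrium).
#' @return An `enrichment_results` data.frame, one row per pathway,
#'   sorted by `p_adj` then pathway name, with columns `tissue`,
#'   `source`, `pathway`, `a`, `b`, `c`, `d`, `universe_size`, `p_raw`,
#'   `p_adj`, `hit_genes` (`";"`-joined, sorted) and `hit_eqtl_count`.
#' @export
scan_tissue <- function(cat, idx, coll, counting_unit = c("egene", "eqtl")) {
  counting_unit <- match.arg(counting_unit)
  stopifnot(inherits(cat, "eqtl_catalog"), inherits(idx, "interval_index"),
            inherits(coll, "geneset_collection"))
  if (nrow(cat$records) == 0L) stop("catalog '", cat$tissue, "' is empty")
  sel <- select_in_region_egenes(cat, idx)
  universe <- intersect(cat$egene_universe, coll$universe)
  pnames <- names(coll$sets)
  n_sets <- length(pnames)

  if (length(universe) == 0L) {
    warning("no shared genes between catalog '", cat$tissue,
            "' and collection '", coll$name, "'; all tests degenerate")
    a <- b <- cc <- d <- usize <- integer(n_sets)
    hit_genes <- rep("", n_sets)
    hit_eqtl <- integer(n_sets)
  } else if (counting_unit == "egene") {
    hits <- intersect(sel$egenes, universe)
    members <- lapply(coll$sets, intersect, universe)
    hit_lists <- lapply(members, intersect, hits)
    a <- vapply(hit_lists, length, 0L)
    psize <- vapply(members, length, 0L)
    b <- length(hits) - a
    cc <- psize - a
    d <- length(universe) - a - b - cc
    usize <- rep(length(universe), n_sets)
    hit_genes <- vapply(hit_lists, function(g) paste(sort(g), collapse = ";"),
                        character(1))
    hit_eqtl <- vapply(hit_lists, function(g) sum(sel$counts[g]), 0L,
                       USE.NAMES = FALSE)
  } else {
    # eQTL-record mode: every record with an in-universe eGene is a unit
    rec <- cat$records[cat$records$egene %in% universe, , drop = FALSE]
    inreg <- region_contains(idx, rec$chrom, rec$pos - 1L)
    n_in <- sum(inreg)
    n_tot <- nrow(rec)
    in_pw <- vapply(coll$sets, function(m) sum(inreg & rec$egene %in% m), 0L)
    tot_pw <- vapply(coll$sets, function(m) sum(rec$egene %in% m), 0L)
    a <- in_pw
    b <- n_in - a
    cc <- tot_pw - a
    d <- n_tot - a - b - cc
    usize <- rep(n_tot, n_sets)
    hit_lists <- lapply(coll$sets, function(m) {
      sort(unique(rec$egene[inreg & rec$egene %in% m]))
    })
    hit_genes <- vapply(hit_lists, paste, character(1), collapse = ";")
    hit_eqtl <- a
  }

  p_raw <- fisher_one_sided_p_vec(a, b, cc, d)
  p_adj <- bh_adjust(p_raw)
  res <- data.frame(
    tissue = rep(cat$tissue, n_sets),
    source = rep(coll$source, n_sets),
    pathway = pnames,
    a = as.integer(a), b = as.integer(b), c = as.integer(cc),
    d = as.integer(d), universe_size = as.integer(usize),
    p_raw = p_raw, p_adj = p_adj,
    hit_genes = unname(hit_genes),
    hit_eqtl_count = as.integer(hit_eqtl),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p_adj, res$pathway, res$tissue), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_results", "data.frame")
  res
}

#' Run the enrichment scan over all tissues and collections
#'
#' @param catalogs Named list of `eqtl_catalog` objects (one per tissue).
#' @param regions A `query_region_set` (or interval data.frame).
#' @param collections A `geneset_collection` or list of them.
#' @param counting_unit Passed to [scan_tissue()].
#' @param bh_family Family for the BH adjustment: `"per_pair"` (default:
#'   within each tissue-collection pair, matching per-tissue per-database
#'   result tables), `"per_tissue"` (all collections of a tissue jointly)
#'   or `"global"` (every test jointly).
#' @return An `enrichment_results` data.frame over all (tissue, pathway)
#'   pairs, sorted by `p_adj`, then pathway, then tissue.
#' @export
run_all <- function(catalogs, regions, collections,
                    counting_unit = c("egene", "eqtl"),
                    bh_family = c("per_pair", "per_tissue", "global")) {
  counting_unit <- match.arg(counting_unit)
  bh_family <- match.arg(bh_family)
  if (inherits(collections, "geneset_collection")) collections <- list(collections)
  stopifnot(length(catalogs) >= 1L, length(collections) >= 1L)
  idx <- build_interval_index(regions)
  tissues <- sort(names(catalogs))
  parts <- list()
  for (t in tissues) {
    for (coll in collections) {
      parts[[length(parts) + 1L]] <- scan_tissue(
        catalogs[[t]], idx, coll, counting_unit = counting_unit)
    }
  }
  res <- do.call(rbind, parts)
  if (bh_family != "per_pair") {
    grp <- if (bh_family == "per_tissue") res$tissue else rep("all", nrow(res))
    for (g in unique(grp)) {
      i <- grp == g
      res$p_adj[i] <- bh_adjust(res$p_raw[i])
    }
  }
  res <- res[order(res$p_adj, res$pathway, res$tissue), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_results", "data.frame")
  res
}
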