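#' Configure a synthetic eQTL-enrichment scenario
#'
#' Defines the study conditions for the generator: toy chromosomes, a gene
#' universe, pathway collection, per-tissue eQTL catalogs and a trait
#' variant list, with an optional planted tissue-pathway enrichment
#' signal. Defaults describe the desk-scale validation scenario: 4
#' chromosomes of 10 Mb, 500 genes, 50 pathways of 20 genes, 3 tissues,
#' 4 eQTLs per gene per tissue, 40 query variants flanked by 50 kb, a
#' background in-region placement rate of 0.05 and a planted enrichment
#' factor of 8 when a signal is planted.
#'
#' @param seed Integer master seed; every random choice derives from it.
#' @param n_chroms,chrom_length_bp Toy genome dimensions.
#' @param n_genes Size of the gene universe.
#' @param n_pathways,pathway_size Pathway collection dimensions (members
#'   drawn without replacement per pathway).
#' @param n_tissues Number of tissue catalogs.
#' @param eqtls_per_gene eQTL records per gene per tissue.
#' @param n_query_variants Trait-associated variants drawn uniformly.
#' @param flank_bp Flank per side for query regions (default 50,000).
#' @param eqtl_p_threshold Catalog load filter; generated nominal
#'   p-values are log-uniform in `[1e-12, eqtl_p_threshold]` so all pass.
#' @param background_inregion_rate Probability that a background eQTL is
#'   placed inside the query regions.
#' @param planted `NULL` for a null scenario, or a list with `tissue`
#'   (index or name), `pathway` (index or name) and `factor` (>= 1): the
#'   planted pair's member-gene eQTLs are placed in-region with
#'   probability `min(1, factor * background_inregion_rate)`.
#' @return A validated `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_chroms = 4L,
                            chrom_length_bp = 10000000L,
                            n_genes = 500L,
                            n_pathways = 50L,
                            pathway_size = 20L,
                            n_tissues = 3L,
                            eqtls_per_gene = 4L,
                            n_query_variants = 40L,
                            flank_bp = 50000L,
                            eqtl_p_threshold = 1e-4,
                            background_inregion_rate = 0.05,
                            planted = NULL) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length_bp = as.integer(chrom_length_bp),
              n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              n_tissues = as.integer(n_tissues),
              eqtls_per_gene = as.integer(eqtls_per_gene),
              n_query_variants = as.integer(n_query_variants),
              flank_bp = as.integer(flank_bp),
              eqtl_p_threshold = as.numeric(eqtl_p_threshold),
              background_inregion_rate = as.numeric(background_inregion_rate),
              planted = planted)
  counts <- cfg[c("n_chroms", "chrom_length_bp", "n_genes", "n_pathways",
                  "pathway_size", "n_tissues", "eqtls_per_gene",
                  "n_query_variants")]
  if (anyNA(unlist(counts)) || any(unlist(counts) < 1L)) {
    stop("all scenario counts must be positive integers")
  }
  if (is.na(cfg$seed)) stop("'seed' must be an integer")
  if (cfg$flank_bp < 0L) stop("'flank_bp' must be >= 0")
  if (cfg$pathway_size > cfg$n_genes) {
    stop("'pathway_size' cannot exceed 'n_genes'")
  }
  if (!(cfg$eqtl_p_threshold > 0 && cfg$eqtl_p_threshold <= 1)) {
    stop("'eqtl_p_threshold' must be in (0, 1]")
  }
  if (!(cfg$background_inregion_rate > 0 && cfg$background_inregion_rate < 1)) {
    stop("'background_inregion_rate' must be in (0, 1)")
  }
  if (!is.null(planted)) {
    if (!is.list(planted) ||
        !all(c("tissue", "pathway", "factor") %in% names(planted))) {
      stop("'planted' must be a list with tissue, pathway and factor")
    }
    if (is.na(as.numeric(planted$factor)) || as.numeric(planted$factor) < 1) {
      stop("planted enrichment factor must be >= 1")
    }
    cfg$planted$factor <- as.numeric(planted$factor)
  }
  structure(cfg, class = "scenario_config")
}

# one RNG, one master seed, explicit substreams per generated component
substream_seed <- function(seed, k) {
  ((as.numeric(seed) %% 100000) * 20011 + k * 7919) %% 2147483647
}

with_substream <- function(seed, k, expr) {
  set.seed(substream_seed(seed, k))
  expr
}

# sample positions (1-based): in-region records uniform over region bp,
# out-of-region records uniform over [lo, hi] with rejection against regions
sample_positions <- function(inreg, chrom, lo, hi, regions_iv, idx,
                             chrom_len) {
  n <- length(inreg)
  out_chrom <- chrom
  out_pos <- integer(n)
  n_in <- sum(inreg)
  if (n_in > 0L) {
    w <- regions_iv$end - regions_iv$start
    ri <- sample.int(nrow(regions_iv), n_in, replace = TRUE, prob = w)
    off <- floor(stats::runif(n_in) * w[ri])
    out_chrom[inreg] <- regions_iv$chrom[ri]
    out_pos[inreg] <- regions_iv$start[ri] + as.integer(off) + 1L
  }
  todo <- which(!inreg)
  attempt <- 0L
  cur_lo <- lo
  cur_hi <- hi
  while (length(todo) > 0L && attempt < 80L) {
    attempt <- attempt + 1L
    if (attempt == 40L) {  # widen stubborn windows to the whole chromosome
      cur_lo[todo] <- 1L
      cur_hi[todo] <- chrom_len
    }
    draw <- cur_lo[todo] +
      as.integer(floor(stats::runif(length(todo)) *
                         (cur_hi[todo] - cur_lo[todo] + 1)))
    hit <- region_contains(idx, out_chrom[todo], draw - 1L)
    out_pos[todo] <- draw
    todo <- todo[hit]
  }
  list(chrom = out_chrom, pos = out_pos)
}

#' Generate a complete synthetic scenario in memory
#'
#' Deterministic given the config (one master seed, explicit substreams
#' per component). Gene anchors are uniform per chromosome and each
#' gene's eQTLs scatter within +/-100 kb of its anchor, mimicking
#' cis-eQTL locality; in-region placement is decided per record by a
#' Bernoulli draw (see [scenario_config()]), which makes the manifest's
#' closed-form expected hit counts exact.
#'
#' @param cfg A `scenario_config`.
#' @return A list with `config`, `chroms` (data.frame `chrom`, `size`),
#'   `gene_map`, `collection`, `variants`, `regions`, `catalogs` (named
#'   list of `eqtl_catalog`) and `manifest` (flat named list recording
#'   the planted pair and every expectation needed to recompute it).
#' @export
simulate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  chroms <- data.frame(chrom = sprintf("chr%d", seq_len(cfg$n_chroms)),
                       size = rep(cfg$chrom_length_bp, cfg$n_chroms),
                       stringsAsFactors = FALSE)
  gene_map <- data.frame(
    ensembl_id = sprintf("ENSG%011d", seq_len(cfg$n_genes)),
    entrez_id = as.character(100000L + seq_len(cfg$n_genes)),
    symbol = sprintf("GENE%04d", seq_len(cfg$n_genes)),
    stringsAsFactors = FALSE
  )
  class(gene_map) <- c("gene_id_map", "data.frame")

  # gene anchors
  anchors <- with_substream(cfg$seed, 1L, {
    data.frame(
      chrom = chroms$chrom[sample.int(cfg$n_chroms, cfg$n_genes, replace = TRUE)],
      pos = 1L + as.integer(floor(stats::runif(cfg$n_genes) * cfg$chrom_length_bp)),
      stringsAsFactors = FALSE
    )
  })

  # pathway collection
  sets <- with_substream(cfg$seed, 2L, {
    lapply(seq_len(cfg$n_pathways), function(i) {
      gene_map$entrez_id[sample.int(cfg$n_genes, cfg$pathway_size)]
    })
  })
  pnames <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  names(sets) <- pnames
  collection <- new_geneset_collection(
    name = "SYNTH", source = "SYNTH", sets = sets,
    urls = stats::setNames(sprintf("http://example.org/%s", pnames), pnames)
  )

  # trait variants and query regions
  variants <- with_substream(cfg$seed, 3L, {
    data.frame(
      trait = "synthetic_trait",
      id = sprintf("rs%06d", seq_len(cfg$n_query_variants)),
      chrom = chroms$chrom[sample.int(cfg$n_chroms, cfg$n_query_variants,
                                      replace = TRUE)],
      pos = 1L + as.integer(floor(stats::runif(cfg$n_query_variants) *
                                    cfg$chrom_length_bp)),
      stringsAsFactors = FALSE
    )
  })
  regions <- build_query_regions(variants, flank_bp = cfg$flank_bp,
                                 chrom_sizes = chroms)
  idx <- build_interval_index(regions)

  # planted pair resolution
  planted_tissue <- planted_pathway <- NA_character_
  planted_factor <- NA_real_
  p_in_planted <- NA_real_
  member_idx <- integer(0)
  tissue_names <- sprintf("tissue%02d", seq_len(cfg$n_tissues))
  if (!is.null(cfg$planted)) {
    pt <- cfg$planted$tissue
    planted_tissue <- if (is.numeric(pt)) tissue_names[as.integer(pt)] else as.character(pt)
    pp <- cfg$planted$pathway
    planted_pathway <- if (is.numeric(pp)) pnames[as.integer(pp)] else as.character(pp)
    if (is.na(planted_tissue) || !(planted_tissue %in% tissue_names)) {
      stop("planted tissue not in scenario")
    }
    if (is.na(planted_pathway) || !(planted_pathway %in% pnames)) {
      stop("planted pathway not in scenario")
    }
    planted_factor <- cfg$planted$factor
    p_in_planted <- min(1, planted_factor * cfg$background_inregion_rate)
    member_idx <- match(collection$sets[[planted_pathway]], gene_map$entrez_id)
  }

  # per-tissue eQTL catalogs
  k <- cfg$eqtls_per_gene
  n_e <- cfg$n_genes * k
  gidx <- rep(seq_len(cfg$n_genes), each = k)
  catalogs <- lapply(seq_len(cfg$n_tissues), function(t) {
    with_substream(cfg$seed, 10L + t, {
      p_in_gene <- rep(cfg$background_inregion_rate, cfg$n_genes)
      if (!is.na(planted_tissue) && tissue_names[t] == planted_tissue) {
        p_in_gene[member_idx] <- p_in_planted
      }
      inreg <- stats::runif(n_e) < p_in_gene[gidx]
      lo <- pmax(1L, anchors$pos[gidx] - 100000L)
      hi <- pmin(cfg$chrom_length_bp, anchors$pos[gidx] + 100000L)
      placed <- sample_positions(inreg, anchors$chrom[gidx], lo, hi,
                                 regions$intervals, idx, cfg$chrom_length_bp)
      pval <- 10^stats::runif(n_e, -12, log10(cfg$eqtl_p_threshold))
      rec <- data.frame(
        variant_id = sprintf("%s_snp%05d", tissue_names[t], seq_len(n_e)),
        chrom = placed$chrom,
        pos = placed$pos,
        egene = gene_map$entrez_id[gidx],
        pvalue = pval,
        stringsAsFactors = FALSE
      )
      new_eqtl_catalog(tissue = tissue_names[t], records = rec,
                       p_threshold = cfg$eqtl_p_threshold)
    })
  })
  names(catalogs) <- tissue_names

  p_bg <- cfg$background_inregion_rate
  manifest <- list(
    seed = cfg$seed, n_chroms = cfg$n_chroms,
    chrom_length_bp = cfg$chrom_length_bp, n_genes = cfg$n_genes,
    n_pathways = cfg$n_pathways, pathway_size = cfg$pathway_size,
    n_tissues = cfg$n_tissues, eqtls_per_gene = cfg$eqtls_per_gene,
    n_query_variants = cfg$n_query_variants, flank_bp = cfg$flank_bp,
    eqtl_p_threshold = cfg$eqtl_p_threshold,
    background_inregion_rate = p_bg,
    planted_tissue = planted_tissue,
    planted_pathway = planted_pathway,
    planted_factor = planted_factor,
    p_in_background = p_bg,
    p_in_planted = p_in_planted,
    hit_prob_background = 1 - (1 - p_bg)^k,
    hit_prob_planted = if (is.na(p_in_planted)) NA_real_ else 1 - (1 - p_in_planted)^k,
    expected_a_planted = if (is.na(p_in_planted)) NA_real_ else
      cfg$pathway_size * (1 - (1 - p_in_planted)^k),
    n_regions = nrow(regions$intervals),
    region_bp = sum(as.numeric(regions$intervals$end - regions$intervals$start))
  )

  list(config = cfg, chroms = chroms, gene_map = gene_map,
       collection = collection, variants = variants, regions = regions,
       catalogs = catalogs, manifest = manifest)
}

#' Plant an enrichment signal into an existing catalog
#'
#' Re-places the eQTLs of the given member genes so each lands inside the
#' query regions with probability `min(1, factor * background_rate)`;
#' non-member records are untouched. `factor = 1` reproduces the
#' background placement distribution; a large factor saturates, putting
#' every member eQTL in-region.
#'
#' @param cat An `eqtl_catalog`.
#' @param regions A `query_region_set`.
#' @param members Character vector of member gene ids to enrich.
#' @param factor Enrichment factor (>= 1).
#' @param background_rate Background in-region placement rate.
#' @param chroms `data.frame` with `chrom`, `size` (for out-of-region
#'   placement windows).
#' @return A new `eqtl_catalog` with re-placed member records.
#' @export
plant_enrichment <- function(cat, regions, members, factor,
                             background_rate, chroms) {
  stopifnot(inherits(cat, "eqtl_catalog"), factor >= 1,
            background_rate > 0, background_rate < 1)
  rec <- cat$records
  sel <- rec$egene %in% members
  if (!any(sel)) return(cat)
  idx <- build_interval_index(regions)
  p_in <- min(1, factor * background_rate)
  n <- sum(sel)
  inreg <- stats::runif(n) < p_in
  sz <- stats::setNames(as.integer(chroms$size), chroms$chrom)
  chrom_len <- max(sz)
  lo <- rep(1L, n)
  hi <- sz[rec$chrom[sel]]
  placed <- sample_positions(inreg, rec$chrom[sel], lo, hi,
                             regions$intervals, idx, chrom_len)
  rec$chrom[sel] <- placed$chrom
  rec$pos[sel] <- placed$pos
  new_eqtl_catalog(tissue = cat$tissue, records = rec,
                   p_threshold = cat$p_threshold)
}

#' Write a synthetic scenario to disk
#'
#' Emits exactly the formats the readers consume: `variants.tsv`,
#' `eqtls.tsv` (gene ids written as versioned Ensembl ids, exercising the
#' id-mapping path), `genesets.gmt` (Entrez members), `gene_map.tsv`,
#' `chrom.sizes` and a flat `manifest.txt`. Byte-identical for identical
#' configs.
#'
#' @param cfg A `scenario_config`.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a named character vector of the paths written.
#' @export
generate_scenario <- function(cfg, outdir) {
  sim <- simulate_scenario(cfg)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(
    variants = file.path(outdir, "variants.tsv"),
    eqtls = file.path(outdir, "eqtls.tsv"),
    gmt = file.path(outdir, "genesets.gmt"),
    gene_map = file.path(outdir, "gene_map.tsv"),
    chrom_sizes = file.path(outdir, "chrom.sizes"),
    manifest = file.path(outdir, "manifest.txt")
  )
  vdf <- data.frame(trait = sim$variants$trait, snp_id = sim$variants$id,
                    chrom = sim$variants$chrom,
                    pos_1based = sim$variants$pos, stringsAsFactors = FALSE)
  utils::write.table(vdf, paths[["variants"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ens <- stats::setNames(sim$gene_map$ensembl_id, sim$gene_map$entrez_id)
  eq <- do.call(rbind, lapply(sim$catalogs, function(cat) {
    r <- cat$records
    data.frame(
      variant_id = r$variant_id, chrom = r$chrom, pos_1based = r$pos,
      gene_id = paste0(ens[r$egene], ".",
                       (match(r$egene, sim$gene_map$entrez_id) %% 9L) + 1L),
      tissue = cat$tissue,
      pvalue = sprintf("%.17g", r$pvalue),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(eq, paths[["eqtls"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(sim$collection, paths[["gmt"]])
  utils::write.table(as.data.frame(sim$gene_map), paths[["gene_map"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste(sim$chroms$chrom, sim$chroms$size, sep = "\t"),
             paths[["chrom_sizes"]])
  man <- sim$manifest
  writeLines(paste0(names(man), "=",
                    vapply(man, function(x) {
                      if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
                    }, character(1))),
             paths[["manifest"]])
  invisible(paths)
}

#' Read a flat key=value manifest
#'
#' @param path Path to a manifest written by [generate_scenario()].
#' @return Named list; numeric-looking values are converted.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(x) {
    v <- paste(x[-1L], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(out, vapply(kv, `[[`, character(1), 1L))
}

#' Empirical type-I-error table under the null
#'
#' Runs the full pipeline on `n_reps` fresh null scenarios (no planted
#' signal; replicate `i` uses master seed `cfg$seed + i`) and reports the
#' fraction of all (tissue, pathway) tests with raw p below each alpha.
#' Because the one-sided exact test is conservative under discreteness,
#' these fractions sit at or below the nominal level.
#'
#' @param cfg A null `scenario_config` (`planted = NULL`).
#' @param n_reps Number of replicate scans.
#' @param alphas Numeric vector of nominal levels.
#' @return A `data.frame` with columns `alpha`, `fraction`, `n_tests`.
#' @export
null_calibration <- function(cfg, n_reps, alphas = c(0.05, 0.01, 1e-4)) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(cfg$planted)) stop("null calibration requires planted = NULL")
  if (n_reps == 0L) {
    return(data.frame(alpha = numeric(0), fraction = numeric(0),
                      n_tests = integer(0)))
  }
  p_all <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    sim <- simulate_scenario(cfg_i)
    res <- run_all(sim$catalogs, sim$regions, sim$collection)
    p_all[[i]] <- res$p_raw
  }
  p <- unlist(p_all)
  data.frame(
    alpha = alphas,
    fraction = vapply(alphas, function(a) if (a >= 1) 1 else mean(p < a), 0),
    n_tests = rep(length(p), length(alphas))
  )
}

#' Planted-signal recovery across replicate seeds
#'
#' For each replicate (master seed `cfg$seed + i`) generates a planted
#' scenario, runs the full enrichment scan and checks whether the planted
#' (tissue, pathway) pair attains the global minimum adjusted p-value and
#' passes the result filter.
#'
#' @param cfg A `scenario_config` with a planted signal.
#' @param n_reps Number of replicates.
#' @param result_threshold Result filter on `p_adj` (default `1e-4`).
#' @return A `data.frame` with one row per replicate: `seed`,
#'   `planted_p_adj`, `is_min`, `passes_filter`.
#' @export
planted_recovery <- function(cfg, n_reps, result_threshold = 1e-4) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(cfg$planted)) stop("planted recovery requires a planted signal")
  rows <- lapply(seq_len(n_reps), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    sim <- simulate_scenario(cfg_i)
    res <- run_all(sim$catalogs, sim$regions, sim$collection)
    pt <- sim$manifest$planted_tissue
    pp <- sim$manifest$planted_pathway
    p_planted <- res$p_adj[res$tissue == pt & res$pathway == pp]
    data.frame(seed = cfg_i$seed,
               planted_p_adj = p_planted,
               is_min = p_planted == min(res$p_adj),
               passes_filter = p_planted <= result_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
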