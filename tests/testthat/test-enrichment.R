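test_that("in-region eGene selection deduplicates LD-linked eQTLs", {
  # 3 eQTLs inside the region, all targeting G1 -> one eGene, count 3
  cat <- tiny_catalog(pos = c(100L, 200L, 300L, 5000L),
                      egene = c("G1", "G1", "G1", "G2"))
  idx <- build_interval_index(tiny_regions(end = 1000L))
  sel <- select_in_region_egenes(cat, idx)
  expect_equal(sel$egenes, "G1")
  expect_equal(unname(sel$counts["G1"]), 3L)

  # no eQTL in any region -> empty set
  far <- tiny_catalog(pos = c(5000L, 6000L), egene = c("G1", "G2"))
  expect_equal(select_in_region_egenes(far, idx)$egenes, character(0))
})

test_that("in-region selection matches a brute-force per-record scan", {
  set.seed(17)
  n <- 5000L
  cat <- tiny_catalog(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample.int(100000L, n, replace = TRUE),
    egene = sprintf("G%03d", sample.int(400, n, replace = TRUE)))
  iv <- merge_intervals(random_intervals(15, c("chr1", "chr2"), 100000L))
  idx <- build_interval_index(iv)
  sel <- select_in_region_egenes(cat, idx)
  inreg <- vapply(seq_len(n), function(i) {
    any(iv$chrom == cat$records$chrom[i] &
          iv$start <= cat$records$pos[i] - 1L &
          cat$records$pos[i] - 1L < iv$end)
  }, logical(1))
  expect_equal(sel$egenes, sort(unique(cat$records$egene[inreg])))
  expect_equal(sum(sel$counts), sum(inreg))
})

test_that("contingency cells classify every universe gene exactly once", {
  t1 <- build_contingency(hits = c("G1", "G2"), pathway = c("G1", "G3"),
                          universe = sprintf("G%d", 1:10))
  expect_equal(unlist(t1[c("a", "b", "c", "d")]),
               c(a = 1L, b = 1L, c = 1L, d = 7L))
  t2 <- build_contingency(character(0), c("G1", "G3"), sprintf("G%d", 1:10))
  expect_equal(c(t2$a, t2$b), c(0L, 0L))
  expect_error(build_contingency("G1", "G1", character(0)), "empty")

  set.seed(8)
  for (rep in 1:50) {
    u <- sprintf("G%03d", sample.int(200, sample(10:100, 1)))
    h <- sample(u, sample.int(length(u), 1))
    p <- sprintf("G%03d", sample.int(250, sample(5:60, 1)))
    tt <- build_contingency(h, p, u)
    cls <- table(factor(paste0(unique(u) %in% h, unique(u) %in% p),
                        levels = c("TRUETRUE", "TRUEFALSE",
                                   "FALSETRUE", "FALSEFALSE")))
    expect_equal(unlist(tt[c("a", "b", "c", "d")], use.names = FALSE),
                 as.integer(cls))
    expect_equal(tt$universe_size, length(unique(u)))
  }
})

test_that("one-sided Fisher p equals hypergeometric tail enumeration", {
  # margins (2,2)/(2,2): all tables enumerable by hand
  expect_equal(fisher_one_sided_p(1, 1, 1, 1), 5 / 6, tolerance = 1e-12)
  expect_equal(fisher_one_sided_p(1, 1, 1, 1), enum_fisher_tail(1, 1, 1, 1),
               tolerance = 1e-15)
  expect_equal(fisher_one_sided_p(2, 0, 0, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(fisher_one_sided_p(0, 5, 3, 10), 1)  # P(A >= 0) = 1
  expect_equal(fisher_one_sided_p(0, 0, 4, 6), 1)   # degenerate margin
  expect_equal(fisher_one_sided_p(0, 7, 0, 9), 1)   # pathway margin empty

  tab <- build_contingency(c("G1", "G2"), c("G1", "G3"), sprintf("G%d", 1:10))
  expect_equal(fisher_one_sided_p(tab),
               enum_fisher_tail(tab$a, tab$b, tab$c, tab$d), tolerance = 1e-13)

  # cross-check against the standard exact-test implementation
  set.seed(31)
  for (rep in 1:40) {
    cells <- as.integer(rmultinom(1, sample(20:80, 1), rep(0.25, 4)))
    got <- fisher_one_sided_p(cells[1], cells[2], cells[3], cells[4])
    want <- stats::fisher.test(matrix(cells, 2, byrow = TRUE),
                               alternative = "greater")$p.value
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("moving a hit gene into the pathway never weakens the enrichment p", {
  set.seed(12)
  for (rep in 1:50) {
    cells <- as.integer(rmultinom(1, sample(20:60, 1), rep(0.25, 4)))
    a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
    if (b == 0L) next
    expect_lte(fisher_one_sided_p(a + 1L, b - 1L, cc, d),
               fisher_one_sided_p(a, b, cc, d) + 1e-12)
  }
})

test_that("BH adjustment follows the step-up formula and its invariants", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.05, 0.05, 0.05)), c(0.05, 0.05, 0.05))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.01)), "\\[0, 1\\]")

  set.seed(4)
  for (rep in 1:25) {
    p <- runif(sample(1:200, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_stepup_oracle(p))
    # cross-check against the standard implementation
    expect_equal(q, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))  # monotone in p
  }
})

test_that("a tissue scan tests every pathway with shared hits and universe", {
  cat <- tiny_catalog(pos = c(100L, 200L, 5000L, 6000L, 7000L),
                      egene = c("G1", "G2", "G3", "G4", "G5"))
  idx <- build_interval_index(tiny_regions(end = 1000L))
  coll <- tiny_collection(list(PW_HIT = c("G1", "G2", "G3"),
                               PW_MISS = c("G4", "G5")))
  res <- scan_tissue(cat, idx, coll)
  expect_equal(nrow(res), 2L)
  expect_equal(res$pathway[1], "PW_HIT")
  expect_equal(res$a[res$pathway == "PW_HIT"], 2L)
  expect_equal(res$hit_genes[res$pathway == "PW_HIT"], "G1;G2")
  expect_equal(res$a[res$pathway == "PW_MISS"], 0L)
  expect_equal(res$universe_size, c(5L, 5L))
  expect_true(all(res$p_adj >= res$p_raw))

  # single-pathway collection: BH is the identity
  res1 <- scan_tissue(cat, idx, tiny_collection(list(ONLY = c("G1", "G4"))))
  expect_equal(res1$p_adj, res1$p_raw)

  # permuting pathway order leaves results identical up to ordering
  norm <- function(d) { rownames(d) <- NULL; d }
  coll_rev <- tiny_collection(rev(coll$sets))
  res_rev <- scan_tissue(cat, idx, coll_rev)
  expect_equal(norm(res_rev[order(res_rev$pathway), ]),
               norm(res[order(res$pathway), ]))

  # shuffling eQTL record order leaves every p bit-identical
  set.seed(2)
  perm <- sample(nrow(cat$records))
  cat_shuf <- tiny_catalog(pos = cat$records$pos[perm],
                           egene = cat$records$egene[perm],
                           variant_id = cat$records$variant_id[perm])
  res_shuf <- scan_tissue(cat_shuf, idx, coll)
  expect_identical(res_shuf$p_raw, res$p_raw)
  expect_identical(res_shuf$p_adj, res$p_adj)
})

test_that("eQTL-record counting mode counts records, not distinct genes", {
  cat <- tiny_catalog(pos = c(100L, 200L, 300L, 5000L),
                      egene = c("G1", "G1", "G1", "G2"))
  idx <- build_interval_index(tiny_regions(end = 1000L))
  coll <- tiny_collection(list(PW = "G1", OTHER = "G2"))
  res_g <- scan_tissue(cat, idx, coll, counting_unit = "egene")
  res_q <- scan_tissue(cat, idx, coll, counting_unit = "eqtl")
  expect_equal(res_g$a[res_g$pathway == "PW"], 1L)
  expect_equal(res_q$a[res_q$pathway == "PW"], 3L)  # LD-linked records all count
  expect_equal(res_q$universe_size, c(4L, 4L))      # all records with in-universe eGenes
  expect_equal(res_q$hit_genes[res_q$pathway == "PW"], "G1")
})

test_that("the full scan composes per-pair scans and orders deterministically", {
  cats <- list(
    liver = tiny_catalog(tissue = "liver", pos = c(100L, 5000L),
                         egene = c("G1", "G2")),
    lung = tiny_catalog(tissue = "lung", pos = c(200L, 6000L),
                        egene = c("G2", "G3"))
  )
  colls <- list(
    tiny_collection(list(P1 = c("G1", "G2"), P2 = c("G2", "G3"),
                         P3 = c("G1", "G3"), P4 = c("G1", "G2", "G3"),
                         P5 = "G1", P6 = "G2", P7 = "G3", P8 = c("G2"),
                         P9 = c("G1"), P10 = c("G3")), name = "DB1"),
    tiny_collection(list(Q1 = c("G1", "G2"), Q2 = c("G2", "G3"),
                         Q3 = c("G1", "G3"), Q4 = c("G1", "G2", "G3"),
                         Q5 = "G1", Q6 = "G2", Q7 = "G3", Q8 = c("G2"),
                         Q9 = c("G1"), Q10 = c("G3")), name = "DB2")
  )
  regions <- tiny_regions(end = 1000L)
  res <- run_all(cats, regions, colls)
  expect_equal(nrow(res), 40L)  # 2 tissues x 2 collections x 10 pathways
  idx <- build_interval_index(regions)
  norm <- function(d) { rownames(d) <- NULL; d }
  for (t in names(cats)) {
    for (coll in colls) {
      part <- scan_tissue(cats[[t]], idx, coll)
      sub <- res[res$tissue == t & res$source == coll$source, ]
      expect_equal(norm(sub[order(sub$pathway), names(part)]),
                   norm(part[order(part$pathway), ]))
    }
  }

  # a tissue with no in-region eQTLs yields all-null results
  cats2 <- list(dry = tiny_catalog(tissue = "dry", pos = c(5000L, 6000L),
                                   egene = c("G1", "G2")))
  res2 <- run_all(cats2, regions, colls[[1]])
  expect_true(all(res2$p_raw == 1))
  expect_true(all(res2$a == 0L))

  # global BH family adjusts across every test jointly
  res_g <- run_all(cats, regions, colls, bh_family = "global")
  expect_equal(res_g$p_adj[order(res_g$tissue, res_g$source, res_g$pathway)],
               bh_adjust(res$p_raw[order(res$tissue, res$source, res$pathway)]))
})
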