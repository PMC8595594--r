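---
title: "Tissue-specific eQTL pathway enrichment: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-specific eQTL pathway enrichment: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlpath)
```

## The problem

Genome-wide association studies localise trait signals to non-coding
intervals, but the gene a variant regulates is often not its physical
neighbour: only a minority of eQTLs have their closest gene as their
target. `eqtlpath` therefore links trait-associated genomic intervals to
biological pathways through *regulatory* evidence: a tissue-specific eQTL
catalog connects each variant to its eGene, and pathways are tested for
over-representation of the eGenes regulated from within the intervals.
Because eQTL catalogs are tissue-resolved, the result is a ranked set of
(tissue, pathway) associations for a trait, not just a gene list.

## The model

**Query regions.** Each trait-associated variant at 1-based position $p$
is flanked by $f$ bp on each side, giving the half-open interval
$[\max(0, p - 1 - f),\; p + f)$ of length $2f + 1$ (the variant base plus
both flanks; we include the variant base because a region defined by a
variant should contain it). Overlapping — and, with half-open coordinates,
abutting — intervals are merged per chromosome. The default flank is
$f = 50{,}000$ bp, the conventional GWAS-locus window.

**Hit selection.** For a tissue $t$ with eQTL catalog $C_t$ (records
filtered at nominal $p \le 10^{-4}$ at load time), the hit set $H$ is the
set of *distinct* eGenes of records whose position falls inside any query
interval. Counting distinct genes rather than records matters: linkage
disequilibrium places many near-copies of the same association in a
catalog, so record counts would be badly inflated. (A record-counting
mode is available via `counting_unit = "eqtl"` for comparison.)

**The test.** For each pathway $P$ in a collection with gene universe
$U_c$, let $U = E_t \cap U_c$, where $E_t$ is the tissue's eGene
universe. Genes that can never be hit in the tissue, or that belong to no
pathway of the collection, carry no information and would only inflate
the "neither" cell. Every gene of $U$ is classified into the 2x2 table

|            | in $P$ | not in $P$ |
|------------|--------|------------|
| hit        | $a$    | $b$        |
| not hit    | $c$    | $d$        |

and the enrichment p-value is the one-sided Fisher exact probability
$\Pr(A \ge a)$ under the hypergeometric null with fixed margins
(alternative "greater"; depletion is not of interest here). Degenerate
margins ($a+b = 0$ or $a+c = 0$) return $p = 1$.

**Multiplicity.** Within each (tissue, collection) pair the p-values are
adjusted by the Benjamini–Hochberg step-up rule,
$q_{(i)} = \min_{j \ge i} p_{(j)} \cdot m / j$ capped at 1. The per-pair
family is the default because published result tables are reported per
tissue and per database; `bh_family = "per_tissue"` and `"global"` are
available when a wider family is wanted. Results are ranked by adjusted
p, ties broken by pathway then tissue name, and the shipped result
filter retains $q \le 10^{-4}$ — applied to *adjusted* p-values, since
those are what the reports display (`filter_on = "raw"` switches this).

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `flank_bp` | 50,000 | bp | symmetric GWAS-locus window per side |
| `eqtl_p_threshold` | 1e-4 | — | nominal-p load filter, inclusive (`<=`) |
| `result_p_threshold` | 1e-4 | — | result filter on adjusted p, inclusive |
| `counting_unit` | `egene` | — | distinct eGenes; record mode is LD-inflated |
| `bh_family` | `per_pair` | — | matches per-tissue, per-database reporting |
| `filter_on` | `adjusted` | — | reports display BH-adjusted p |

The canonical gene namespace is Entrez (what GMT bundles of the major
pathway databases use); Ensembl ids in eQTL tables are mapped at load via
an offline id table, with version suffixes (`.N`) stripped. Records whose
id cannot be mapped are dropped with a logged count, and pathway members
absent from the universe are excluded from that pathway's margins.

## Numerical choices

* The hypergeometric tail is evaluated via `phyper`; the test suite
  verifies it against a full `lchoose` enumeration over every 2x2 table
  with universe size up to 60 (about 6.4e5 tables) to within 1e-12, and
  against `fisher.test(alternative = "greater")` on random tables.
* `bh_adjust` evaluates the step-up formula literally (suffix running
  minimum over $p_{(j)} m / j$); it agrees with `stats::p.adjust` to
  within one floating-point rounding of the scaling step, and the suite
  checks bit-exact agreement with the literal formula.
* Intervals are 0-based half-open internally (BED convention); 1-based
  inputs are converted at the read boundary. Merging is backed by
  `GenomicRanges::reduce`; membership queries use per-chromosome binary
  search, which the suite checks against linear scans.
* $-\log_{10}$ heatmap values floor adjusted p at 1e-300 so cells stay
  finite; untested cells are masked, and the TSV export is the contract
  (full float precision, lossless round-trip) while the PNG is cosmetic.
* Duplicate (variant, eGene, tissue) records collapse to their smallest
  p at load; a variant regulating several genes contributes one record
  per eGene.

## What the generator emulates — and what it does not

`simulate_scenario()` builds a complete input bundle: toy chromosomes,
a gene universe with an Ensembl/Entrez/symbol map, uniformly placed gene
anchors whose eQTLs scatter within ±100 kb (cis-locality), per-tissue
catalogs whose nominal p-values are log-uniform in `[1e-12, 1e-4]` (all
pass the load filter; filtering itself is tested with out-of-range
spikes), a pathway collection drawn without replacement, and a trait
variant list. In-region placement is an explicit per-record Bernoulli
draw: rate `background_inregion_rate` (default 0.05) for background
records, `min(1, factor * rate)` for members of the planted pathway in
the planted tissue. That choice makes the manifest's expected hit count
closed-form — $E[a] = \sum_{g \in P} 1 - (1 - p_{in})^k$ with $k$ eQTLs
per gene — which the tests verify.

The default study conditions are 4 chromosomes x 10 Mb, 500 genes, 50
pathways x 20 genes, 3 tissues, 4 eQTLs per gene, 40 query variants,
flank 50 kb and planted factor 8. Under these conditions the planted
pair is the global minimum adjusted p in ≥95/100 replicates, and 200
null scans put the fraction of raw p below 0.05 at or under the nominal
level (the exact test is conservative under discreteness). These sizes
were chosen once as a realistic desk-scale emulation; the generator does
**not** model LD structure, allele-frequency or effect-size
distributions, non-uniform gene density, or catalog-scale volumes — so
passing tests demonstrate correctness of the machinery and calibration
of the statistic under idealised sampling, not robustness to the
correlation structure of real genotype data. On real catalogs,
LD-induced dependence between neighbouring records is absorbed by the
distinct-eGene counting unit but dependence *between genes* in a region
remains, which is the main caveat when reading small p-values.

## Known limitations and open choices

* The 2x2 margins are not uniquely dictated by the enrichment idea; the
  universe intersection above is this package's stated choice and the
  main fidelity risk against other implementations of the same test.
* Tissues with larger catalogs have more power; imbalanced catalogs can
  produce coincidental enrichments in well-sampled tissues. Treat
  cross-tissue comparisons qualitatively.
* No liftover, no LD-aware region definition, no colocalization; the
  multi-tissue "one row, many tissues" catalog export formats of large
  consortia must be converted to the canonical long-format TSV first.
* Cytoband labels are an annotation convenience (a gene is located by
  the band of its first in-region eQTL), not part of the statistics.

## A worked run

```{r example, eval = FALSE}
bundle <- tempfile()
cmd_simulate(list(seed = 42L,
                  planted = list(tissue = 1, pathway = 3, factor = 8)),
             outdir = bundle)
res <- cmd_enrich(list(variants = file.path(bundle, "variants.tsv"),
                       eqtl_table = file.path(bundle, "eqtls.tsv"),
                       gmt = file.path(bundle, "genesets.gmt"),
                       gene_map = file.path(bundle, "gene_map.tsv")),
                  outdir = tempfile())
head(res$synthetic_trait)
```

The per-trait outputs are a full results TSV, a filtered tissue-by-
pathway `-log10(q)` matrix with optional heatmap, a gene-hit table
(genes ordered by in-region eQTL support, locations as cytobands or
containing intervals), the merged regions as BED, and a manifest with
config values and input checksums sufficient to reproduce the run
bit-identically.
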