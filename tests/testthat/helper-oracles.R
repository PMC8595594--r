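# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the merge oracle paints a per-bp coverage mask,
# the Fisher oracle enumerates the hypergeometric tail from log-binomial
# coefficients, and the BH oracle applies the step-up formula directly.

# per-bp coverage mask -> maximal runs, per chromosome (0-based half-open)
mask_merge_oracle <- function(iv, chrom_len) {
  parts <- list()
  for (ch in sort(unique(iv$chrom))) {
    mask <- logical(chrom_len[[ch]])
    rows <- iv[iv$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      mask[(rows$start[r] + 1L):rows$end[r]] <- TRUE
    }
    runs <- rle(mask)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values
    if (any(keep)) {
      parts[[ch]] <- data.frame(chrom = ch, start = starts[keep] - 1L,
                                end = ends[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(parts) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

covered_bp <- function(iv, chrom_len) {
  sum(as.numeric(mask_merge_oracle(iv, chrom_len)$end) -
        as.numeric(mask_merge_oracle(iv, chrom_len)$start))
}

# P(A >= a) by direct enumeration of the hypergeometric tail (vectorized)
enum_fisher_tail <- function(a, b, cc, d) {
  K <- a + cc   # pathway genes
  n <- a + b    # hits
  N <- a + b + cc + d
  jmax <- pmin(K, n)
  lens <- pmax(jmax - a + 1L, 0L)
  p <- numeric(length(a))
  degen <- K == 0L | n == 0L
  p[degen] <- 1
  todo <- which(!degen & lens > 0L)
  if (length(todo) > 0L) {
    tab <- rep(todo, lens[todo])
    j <- sequence(lens[todo]) - 1L + rep(a[todo], lens[todo])
    terms <- exp(lchoose(K[tab], j) + lchoose(N[tab] - K[tab], n[tab] - j) -
                   lchoose(N[tab], n[tab]))
    sums <- rowsum(terms, tab)
    p[as.integer(rownames(sums))] <- sums[, 1L]
  }
  pmin(pmax(p, 0), 1)
}

# step-up BH applied literally: q_i = min_{j >= i} p_(j) * m / j, capped at 1
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  scaled <- po * m / seq_len(m)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(scaled[i:m]))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# linear-scan membership oracle for interval queries
linear_contains <- function(iv, chrom, pos) {
  vapply(seq_along(pos), function(i) {
    any(iv$chrom == chrom[i] & iv$start <= pos[i] & pos[i] < iv$end)
  }, logical(1))
}

linear_overlaps <- function(iv, chrom, start, end) {
  vapply(seq_along(start), function(i) {
    any(iv$chrom == chrom[i] & iv$start < end[i] & start[i] < iv$end)
  }, logical(1))
}

random_intervals <- function(n, chroms, chrom_len, max_width = 5000L) {
  ch <- sample(chroms, n, replace = TRUE)
  start <- sample.int(chrom_len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  genomic_intervals(ch, start, start + width,
                    label = sprintf("iv%03d", seq_len(n)))
}

md5_of <- function(paths) unname(tools::md5sum(sort(paths)))
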