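# Independent brute-force oracles used across the suite.  These are
# deliberately naive O(n^2) (or fully enumerated) implementations kept
# separate from the package's algorithms.

# Single-linkage interval merging by repeated pairwise joining.
oracle_merge <- function(df) {
  df <- df[order(df$chrom, df$start), c("chrom", "start", "end")]
  repeat {
    merged <- FALSE
    n <- nrow(df)
    for (i in seq_len(n)) {
      if (merged) break
      for (j in seq_len(n)) {
        if (i == j) next
        if (df$chrom[i] == df$chrom[j] &&
            df$start[i] < df$end[j] && df$start[j] < df$end[i]) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df <- df[-j, ]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  df[order(df$chrom, df$start), ]
}

# Benjamini-Hochberg as running minimum of p * m / rank from the bottom.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Membership counting of cut positions in regions by a double loop.
oracle_count <- function(pos, counts, regions) {
  out <- stats::setNames(integer(nrow(regions)), regions$name)
  for (i in seq_along(pos)) {
    for (j in seq_len(nrow(regions))) {
      if (pos[i] >= regions$start[j] && pos[i] < regions$end[j]) {
        out[j] <- out[j] + counts[i]
        break
      }
    }
  }
  out
}

# Fractional-overlap filter by exhaustive pairwise checking.
oracle_overlap_filter <- function(a, b, min_frac) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_frac * (a$end[i] - a$start[i])) keep[i] <- TRUE
    }
  }
  a[keep, ]
}

# Full running-sum GSEA enrichment score (position by position).
oracle_gsea_es <- function(hit, weights_abs, weight) {
  n <- length(hit)
  nh <- sum(hit)
  inc <- if (weight == 0) rep(1, n) else weights_abs
  inc[!hit] <- 0
  inc <- inc / sum(inc)
  dec <- ifelse(hit, 0, 1 / (n - nh))
  run <- cumsum(inc - dec)
  if (max(run) >= -min(run)) max(run) else min(run)
}

# Selection of the top-k records under the signed-p ordering, by
# repeatedly extracting the best remaining record.
oracle_signed_p_top <- function(records, k) {
  score <- sign(records$log2fc) * -log10(pmax(records$p, 1e-300))
  ids <- character(0)
  remaining <- seq_len(nrow(records))
  for (i in seq_len(k)) {
    best <- remaining[1]
    for (j in remaining) {
      if (score[j] > score[best] ||
          (score[j] == score[best] &&
             abs(records$log2fc[j]) > abs(records$log2fc[best])) ||
          (score[j] == score[best] &&
             abs(records$log2fc[j]) == abs(records$log2fc[best]) &&
             records$region[j] < records$region[best])) {
        best <- j
      }
    }
    ids <- c(ids, records$region[best])
    remaining <- setdiff(remaining, best)
  }
  ids
}

# Small strongly informative PWM on a fixed consensus, for scan tests.
toy_pwm <- function(consensus = "ACGTACGTAC", prob = 0.985,
                    id = "toy") {
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - prob) / 3, length(idx), 4)
  m[cbind(seq_along(idx), idx)] <- prob
  pwm(id, m)
}

# Random interval tibble on a small genome.
random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 1000L, max_len = 120L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = start + sample.int(max_len, n, replace = TRUE),
                 name = sprintf("iv%03d", seq_len(n)),
                 score = 0, strand = ".")
}
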