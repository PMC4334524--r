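make_track <- function(pos, chrom = "chr1") {
  extract_cutsites(tibble::tibble(chrom = chrom, start = as.integer(pos),
                                  end = as.integer(pos) + 50L,
                                  strand = "+"), "single_end")
}

test_that("region counting follows half-open membership", {
  regions <- tibble::tibble(chrom = "chr1", start = 900L, end = 1100L,
                            name = "r1", score = 0, strand = ".")
  expect_equal(unname(count_in_regions(make_track(1000), regions)), 1L)
  # site exactly at the end coordinate is outside
  expect_equal(unname(count_in_regions(make_track(1100), regions)), 0L)
  expect_equal(unname(count_in_regions(make_track(900), regions)), 1L)

  bad <- tibble::tibble(chrom = "chr1", start = c(0L, 50L),
                        end = c(100L, 150L), name = c("a", "b"),
                        score = 0, strand = ".")
  expect_error(count_in_regions(make_track(10), bad), "overlap")
})

test_that("region counting agrees with the membership oracle", {
  for (seed in 1:100) {
    set.seed(2000 + seed)
    starts <- sort(sample(seq(0, 5000, by = 120), 10))
    regions <- tibble::tibble(chrom = "chr1", start = starts,
                              end = starts + 100L,
                              name = sprintf("r%02d", 1:10),
                              score = 0, strand = ".")
    pos <- sample.int(5200, 200, replace = TRUE)
    tr <- make_track(pos)
    got <- count_in_regions(tr, regions)
    base <- ifelse(tr$sites$strand == "-", tr$sites$pos - 1L, tr$sites$pos)
    want <- oracle_count(base, tr$sites$count, regions)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("median-of-ratios size factors match the hand-computed example", {
  m <- matrix(c(10, 30, 20, 60), 2, 2)
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-4)
  # identical columns
  m2 <- matrix(c(5, 9, 5, 9, 5, 9), 2, 3)
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))
  # global rescaling leaves factor ratios unchanged
  f1 <- size_factors(m)
  f2 <- size_factors(m * 7)
  expect_equal(f1[1] / f1[2], f2[1] / f2[2])
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)), "pseudo")
  expect_silent(size_factors(matrix(c(0, 1, 1, 0), 2, 2),
                             pseudo_reference = TRUE))
})

sim_pair <- function(seed, n = 300, lfc = 0) {
  cfg <- sim_config(seed = seed, n_regions = n, frac_open = 0,
                    frac_close = 0, dispersion = 0.1)
  s <- simulate_counts(cfg)
  s
}

test_that("adjusted p-values match the brute-force BH oracle", {
  s <- sim_pair(31)
  d <- differential_test(s$counts, s$design, c("TUM", "WT"))
  ok <- !is.na(d$p)
  expect_equal(d$padj[ok], oracle_bh(d$p[ok]))
  expect_true(all(d$padj[ok] >= d$p[ok]))
})

test_that("swapping contrast levels flips fold changes, not p-values", {
  s <- sim_pair(32)
  d1 <- differential_test(s$counts, s$design, c("TUM", "WT"))
  d2 <- differential_test(s$counts, s$design, c("WT", "TUM"))
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-6)
  expect_equal(d1$p, d2$p, tolerance = 1e-6)
})

test_that("a constant multiplier on one assay is absorbed by the batch term", {
  s <- sim_pair(33)
  d1 <- differential_test(s$counts, s$design, c("TUM", "WT"))
  y2 <- s$counts
  faire <- s$design$sample[s$design$batch == "FAIRE"]
  y2[, faire] <- y2[, faire] * 2L
  d2 <- differential_test(y2, s$design, c("TUM", "WT"))
  # exact invariance cannot hold at the count level (the dispersion is
  # re-estimated on the rescaled counts), but the typical shift is tiny
  expect_lt(stats::median(abs(d1$p - d2$p), na.rm = TRUE), 0.02)
  expect_lt(max(abs(d1$p - d2$p), na.rm = TRUE), 0.25)
  expect_lt(stats::median(abs(d1$log2fc - d2$log2fc), na.rm = TRUE), 0.05)
})

test_that("a planted batch effect does not inflate the condition test", {
  cfg <- sim_config(seed = 37, n_regions = 800, frac_open = 0,
                    frac_close = 0, dispersion = 0.1, batch_lfc = 2)
  s <- simulate_counts(cfg)
  d <- differential_test(s$counts, s$design, c("TUM", "WT"))
  expect_lt(mean(d$p < 0.05, na.rm = TRUE), 0.08)
})

test_that("extreme separation yields a confident call", {
  set.seed(9)
  cts <- rbind(matrix(c(0L, 0L, 0L, 100L, 100L, 100L), 1),
               matrix(rpois(6 * 20, 50), 20))
  rownames(cts) <- paste0("r", 1:21)
  colnames(cts) <- paste0("s", 1:6)
  des <- tibble::tibble(sample = paste0("s", 1:6),
                        condition = rep(c("A", "B"), each = 3),
                        batch = "ATAC")
  d <- differential_test(cts, des, c("B", "A"))
  expect_gt(d$log2fc[1], 5)
  expect_lt(d$padj[1], 0.01)
  # and the reverse contrast is strongly negative
  d2 <- differential_test(cts, des, c("A", "B"))
  expect_lt(d2$log2fc[1], -5)
})

test_that("differential test rejects underpowered designs", {
  s <- sim_pair(34)
  expect_error(differential_test(s$counts, s$design, c("TUM", "nope")),
               "contrast")
  des1 <- s$design[c(1, 4, 5, 6), ]
  expect_error(differential_test(s$counts[, des1$sample], des1,
                                 c("TUM", "WT")), "2 samples")
})

test_that("sample correlation is affine-invariant and separates noise", {
  s <- sim_pair(35)
  expect_equal(sample_correlation(s$counts, c("WT_1", "WT_1")), 1)
  m <- cbind(a = s$counts[, 1], b = s$counts[, 1] * 3L)
  expect_equal(sample_correlation(m, c("a", "b")), 1, tolerance = 1e-10)
  set.seed(36)
  ind <- cbind(a = rpois(5000, 50), b = rpois(5000, 50))
  expect_lt(sample_correlation(ind, c("a", "b")), 0.05)
  cst <- cbind(a = rep(5L, 10), b = rpois(10, 50))
  expect_error(sample_correlation(cst, c("a", "b")), "variance")
})
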