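test_that("cut-site extraction follows the 5' end convention", {
  fr <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1050L,
                       name = ".", score = 0, strand = "+")
  tr <- extract_cutsites(fr, "single_end")
  expect_equal(tr$sites$pos, 1000L)
  fr$strand <- "-"
  tr <- extract_cutsites(fr, "single_end")
  expect_equal(tr$sites$pos, 1050L)

  # multiplicity aggregates identical cut sites
  fr3 <- tibble::tibble(chrom = "chr1", start = 1000L,
                        end = c(1050L, 1060L, 1070L), strand = "+")
  tr3 <- extract_cutsites(fr3, "single_end")
  expect_equal(tr3$sites$count, 3L)
  expect_equal(tr3$total_count, 3L)

  # paired-end mode: both fragment ends are cut sites
  trp <- extract_cutsites(fr3, "paired_end")
  expect_equal(trp$total_count, 2L * nrow(fr3))

  frx <- fr3; frx$strand <- "."
  expect_error(extract_cutsites(frx, "single_end"), "strand")
})

test_that("coverage extends cuts to 11 bp windows and merges equal runs", {
  one <- extract_cutsites(tibble::tibble(
    chrom = "chr1", start = 1000L, end = 1050L, strand = "+"),
    "single_end")
  cov <- coverage_track(one, scale = 1)
  expect_equal(cov$start, 995)
  expect_equal(cov$end, 1006)
  expect_equal(cov$value, 1)

  two <- extract_cutsites(tibble::tibble(
    chrom = "chr1", start = c(1000L, 1003L), end = 1050L, strand = "+"),
    "single_end")
  cov2 <- coverage_track(two)
  expect_equal(cov2$start, c(995, 998, 1006))
  expect_equal(cov2$end, c(998, 1006, 1009))
  expect_equal(cov2$value, c(1, 2, 1))

  # linearity in scale, and the coverage integral identity
  cov_half <- coverage_track(two, scale = 0.5)
  expect_equal(cov_half$value, cov2$value / 2)
  expect_error(coverage_track(two, scale = 0), "positive")

  set.seed(4)
  fr <- tibble::tibble(chrom = "chr1",
                       start = sample(5000:20000, 300, replace = TRUE),
                       end = 30000L,
                       strand = sample(c("+", "-"), 300, replace = TRUE))
  tr <- extract_cutsites(fr, "single_end")
  cov <- coverage_track(tr, scale = 1.7)
  expect_equal(sum((cov$end - cov$start) * cov$value),
               11 * tr$total_count * 1.7)
})

test_that("minus-strand cut windows are centered on the 5' base", {
  tr <- extract_cutsites(tibble::tibble(
    chrom = "chr1", start = 900L, end = 1000L, strand = "-"),
    "single_end")
  cov <- coverage_track(tr)
  # cut base is 999 (= end - 1): window [994, 1005)
  expect_equal(cov$start, 994)
  expect_equal(cov$end, 1005)
})

test_that("aggregate profiles orient, localize and normalize correctly", {
  anchors <- tibble::tibble(chrom = "chr1",
                            start = c(1000L, 3000L), end = c(1200L, 3200L),
                            name = c("a", "b"), score = 0, strand = "+")
  centers <- (anchors$start + anchors$end) %/% 2L
  tr <- extract_cutsites(tibble::tibble(
    chrom = "chr1", start = centers, end = centers + 50L, strand = "+"),
    "single_end")
  prof <- aggregate_profile(tr, anchors, half_window = 100)
  expect_equal(unname(prof[["0"]]), 2)
  expect_equal(sum(prof), 2)

  pn <- aggregate_profile(tr, anchors, half_window = 100,
                          normalize = "total_in_window")
  expect_equal(sum(pn), 1)

  # flipping anchor strand mirrors the profile
  tr_off <- extract_cutsites(tibble::tibble(
    chrom = "chr1", start = centers + 30L, end = centers + 80L,
    strand = "+"), "single_end")
  p_plus <- aggregate_profile(tr_off, anchors, half_window = 100)
  anchors_minus <- anchors; anchors_minus$strand <- "-"
  p_minus <- aggregate_profile(tr_off, anchors_minus, half_window = 100)
  expect_equal(unname(p_plus[["30"]]), 2)
  expect_equal(unname(p_minus[["-30"]]), 2)

  # translation equivariance
  shift <- 12345L
  tr_shift <- extract_cutsites(tibble::tibble(
    chrom = "chr1", start = centers + shift, end = centers + shift + 50L,
    strand = "+"), "single_end")
  anchors_shift <- anchors
  anchors_shift$start <- anchors$start + shift
  anchors_shift$end <- anchors$end + shift
  expect_equal(aggregate_profile(tr_shift, anchors_shift, half_window = 100),
               prof)

  # uniform cut sites give a flat profile
  set.seed(11)
  u <- tibble::tibble(chrom = "chr1",
                      start = sample(4000:6000, 100000, replace = TRUE),
                      end = 20000L, strand = "+")
  tru <- extract_cutsites(u, "single_end")
  anch <- tibble::tibble(chrom = "chr1", start = 4000L, end = 6000L,
                         name = "m", score = 0, strand = "+")
  pf <- aggregate_profile(tru, anch, half_window = 500)
  binned <- colSums(matrix(pf[1:1000], nrow = 50))
  expect_lt(max(binned) / min(binned), 1.2)
})

test_that("fragment-length modes are detected from the histogram", {
  fr <- tibble::tibble(chrom = "chr1", start = 0L, end = 200L,
                       strand = "+")
  fh <- fragment_length_histogram(fr[rep(1, 500), ])
  expect_equal(nrow(fh$modes), 1)
  expect_equal(fh$modes$length, 200L)

  cfg <- sim_config(seed = 8, n_regions = 50,
                    fragment_modes = data.frame(
                      mean = c(100, 320), sd = c(15, 25),
                      weight = c(0.6, 0.4)))
  regs <- simulate_counts(cfg)$regions
  frs <- simulate_fragments(cfg, regs, n_fragments = 10000)
  fh2 <- fragment_length_histogram(frs)
  expect_equal(nrow(fh2$modes), 2)
  expect_lt(max(abs(fh2$modes$length - c(100, 320))), 20)

  expect_error(fragment_length_histogram(fr[0, ]), "no fragments")
  expect_error(fragment_length_histogram(fr, max_length = 100L),
               "no fragments")
})
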