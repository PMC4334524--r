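test_that("PWM construction validates and normalizes", {
  expect_error(pwm("x", matrix(1, 4, 3)), "4 columns")
  expect_error(pwm("x", matrix(1, 3, 4)), "length >= 4")
  p <- toy_pwm("ACGTA")
  expect_equal(rowSums(p$matrix), rep(1, 5), tolerance = 1e-6)
  expect_equal(pwm_consensus(p), "ACGTA")
})

test_that("best-hit scanning finds the planted consensus at closed-form score", {
  p <- toy_pwm("ACGTACGTAC")
  cons <- pwm_consensus(p)
  set.seed(41)
  bg <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
              collapse = "")
  seqs <- paste0(substr(bg, 1, 10), cons, substr(bg, 21, 100))
  hit <- scan_best_hit(seqs, p, threshold_bits = 7)
  expect_equal(hit$offset, 10L)
  expect_equal(hit$strand, "+")
  # closed-form consensus score: sum log2(p_i(consensus) / background)
  want <- sum(log2(p$matrix[cbind(1:10, match(strsplit(cons, "")[[1]],
                                              c("A", "C", "G", "T")))] /
                     0.25))
  expect_equal(hit$score, want, tolerance = 1e-10)

  # all-N scores 0 bits everywhere: below threshold 7
  expect_equal(nrow(scan_best_hit(strrep("N", 50), p, 7)), 0)
  expect_equal(scan_best_hit(strrep("N", 50), p, -Inf)$score, 0)

  # reverse complement: same score on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    seqs)))
  hit_rc <- scan_best_hit(rc, p, threshold_bits = 7)
  expect_equal(hit_rc$score, hit$score)
  expect_equal(hit_rc$strand, "-")

  # sequence shorter than the motif: no hit, no error
  expect_equal(nrow(scan_best_hit("ACGT", p, -Inf)), 0)
})

test_that("re-centering places windows on motif midpoints", {
  regions <- tibble::tibble(chrom = "chr2", start = 1000L, end = 1500L,
                            name = "r1", score = 0, strand = ".")
  hits <- tibble::tibble(region = "r1", offset = 240L, strand = "+",
                         score = 12)
  out <- recenter_on_motif(regions, hits, motif_length = 20, window = 250)
  expect_equal(out$start, 1000)
  expect_equal(out$end, 1501)
  expect_equal(out$strand, "+")

  # regions without hits are absent
  r2 <- dplyr::bind_rows(regions,
                         tibble::tibble(chrom = "chr2", start = 5000L,
                                        end = 5500L, name = "r2",
                                        score = 0, strand = "."))
  out2 <- recenter_on_motif(r2, hits, motif_length = 20, window = 250)
  expect_equal(out2$name, "r1")

  # clipping at chromosome bounds warns
  h0 <- tibble::tibble(region = "r1", offset = 0L, strand = "-", score = 1)
  r0 <- regions; r0$start <- 10L; r0$end <- 510L
  expect_warning(recenter_on_motif(r0, h0, motif_length = 20, window = 250),
                 "clipped")
})

test_that("recovery AUC equals its brute-force definition", {
  db <- paste0("r", 1:10)
  expect_equal(recovery_auc(db, c("r1", "r2"), 5), 0.9)
  expect_equal(recovery_auc(db, c("r4", "r5"), 5), 0.3)
  expect_equal(recovery_auc(db, c("r9", "r10"), 5), 0)
  expect_error(recovery_auc(db, character(0), 5), "non-empty")

  for (seed in 1:50) {
    set.seed(3000 + seed)
    n <- sample(20:60, 1)
    db <- sprintf("x%03d", sample(1000, n))
    ranking <- sample(db)
    input <- sample(db, sample(3:10, 1))
    t <- sample.int(n, 1)
    got <- recovery_auc(ranking, input, t)
    rec <- numeric(t)
    for (i in seq_len(t)) {
      rec[i] <- sum(ranking[1:i] %in% input) / length(input)
    }
    expect_equal(got, mean(rec), info = paste("seed", seed))
  }
})

test_that("NES is a population z-score over the motif collection", {
  aucs <- c(a = 0.1, b = 0.2, c = 0.3)
  nes <- nes_scores(aucs)
  expect_equal(unname(nes["c"]), 1.2247, tolerance = 1e-4)
  expect_equal(unname(nes["b"]), 0)
  # location invariance
  expect_equal(nes_scores(aucs + 0.17), nes)
  # scaling the spread scales NES inversely
  expect_equal(nes_scores(0.5 + 2 * (aucs - 0.2)), nes)
  expect_error(nes_scores(c(1, 2)), "at least 3")
  expect_error(nes_scores(c(a = .1, b = .1, c = .1)), "variance")
})

test_that("a planted motif is recovered by ranking and targeted", {
  cfg <- sim_config(seed = 9, n_regions = 300, n_chroms = 2)
  st <- simulate_motif_study(cfg, n_input = 40, n_bearing = 32,
                             n_decoys = 10)
  rks <- build_rankings(st$sequences, st$pwms)
  er <- enrich(st$input_ids, rks, rank_threshold = 300)
  expect_equal(er$table$motif[1], "M")
  expect_gt(er$table$nes[1], 2.5)
  rec <- length(intersect(er$targets$M, st$bearing_ids)) /
    length(st$bearing_ids)
  expect_gte(rec, 0.9)
})

test_that("input regions map onto a database by reciprocal overlap", {
  db <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L),
                       end = c(500L, 1500L), name = c("d1", "d2"),
                       score = 0, strand = ".")
  inp <- tibble::tibble(chrom = "chr1", start = c(100L, 2000L),
                        end = c(600L, 2400L))
  m <- map_regions_to_database(inp, db, 0.4)
  expect_equal(m$ids, "d1")
  expect_equal(m$n_unmapped, 1)
})
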