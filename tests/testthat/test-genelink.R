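toy_models <- function() {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"),
    chrom = "chr1",
    start = c(20000L, 32000L),
    end = c(30000L, 40000L),
    strand = c("+", "-"),
    tss = c(20000L, 39999L))
  introns <- as_bed(tibble::tibble(
    chrom = "chr1",
    start = c(22000L, 26000L, 34000L),
    end = c(24000L, 28000L, 36000L),
    name = c("gA", "gA", "gB")))
  list(genes = genes, introns = introns)
}

peak_row <- function(start, end, name, lfc = 1, p = 1e-4, padj = 1e-3) {
  tibble::tibble(chrom = "chr1", start = as.integer(start),
                 end = as.integer(end), name = name,
                 log2fc = lfc, p = p, padj = padj)
}

test_that("peaks link to genes through introns and the upstream window", {
  models <- toy_models()
  peaks <- dplyr::bind_rows(
    peak_row(16800, 17200, "p_up3kb"),      # 3 kb upstream of gA TSS
    peak_row(13500, 13900, "p_up6kb"),      # 6 kb upstream: too far
    peak_row(26500, 26900, "p_intron2"),    # inside gA intron 2
    peak_row(41000, 41400, "p_upB"),        # 1-1.4 kb upstream of gB (-)
    peak_row(50000, 50400, "p_desert"))
  links <- assign_peaks(peaks, models, mode = "upstream5kb_intronic")
  expect_equal(links$peak[links$gene == "gA"], "p_up3kb")
  expect_equal(links$peak[links$gene == "gB"], "p_upB")
  expect_false("p_up6kb" %in% links$peak)
  expect_false("p_desert" %in% links$peak)

  # the retained peak per gene is the most significant one
  peaks2 <- dplyr::bind_rows(
    peak_row(16800, 17200, "weak", padj = 0.5),
    peak_row(26500, 26900, "strong", padj = 1e-6))
  links2 <- assign_peaks(peaks2, models)
  expect_equal(links2$peak[links2$gene == "gA"], "strong")

  # a peak in an intron that is also upstream of a neighbor links to both
  models3 <- toy_models()
  models3$genes$start[2] <- 27500L
  models3$genes$end[2] <- 35000L
  models3$genes$strand[2] <- "+"
  models3$genes$tss[2] <- 27500L
  links3 <- assign_peaks(peak_row(26500, 26900, "shared"), models3)
  expect_setequal(links3$gene, c("gA", "gB"))
})

test_that("nearest-TSS mode assigns every peak to exactly one gene", {
  models <- toy_models()
  peaks <- dplyr::bind_rows(
    peak_row(100, 500, "far_left"),
    peak_row(29000, 29400, "between"),
    peak_row(60000, 60400, "far_right"))
  links <- assign_peaks(peaks, models, mode = "nearest_tss")
  expect_setequal(links$gene, c("gA", "gB"))
  # ties resolve to the leftmost peak; the gB link is the right-hand peak
  expect_equal(links$peak[links$gene == "gA"], "far_left")
  expect_equal(links$peak[links$gene == "gB"], "far_right")
})

test_that("ranked gene lists order by metric with deterministic ties", {
  links <- tibble::tibble(gene = c("g1", "g2"), peak = c("a", "b"),
                          log2fc = c(2, -2), p = c(1e-3, 1e-3),
                          padj = c(1e-2, 1e-2))
  rk <- ranked_list(links)
  expect_equal(rk$gene, c("g1", "g2"))
  ties <- tibble::tibble(gene = c("gz", "ga"), peak = c("a", "b"),
                         log2fc = c(1, 1), p = 0.01, padj = 0.1)
  expect_equal(ranked_list(ties)$gene, c("ga", "gz"))

  set.seed(71)
  big <- tibble::tibble(gene = sprintf("g%03d", 1:500), peak = "x",
                        log2fc = round(rnorm(500), 3),
                        p = runif(500), padj = runif(500))
  got <- ranked_list(big)$gene
  want <- big$gene[order(-big$log2fc, big$gene)]
  expect_equal(got, want)
})

test_that("GSEA enrichment scores match hand and brute-force computation", {
  # perfectly concentrated set: the running sum tops out at 1
  rk <- tibble::tibble(gene = paste0("g", 1:10), score = 10:1)
  r <- gsea(rk, paste0("g", 1:5), weight = 0, n_perm = 100, seed = 1)
  expect_equal(r$es, 1)

  rk5 <- tibble::tibble(gene = paste0("g", 1:5), score = c(5, 4, 3, 2, 1))
  r5 <- gsea(rk5, c("g1", "g3"), weight = 1, n_perm = 100, seed = 1)
  expect_equal(r5$es, 0.6667, tolerance = 1e-4)
  expect_equal(r5$leading_edge, c("g1", "g3"))

  expect_error(gsea(rk5, c("zz"), n_perm = 100), "disjoint")

  # brute-force equivalence on random instances
  for (seed in 1:50) {
    set.seed(4000 + seed)
    n <- sample(10:50, 1)
    scores <- sort(round(rnorm(n, 0, 2), 2), decreasing = TRUE)
    rkx <- tibble::tibble(gene = sprintf("g%03d", 1:n), score = scores)
    nh <- sample(2:(n - 2), 1)
    gs <- sample(rkx$gene, nh)
    w <- sample(c(0, 1), 1)
    if (w == 1 && all(abs(scores[rkx$gene %in% gs]) == 0)) next
    got <- gsea(rkx, gs, weight = w, n_perm = 100, seed = 5)$es
    want <- oracle_gsea_es(rkx$gene %in% gs, abs(scores), w)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("enhancer recovery curves count first-overlap ranks", {
  ranked <- tibble::tibble(chrom = "chr1",
                           start = seq(0L, 900L, by = 100L),
                           end = seq(50L, 950L, by = 100L),
                           name = paste0("pk", 1:10), score = 10:1,
                           strand = ".")
  # enhancers identical to the top 3 regions
  sets <- list(top3 = ranked[1:3, c("chrom", "start", "end")],
               nowhere = tibble::tibble(chrom = "chr9", start = 1L,
                                        end = 100L))
  curves <- enhancer_recovery(ranked, sets)
  expect_equal(curves$top3[3], 3L)
  expect_equal(curves$top3[10], 3L)
  expect_true(all(curves$nowhere == 0))
  expect_warning(enhancer_recovery(ranked, list(empty = ranked[0, ])),
                 "empty")
})

test_that("peak location categories partition with fixed precedence", {
  models <- toy_models()
  peaks <- dplyr::bind_rows(
    peak_row(19400, 19600, "prom"),     # overlaps [19000, 20000) promoter
    peak_row(26500, 26900, "intr"),     # inside gA intron 2
    peak_row(21000, 21500, "exon"),     # gA body outside introns
    peak_row(50000, 50400, "dist"),
    peak_row(19900, 20100, "promexon")) # spans TSS: promoter wins
  ann <- annotate_locations(peaks, models, promoter_bp = 1000)
  expect_equal(ann$categories,
               c("promoter", "intron", "exon", "distal_intergenic",
                 "promoter"))
  expect_equal(sum(ann$counts), nrow(peaks))
})

test_that("probe collapse keeps the most significant probe per gene", {
  de <- tibble::tibble(gene = c("a", "a", "b"),
                       logFC = c(1, 2, 3),
                       p = c(0.2, 0.001, 0.01),
                       padj = c(0.4, 0.01, 0.05))
  got <- collapse_probes(de)
  expect_equal(nrow(got), 2)
  expect_equal(got$logFC[got$gene == "a"], 2)
})
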