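#' Assign peaks to genes
#'
#' In `upstream5kb_intronic` mode a peak links to a gene if it overlaps any
#' of the gene's introns or the strand-aware upstream window of the TSS
#' (exclusive of the gene body); a peak may link to several genes.  In
#' `nearest_tss` mode every peak links to exactly one gene, the one whose
#' TSS is closest to the peak midpoint.  Per gene, the retained peak is the
#' most significant one (smallest `padj`, ties by larger `|log2fc|`, then
#' leftmost start).
#'
#' @param peaks Tibble combining interval columns (`chrom`, `start`, `end`,
#'   `name`) with differential columns (`log2fc`, `p`, `padj`).
#' @param models Gene models from [read_gene_models()] /
#'   [simulate_annotation()].
#' @param mode `"upstream5kb_intronic"` or `"nearest_tss"`.
#' @param upstream_bp Upstream window size (default 5000).
#' @return Tibble `gene`, `peak`, `log2fc`, `p`, `padj` with one row per
#'   gene that received a peak.
#' @export
assign_peaks <- function(peaks, models,
                         mode = c("upstream5kb_intronic", "nearest_tss"),
                         upstream_bp = 5000L) {
  mode <- match.arg(mode)
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("chrom", "start", "end", "name", "log2fc", "padj")
                %in% names(peaks)))
  g <- models$genes
  if (any(is.na(g$tss))) {
    warning(sum(is.na(g$tss)), " gene(s) without TSS skipped")
    g <- g[!is.na(g$tss), ]
  }
  links <- NULL
  if (mode == "upstream5kb_intronic") {
    upstream <- tibble::tibble(
      chrom = g$chrom,
      start = ifelse(g$strand == "-", g$tss + 1L,
                     pmax(g$tss - upstream_bp, 0L)),
      end = ifelse(g$strand == "-", g$tss + 1L + upstream_bp, g$tss),
      name = g$gene_id)
    upstream <- upstream[upstream$end > upstream$start, ]
    targets <- dplyr::bind_rows(models$introns[c("chrom", "start", "end",
                                                 "name")],
                                upstream)
    ov <- bed_overlaps(peaks, targets)
    if (nrow(ov) == 0) {
      return(tibble::tibble(gene = character(), peak = character(),
                            log2fc = numeric(), p = numeric(),
                            padj = numeric()))
    }
    links <- tibble::tibble(gene = targets$name[ov$b_idx],
                            peak_idx = ov$a_idx)
    links <- dplyr::distinct(links)
  } else {
    mid <- (peaks$start + peaks$end) %/% 2L
    gi <- vapply(seq_len(nrow(peaks)), function(i) {
      cand <- which(g$chrom == peaks$chrom[i])
      if (length(cand) == 0) return(NA_integer_)
      dd <- abs(g$tss[cand] - mid[i])
      cand[order(dd, g$gene_id[cand])][1]
    }, integer(1))
    keep <- !is.na(gi)
    links <- tibble::tibble(gene = g$gene_id[gi[keep]],
                            peak_idx = which(keep))
  }
  links$padj <- peaks$padj[links$peak_idx]
  links$p <- peaks$p[links$peak_idx]
  links$log2fc <- peaks$log2fc[links$peak_idx]
  links$peak <- peaks$name[links$peak_idx]
  links$start <- peaks$start[links$peak_idx]
  links <- links[order(links$gene, links$padj, -abs(links$log2fc),
                       links$start), ]
  links <- links[!duplicated(links$gene), ]
  tibble::as_tibble(links[c("gene", "peak", "log2fc", "p", "padj")])
}

#' Ranked gene list from peak-gene links
#'
#' Orders genes by the chosen metric of their retained peak, descending
#' (most strongly opening on top, closing at the bottom); exact ties break
#' lexicographically by gene id.
#'
#' @param links Tibble from [assign_peaks()].
#' @param metric `"log2fc"` or `"signed_logp"`
#'   (`sign(log2fc) * -log10(p)`).
#' @return Tibble `gene`, `score` in rank order.
#' @export
ranked_list <- function(links, metric = c("log2fc", "signed_logp")) {
  metric <- match.arg(metric)
  score <- switch(metric,
                  log2fc = links$log2fc,
                  signed_logp = sign(links$log2fc) *
                    -log10(pmax(links$p, 1e-300)))
  out <- tibble::tibble(gene = links$gene, score = score)
  out[order(-out$score, out$gene), ]
}

# Enrichment score of a preranked GSEA given sorted hit positions.
# Extremes of the running sum occur only at, or just before, hit positions.
gsea_es <- function(hit_pos, hit_weights, n_total) {
  nh <- length(hit_pos)
  miss_pen <- 1 / (n_total - nh)
  cw <- cumsum(hit_weights)
  k <- seq_len(nh)
  after <- cw - (hit_pos - k) * miss_pen           # just after each hit
  before <- c(0, cw[-nh]) - (hit_pos - k) * miss_pen      # just before
  hi <- max(after)
  lo <- min(c(before, cw[nh] - (n_total - nh) * miss_pen))
  if (hi >= -lo) hi else lo
}

#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running statistic on a ranked gene list:
#' hits increment by `|score|^weight` (normalized over the set), misses
#' decrement by `1/(N - Nh)`; the enrichment score (ES) is the extremum of
#' the running sum.  The null is built by permuting gene labels (the only
#' valid scheme for a preranked list); `nes = es / mean(|null es| of the
#' same sign)` and the p-value is the add-one-corrected fraction of
#' same-sign null ES at least as extreme.
#'
#' @param ranked Tibble `gene`, `score` from [ranked_list()] (rank order).
#' @param gene_set Character vector of gene ids.
#' @param weight 0 (classical KS) or 1 (score-weighted).
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Integer seed for the permutations.
#' @return List: `es`, `nes`, `p`, `leading_edge` (gene ids up to the ES
#'   extremum for positive ES, from it for negative), `n_hits`.
#' @export
gsea <- function(ranked, gene_set, weight = 1, n_perm = 1000L, seed = 1L) {
  stopifnot(weight %in% c(0, 1), n_perm >= 100)
  genes <- ranked$gene
  n <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene_set is disjoint from the ranked list")
  if (nh == n) stop("gene_set covers the whole ranked list")
  absw <- if (weight == 0) rep(1, n) else abs(ranked$score)
  # guard: all-zero weights degenerate to classical increments
  if (all(absw[hit] == 0)) absw <- rep(1, n)
  pos <- which(hit)
  w_obs <- absw[pos] / sum(absw[pos])
  es <- gsea_es(pos, w_obs, n)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    p <- sort(sample.int(n, nh))
    w <- absw[p] / sum(absw[p])
    gsea_es(p, w, n)
  }, numeric(1))
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  run_best <- if (es >= 0) {
    cw <- cumsum(w_obs)
    k <- seq_along(pos)
    kstar <- which.max(cw - (pos - k) / (n - nh))
    genes[pos[seq_len(kstar)]]
  } else {
    cw <- c(0, cumsum(w_obs)[-nh])
    k <- seq_along(pos)
    kstar <- which.min(cw - (pos - k + 1) / (n - nh))
    genes[pos[pos >= pos[kstar]]]
  }
  list(es = es, nes = nes, p = p, leading_edge = run_best, n_hits = nh)
}

#' Recovery of curated enhancer sets down a region ranking
#'
#' For each named enhancer set, counts how many enhancers have been hit
#' (>= 1 bp overlap) by the regions seen so far while descending the
#' ranking — the curve used to compare how well ATAC and FAIRE peaks
#' recover known enhancers.
#'
#' @param ranked_regions Interval tibble in rank order (best first).
#' @param enhancer_sets Named list of interval tibbles.
#' @return Named list of integer vectors; element i of a curve is the
#'   number of distinct enhancers recovered by rank i.  Empty sets are
#'   skipped with a warning.
#' @export
enhancer_recovery <- function(ranked_regions, enhancer_sets) {
  ranked_regions <- as_bed(ranked_regions)
  n <- nrow(ranked_regions)
  out <- list()
  for (nm in names(enhancer_sets)) {
    enh <- enhancer_sets[[nm]]
    if (is.null(enh) || nrow(enh) == 0) {
      warning("enhancer set '", nm, "' is empty; skipped")
      next
    }
    ov <- bed_overlaps(as_bed(enh), ranked_regions)
    curve <- integer(n)
    if (nrow(ov) > 0) {
      first_rank <- tapply(ov$b_idx, ov$a_idx, min)
      curve <- cumsum(tabulate(first_rank, nbins = n))
    }
    out[[nm]] <- curve
  }
  out
}

#' Genomic-location annotation of peaks
#'
#' Assigns each peak one category with precedence
#' promoter > exon > intron > distal_intergenic, where the promoter is the
#' strand-aware `promoter_bp` window upstream of the TSS and exons are the
#' gene span minus the introns.
#'
#' @param peaks Interval tibble.
#' @param models Gene models.
#' @param promoter_bp Promoter window size (default 1000).
#' @return List with `categories` (character per peak) and `counts`
#'   (named table over the four categories).
#' @export
annotate_locations <- function(peaks, models, promoter_bp = 1000L) {
  peaks <- as_bed(peaks)
  g <- models$genes
  prom <- tibble::tibble(
    chrom = g$chrom,
    start = ifelse(g$strand == "-", g$tss + 1L,
                   pmax(g$tss - promoter_bp, 0L)),
    end = ifelse(g$strand == "-", g$tss + 1L + promoter_bp, g$tss))
  prom <- prom[prom$end > prom$start, ]
  introns <- models$introns
  # explicit exon intervals: gene span minus its introns
  exons <- lapply(seq_len(nrow(g)), function(i) {
    span <- IRanges::IRanges(g$start[i] + 1L, g$end[i])
    ints <- introns[introns$name == g$gene_id[i], ]
    ex <- if (nrow(ints) == 0) span else
      BiocGenerics::setdiff(span, IRanges::IRanges(ints$start + 1L,
                                                   ints$end))
    tibble::tibble(chrom = g$chrom[i], start = IRanges::start(ex) - 1L,
                   end = IRanges::end(ex))
  })
  exons <- dplyr::bind_rows(exons)
  cat <- rep("distal_intergenic", nrow(peaks))
  in_any <- function(targets) {
    if (nrow(targets) == 0) return(logical(nrow(peaks)))
    seq_len(nrow(peaks)) %in% bed_overlaps(peaks, targets)$a_idx
  }
  cat[in_any(introns)] <- "intron"
  cat[in_any(exons)] <- "exon"
  cat[in_any(prom)] <- "promoter"
  counts <- table(factor(cat, levels = c("promoter", "exon", "intron",
                                         "distal_intergenic")))
  list(categories = cat, counts = counts)
}

#' Collapse probe-level differential expression to genes
#'
#' For microarray tables with several probes per gene, keeps per gene the
#' probe with the most significant adjusted p-value.
#'
#' @param de Tibble with columns `gene`, `logFC`, `p`, `padj`.
#' @return One row per gene.
#' @export
collapse_probes <- function(de) {
  de <- tibble::as_tibble(de)
  stopifnot(all(c("gene", "logFC", "p", "padj") %in% names(de)))
  de <- de[order(de$gene, de$padj, de$p), ]
  de[!duplicated(de$gene), ]
}
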