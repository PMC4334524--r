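#' Genomic intervals as BED-convention tibbles
#'
#' Throughout the package, genomic intervals are plain tibbles in BED
#' convention: 0-based, half-open `[start, end)` coordinates with columns
#' `chrom`, `start`, `end` and optionally `name`, `score`, `strand`.
#' `as_bed()` coerces and validates a data frame into this shape.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (missing optional columns filled with `"."`, `0`, `"."`).
#' @export
as_bed <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    stop("interval table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"name" %in% names(x)) x$name <- "."
  if (!"score" %in% names(x)) x$score <- 0
  if (!"strand" %in% names(x)) x$strand <- "."
  if (any(is.na(x$start)) || any(is.na(x$end))) {
    stop("interval coordinates must not be NA")
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    stop("invalid interval at row ", bad[1], ": need 0 <= start < end")
  }
  if (any(!nzchar(as.character(x$chrom)))) stop("empty chrom name")
  x[c("chrom", "start", "end", "name", "score", "strand")]
}

#' Single-linkage merge of intervals
#'
#' Merges every group of intervals connected by >= 1 bp overlap into one
#' interval (single linkage).  Because coordinates are half-open, abutting
#' intervals (`[100,200)` and `[200,300)`) do not overlap and are kept
#' separate.  This is the operator used both for building the combined peak
#' set across samples and for clustering differential peaks into unique
#' candidate regulatory regions.
#'
#' @param x Interval tibble (or list of tibbles, concatenated first).
#' @return Sorted, non-overlapping interval tibble.  Column `n_merged`
#'   records how many input intervals each output interval absorbed.
#' @export
merge_intervals <- function(x) {
  if (is.data.frame(x)) x <- list(x)
  x <- lapply(x, as_bed)
  x <- dplyr::bind_rows(x)
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_merged = integer()))
  }
  x <- dplyr::arrange(x, .data$chrom, .data$start, .data$end)
  out <- lapply(split(x, x$chrom), function(d) {
    # new cluster starts where start >= running max of previous ends
    hi <- cummax(d$end)
    cl <- cumsum(c(TRUE, d$start[-1] >= hi[-nrow(d)]))
    tibble::tibble(
      chrom = d$chrom[1],
      start = as.vector(tapply(d$start, cl, min)),
      end = as.vector(tapply(d$end, cl, max)),
      n_merged = as.vector(tapply(cl, cl, length)))
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

# Overlap join between two BED tibbles; returns index pairs and overlap widths.
bed_overlaps <- function(a, b) {
  a <- as_bed(a); b <- as_bed(b)
  res <- list()
  for (chr in unique(a$chrom)) {
    ia <- which(a$chrom == chr)
    ib <- which(b$chrom == chr)
    if (length(ib) == 0) next
    ra <- IRanges::IRanges(a$start[ia] + 1L, a$end[ia])
    rb <- IRanges::IRanges(b$start[ib] + 1L, b$end[ib])
    hits <- IRanges::findOverlaps(ra, rb)
    if (length(hits) == 0) next
    qa <- ia[S4Vectors::queryHits(hits)]
    qb <- ib[S4Vectors::subjectHits(hits)]
    ov <- pmin(a$end[qa], b$end[qb]) - pmax(a$start[qa], b$start[qb])
    res[[chr]] <- tibble::tibble(a_idx = qa, b_idx = qb, overlap = ov)
  }
  if (length(res) == 0) {
    return(tibble::tibble(a_idx = integer(), b_idx = integer(),
                          overlap = integer()))
  }
  dplyr::bind_rows(res)
}

#' Filter intervals by fractional overlap
#'
#' Keeps each interval of `a` for which some single interval of `b` covers at
#' least `min_frac` of its length, mirroring the `-f` semantics of
#' `bedtools intersect` (the fraction is evaluated per overlapping `b`
#' interval, never summed across them).  With `min_frac = 0.4` this is the
#' 40%-overlap rule used to compare peak sets against reference regions.
#'
#' @param a,b Interval tibbles.
#' @param min_frac Required overlap fraction of each `a` interval, in (0, 1].
#' @return The subset of `a` passing the filter, original row order.
#' @export
overlap_fraction_filter <- function(a, b, min_frac = 0.4) {
  stopifnot(is.numeric(min_frac), length(min_frac) == 1)
  if (!(min_frac > 0 && min_frac <= 1)) stop("min_frac must be in (0, 1]")
  a <- as_bed(a)
  if (nrow(a) == 0 || nrow(b) == 0) return(a[0, ])
  ov <- bed_overlaps(a, b)
  if (nrow(ov) == 0) return(a[0, ])
  len <- (a$end - a$start)[ov$a_idx]
  keep <- sort(unique(ov$a_idx[ov$overlap >= min_frac * len]))
  a[keep, ]
}
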