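#' Read a BED file into an interval tibble
#'
#' BED3 to BED6 are accepted; absent optional columns are filled with
#' defaults.  Coordinates stay 0-based half-open.
#'
#' @param path Path to a (plain-text, uncompressed) BED file.
#' @return An interval tibble (see [as_bed()]).
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", comment.char = "#")
  if (ncol(x) < 3) stop("BED file has fewer than 3 columns: ", path)
  x <- x[, seq_len(min(ncol(x), 6)), drop = FALSE]
  names(x) <- cols[seq_len(ncol(x))]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if ("score" %in% names(x)) x$score <- suppressWarnings(as.numeric(x$score))
  as_bed(x)
}

#' Write an interval tibble as BED6
#' @param x Interval tibble.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  x <- as_bed(x)
  readr::write_tsv(x, path, col_names = FALSE)
  invisible(path)
}

#' Write a coverage tibble as bedGraph
#' @param x Tibble with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  readr::write_tsv(x[c("chrom", "start", "end", "value")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' First column holds region ids; remaining columns are integer counts, one
#' per sample.
#' @param path Path to counts TSV.
#' @return Integer matrix, region ids as rownames.
#' @export
read_counts <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(x[[1]])
  m
}

#' Write a count matrix to TSV
#' @param counts Integer matrix with rownames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(region = rownames(counts), counts, check.names = FALSE)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}

#' Read a sample design table
#'
#' Columns: `sample`, `condition`, `batch` (assay: e.g. ATAC/FAIRE) and
#' optionally `replicate`.
#' @param path Path to design TSV.
#' @return Design tibble.
#' @export
read_design <- function(path) {
  x <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                           colClasses = "character"))
  req <- c("sample", "condition", "batch")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("design is missing column(s): ",
                         paste(miss, collapse = ", "))
  x
}

#' Parse position weight matrices from JASPAR-style text
#'
#' Accepts the JASPAR `.pfm` dialect: a `>id` header followed by four rows of
#' counts or frequencies, either bare numbers or wrapped as
#' `A [ 1 2 3 ]`.  Also accepts the Cluster-Buster dialect, where each
#' `>id` block lists one row per motif position with four columns (A C G T).
#' Counts are converted to per-position probabilities with a pseudocount.
#'
#' @param path Path to the motif file.
#' @param dialect `"jaspar"` (rows = bases) or `"clusterbuster"`
#'   (rows = positions).
#' @param pseudocount Added to every cell before normalization.
#' @param background Background base probabilities (A, C, G, T).
#' @return Named list of PWM objects (see [pwm()]).
#' @export
read_pwms <- function(path, dialect = c("jaspar", "clusterbuster"),
                      pseudocount = 0.001,
                      background = rep(0.25, 4)) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no '>' motif headers found in ", path)
  blocks <- Map(function(from, to) lines[from:to],
                hdr, c(hdr[-1] - 1L, length(lines)))
  out <- list()
  for (blk in blocks) {
    id <- sub("^>\\s*", "", blk[1])
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- blk[-1]
    num <- lapply(body, function(l) {
      l <- gsub("[][]", " ", l)
      l <- sub("^\\s*[ACGTacgt][:|]?\\s+", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    mat <- do.call(rbind, num)
    if (dialect == "jaspar") {
      if (nrow(mat) != 4) stop("JASPAR motif ", id, " must have 4 rows")
      mat <- t(mat)
    } else if (ncol(mat) != 4) {
      stop("Cluster-Buster motif ", id, " must have 4 columns")
    }
    out[[id]] <- pwm(id, mat, background = background,
                     pseudocount = pseudocount)
  }
  out
}

#' Load gene models from a GFF3 file
#'
#' Reads `gene` and `exon` features, derives each gene's strand-aware TSS and
#' its intron intervals (gaps between the union of exons of all isoforms).
#' Coordinates are converted from GFF's 1-based closed convention to the
#' package's 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A list with `genes` (tibble: gene_id, chrom, start, end, strand,
#'   tss) and `introns` (interval tibble with `name` = gene_id).
#' @export
read_gene_models <- function(path) {
  x <- rtracklayer::readGFF(path,
                            columns = c("seqid", "type", "start", "end",
                                        "strand"),
                            tags = c("ID", "Parent"))
  x <- as.data.frame(x)
  genes <- x[x$type == "gene", ]
  if (nrow(genes) == 0) stop("no gene features in ", path)
  gid <- as.character(genes$ID)
  g <- tibble::tibble(
    gene_id = gid,
    chrom = as.character(genes$seqid),
    start = genes$start - 1L,   # to 0-based half-open
    end = genes$end,
    strand = genes$strand
  )
  g$tss <- ifelse(g$strand == "-", g$end - 1L, g$start)
  exons <- x[x$type == "exon", ]
  introns <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), name = character())
  if (nrow(exons) > 0) {
    pid <- vapply(exons$Parent, function(p)
      if (length(p) > 0) as.character(p)[1] else NA_character_,
      character(1))
    # Parent may be a transcript id of form <gene>.t<k> or the gene itself
    pgene <- sub("\\.t[0-9]+$", "", pid)
    per_gene <- split(seq_len(nrow(exons)), pgene)
    ilist <- lapply(names(per_gene), function(id) {
      rows <- exons[per_gene[[id]], ]
      r <- IRanges::reduce(IRanges::IRanges(rows$start, rows$end))
      grow <- g[match(id, g$gene_id), ]
      if (is.na(grow$gene_id[1])) return(NULL)
      gaps <- IRanges::gaps(r, start = grow$start + 1L, end = grow$end)
      if (length(gaps) == 0) return(NULL)
      tibble::tibble(chrom = grow$chrom, start = IRanges::start(gaps) - 1L,
                     end = IRanges::end(gaps), name = id)
    })
    ilist <- ilist[!vapply(ilist, is.null, logical(1))]
    if (length(ilist)) introns <- dplyr::bind_rows(ilist)
  }
  list(genes = g, introns = as_bed(introns))
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()] for simulated annotations: writes one
#' `gene` feature per gene and one `exon` feature per exonic segment (the
#' complement of the introns within the gene span).
#'
#' @param models List with `genes` and `introns` as from [read_gene_models()].
#' @param path Output path.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  introns <- models$introns
  rows <- character(0)
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    rows <- c(rows, paste(gi$chrom, "regland", "gene", gi$start + 1L, gi$end,
                          ".", gi$strand, ".", paste0("ID=", gi$gene_id),
                          sep = "\t"))
    ints <- introns[introns$name == gi$gene_id, ]
    span <- IRanges::IRanges(gi$start + 1L, gi$end)
    ex <- if (nrow(ints) == 0) span else
      BiocGenerics::setdiff(span, IRanges::IRanges(ints$start + 1L, ints$end))
    for (j in seq_along(ex)) {
      rows <- c(rows, paste(gi$chrom, "regland", "exon",
                            IRanges::start(ex)[j], IRanges::end(ex)[j],
                            ".", gi$strand, ".",
                            paste0("ID=", gi$gene_id, ".e", j,
                                   ";Parent=", gi$gene_id, ".t1"),
                            sep = "\t"))
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
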