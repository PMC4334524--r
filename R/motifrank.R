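#' Position weight matrix
#'
#' A PWM is stored as a positions x 4 probability matrix (columns A, C, G,
#' T) with a background distribution and pseudocount.  Count or frequency
#' matrices are normalized per position after adding the pseudocount, which
#' guards against minus-infinity log-odds for zero counts.
#'
#' @param id Motif identifier.
#' @param matrix Numeric matrix, positions x 4 (counts, frequencies or
#'   probabilities).
#' @param background Background base probabilities (A, C, G, T).
#' @param pseudocount Added to every cell before per-position
#'   renormalization.
#' @return A `regland_pwm` object with elements `id`, `matrix` (row sums
#'   1), `background`, `lod` (log2-odds matrix), `length`.
#' @export
pwm <- function(id, matrix, background = rep(0.25, 4),
                pseudocount = 0.001) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4) stop("PWM matrix must have 4 columns (A, C, G, T)")
  if (nrow(matrix) < 4) stop("PWM must have length >= 4")
  if (any(matrix < 0)) stop("PWM entries must be non-negative")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 probabilities summing to 1")
  }
  m <- matrix + pseudocount
  m <- m / rowSums(m)
  colnames(m) <- c("A", "C", "G", "T")
  lod <- log2(sweep(m, 2, background, "/"))
  structure(list(id = id, matrix = m, background = background,
                 pseudocount = pseudocount, lod = lod,
                 length = nrow(m)),
            class = "regland_pwm")
}

#' @export
print.regland_pwm <- function(x, ...) {
  cat("<pwm>", x$id, "length", x$length, "\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param x A [pwm()] object.
#' @return Character string of most probable bases.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "regland_pwm"))
  paste(colnames(x$matrix)[apply(x$matrix, 1, which.max)], collapse = "")
}

# Encode a DNA string as 1..4 (A,C,G,T), NA elsewhere (N etc.).
encode_dna <- function(sequence) {
  v <- strsplit(toupper(sequence), "")[[1]]
  match(v, c("A", "C", "G", "T"))
}

# Coerce sequences (DNAStringSet or character) keeping names.
chr_seqs <- function(sequences) {
  if (is.character(sequences)) return(sequences)
  s <- as.character(sequences)
  if (is.null(names(s))) names(s) <- names(sequences)
  s
}

# Best log2-odds score over both strands for a pre-encoded sequence.
best_score_code <- function(code, lod) {
  if (length(code) < nrow(lod)) return(-Inf)
  f <- scan_scores(code, lod)
  r <- scan_scores(rev(5L - code), lod)
  max(f, r)
}

# Log2-odds score at every offset on one strand; N bases contribute 0.
scan_scores <- function(code, lod) {
  L <- nrow(lod)
  n <- length(code) - L + 1L
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (i in seq_len(L)) {
    contrib <- lod[i, ][code[i:(i + n - 1L)]]
    contrib[is.na(contrib)] <- 0
    sc <- sc + contrib
  }
  sc
}

#' Best PWM hit in a sequence
#'
#' Scores every offset on both strands with the log2 likelihood ratio
#' (PWM vs background) and returns the maximum if it reaches the
#' threshold.  `N` positions contribute 0 bits.  Ties are resolved in
#' favor of the smallest offset, `+` strand first.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param pwm A [pwm()] object.
#' @param threshold_bits Minimum score in bits; use `-Inf` to always get
#'   the best hit.
#' @return Tibble with one row (`offset` 0-based, `strand`, `score`), or a
#'   zero-row tibble if no position reaches the threshold (including when
#'   the sequence is shorter than the motif).
#' @export
scan_best_hit <- function(sequence, pwm, threshold_bits = 7) {
  stopifnot(inherits(pwm, "regland_pwm"))
  empty <- tibble::tibble(offset = integer(), strand = character(),
                          score = numeric())
  code <- encode_dna(sequence)
  if (length(code) < pwm$length) return(empty)
  fwd <- scan_scores(code, pwm$lod)
  # reverse strand: complement code (A<->T, C<->G) and reverse
  rc <- rev(5L - code)
  rev_sc <- scan_scores(rc, pwm$lod)
  # offset in original coordinates for reverse hits
  n <- length(fwd)
  rev_sc <- rev(rev_sc)
  best <- max(fwd, rev_sc)
  if (best < threshold_bits) return(empty)
  # smallest offset wins; '+' preferred on exact tie
  cand_f <- which(fwd == best)
  cand_r <- which(rev_sc == best)
  off_f <- if (length(cand_f)) cand_f[1] else Inf
  off_r <- if (length(cand_r)) cand_r[1] else Inf
  if (off_f <= off_r) {
    tibble::tibble(offset = unname(off_f) - 1L, strand = "+",
                   score = unname(best))
  } else {
    tibble::tibble(offset = unname(off_r) - 1L, strand = "-",
                   score = unname(best))
  }
}

#' Best-hit scores for a set of region sequences
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @param pwm A [pwm()] object.
#' @param threshold_bits Minimum reported score (default `-Inf`: score
#'   every region).
#' @return Tibble `region`, `offset`, `strand`, `score` (regions without a
#'   hit are absent).
#' @export
scan_regions <- function(sequences, pwm, threshold_bits = -Inf) {
  seqs <- chr_seqs(sequences)
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  hits <- lapply(names(seqs), function(id) {
    h <- scan_best_hit(seqs[[id]], pwm, threshold_bits)
    if (nrow(h) == 0) return(NULL)
    h$region <- id
    h
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0) {
    return(tibble::tibble(region = character(), offset = integer(),
                          strand = character(), score = numeric()))
  }
  dplyr::bind_rows(hits)[c("region", "offset", "strand", "score")]
}

#' Re-center regions on their best motif hit
#'
#' Replaces each region by a fixed-size window centered on the midpoint of
#' its best-scoring motif instance, oriented by the hit strand — the
#' preparation step for footprint aggregation around, e.g., CTCF motifs.
#' Regions without a hit are dropped.
#'
#' @param regions Interval tibble; `name` must match `hits$region`.
#' @param hits Tibble from [scan_regions()] (one row per region).
#' @param motif_length Motif length in bp.
#' @param window Half-window; output intervals are
#'   `[center - window, center + window + 1)`.
#' @param chrom_sizes Optional named vector for clipping; windows running
#'   past a chromosome end are clipped with a warning.
#' @return Interval tibble of recentered, stranded windows.
#' @export
recenter_on_motif <- function(regions, hits, motif_length, window = 250L,
                              chrom_sizes = NULL) {
  regions <- as_bed(regions)
  hits <- tibble::as_tibble(hits)
  if (anyDuplicated(hits$region)) stop("one hit per region expected")
  idx <- match(hits$region, regions$name)
  if (any(is.na(idx))) stop("hit for unknown region")
  center <- regions$start[idx] + hits$offset + motif_length %/% 2L
  out <- tibble::tibble(
    chrom = regions$chrom[idx],
    start = center - window,
    end = center + window + 1L,
    name = hits$region, score = hits$score, strand = hits$strand)
  clipped <- out$start < 0
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[out$chrom]
    clipped <- clipped | out$end > lim
    out$end <- pmin(out$end, lim)
  }
  out$start <- pmax(out$start, 0L)
  if (any(clipped)) {
    warning(sum(clipped), " recentered window(s) clipped at chromosome ",
            "bounds")
  }
  as_bed(out)
}

#' Area under the recovery curve
#'
#' Walking down a motif's genome-wide ranking of the region database, the
#' recovery at rank i is the fraction of the input set seen so far; the
#' AUC is the mean recovery over the top `rank_threshold` ranks,
#' normalized to `[0, 1]`.
#'
#' @param ranking Character vector: the full database in rank order.
#' @param input_set Character vector of region ids, a subset of the
#'   database.
#' @param rank_threshold Number of top ranks the AUC integrates over.
#' @return AUC in `[0, 1]`.
#' @export
recovery_auc <- function(ranking, input_set, rank_threshold = 10000L) {
  input_set <- unique(input_set)
  if (length(input_set) == 0) stop("input_set must be non-empty")
  if (!all(input_set %in% ranking)) {
    stop("input_set contains ids absent from the ranking")
  }
  rank_threshold <- min(rank_threshold, length(ranking))
  hit <- ranking[seq_len(rank_threshold)] %in% input_set
  recovery <- cumsum(hit) / length(input_set)
  mean(recovery)
}

#' Normalized enrichment scores from a collection of AUCs
#'
#' Z-scores each motif's AUC against the distribution over the whole motif
#' collection: `nes = (auc - mean(aucs)) / sd_pop(aucs)` with the
#' population (divide-by-n) standard deviation.
#'
#' @param aucs Named numeric vector of AUCs, one per motif (>= 3).
#' @return Named numeric vector of NES values.
#' @export
nes_scores <- function(aucs) {
  if (length(aucs) < 3) stop("need at least 3 motifs")
  mu <- mean(aucs)
  sdp <- sqrt(mean((aucs - mu)^2))
  if (sdp == 0) stop("zero variance across AUCs")
  (aucs - mu) / sdp
}

#' Build per-motif rankings of a region database
#'
#' Scores every database region with each motif's best hit (no threshold)
#' and orders the database by score, descending; ties are broken by region
#' id so rankings are deterministic.
#'
#' @param sequences Named sequences of the database regions.
#' @param pwms List of [pwm()] objects.
#' @return Named list of character vectors (one ranking per motif).
#' @export
build_rankings <- function(sequences, pwms) {
  seqs <- chr_seqs(sequences)
  ids <- names(seqs)
  if (is.null(ids)) stop("database sequences must be named")
  codes <- lapply(seqs, encode_dna)
  lapply(pwms, function(p) {
    score <- vapply(codes, best_score_code, numeric(1), lod = p$lod)
    ids[order(-score, ids)]
  })
}

#' Motif enrichment of a region set by recovery-curve AUC
#'
#' Ranks every motif by the NES of its recovery AUC for the input region
#' set over a genome-wide database ranking.  For each motif passing
#' `nes_cutoff`, candidate target regions are the input regions ranked
#' above the leading-edge rank `r*`, the rank maximizing the difference
#' between the motif's recovery and the mean recovery over all motifs at
#' that rank.  Input ids absent from the database can be mapped first by
#' >= 40% reciprocal overlap via [map_regions_to_database()].
#'
#' @param input_ids Character vector of database region ids (the input
#'   set).
#' @param rankings Named list from [build_rankings()].
#' @param rank_threshold AUC integration depth (default 10000, capped at
#'   the database size).
#' @param nes_cutoff Report motifs with NES above this (default 2.5).
#' @param tf_of Optional named character vector mapping motif id -> TF;
#'   when given, only the best-NES motif per TF is reported.
#' @return List with `table` (tibble `motif`, `auc`, `nes`, `rank`,
#'   `n_targets`, sorted by NES), `targets` (named list of candidate
#'   target ids per reported motif) and `rank_threshold`.
#' @export
enrich <- function(input_ids, rankings, rank_threshold = 10000L,
                   nes_cutoff = 2.5, tf_of = NULL) {
  input_ids <- unique(input_ids)
  db <- rankings[[1]]
  rank_threshold <- min(rank_threshold, length(db))
  aucs <- vapply(rankings, recovery_auc, numeric(1),
                 input_set = input_ids, rank_threshold = rank_threshold)
  nes <- nes_scores(aucs)
  # recovery matrix for the leading-edge rank
  rec <- vapply(rankings, function(r) {
    cumsum(r[seq_len(rank_threshold)] %in% input_ids) / length(input_ids)
  }, numeric(rank_threshold))
  mean_rec <- rowMeans(rec)
  tab <- tibble::tibble(motif = names(rankings), auc = unname(aucs),
                        nes = unname(nes))
  tab <- tab[order(-tab$nes, tab$motif), ]
  tab$rank <- seq_len(nrow(tab))
  if (!is.null(tf_of)) {
    tab$tf <- unname(tf_of[tab$motif])
    tab <- tab[!duplicated(tab$tf) | is.na(tab$tf), ]
  }
  reported <- tab$motif[tab$nes > nes_cutoff]
  targets <- list()
  n_targets <- integer(nrow(tab))
  for (m in reported) {
    gain <- rec[, m] - mean_rec
    rstar <- which.max(gain)
    lead <- rankings[[m]][seq_len(rstar)]
    targets[[m]] <- intersect(lead, input_ids)
  }
  tab$n_targets <- vapply(tab$motif, function(m)
    if (m %in% names(targets)) length(targets[[m]]) else NA_integer_,
    integer(1))
  list(table = tab, targets = targets, rank_threshold = rank_threshold)
}

#' Map input regions onto a database by reciprocal overlap
#'
#' Assigns each input interval the id of a database region overlapping it
#' reciprocally by at least `min_frac` of both lengths (best overlap wins).
#' Unmappable inputs are dropped and counted.
#'
#' @param input Interval tibble.
#' @param database Interval tibble with unique `name`s.
#' @param min_frac Reciprocal overlap fraction (default 0.4).
#' @return List with `ids` (mapped database ids) and `n_unmapped`.
#' @export
map_regions_to_database <- function(input, database, min_frac = 0.4) {
  input <- as_bed(input); database <- as_bed(database)
  ov <- bed_overlaps(input, database)
  if (nrow(ov) > 0) {
    la <- (input$end - input$start)[ov$a_idx]
    lb <- (database$end - database$start)[ov$b_idx]
    ok <- ov$overlap >= min_frac * la & ov$overlap >= min_frac * lb
    ov <- ov[ok, ]
  }
  if (nrow(ov) == 0) return(list(ids = character(), n_unmapped = nrow(input)))
  ov <- ov[order(ov$a_idx, -ov$overlap), ]
  ov <- ov[!duplicated(ov$a_idx), ]
  list(ids = unique(database$name[ov$b_idx]),
       n_unmapped = nrow(input) - length(unique(ov$a_idx)))
}
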