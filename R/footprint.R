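#' Motif-centered cut-site matrix
#'
#' Raw (unextended) cut-site counts around each motif-centered anchor: one
#' row per anchor, one column per relative position in `-half_window ..
#' +half_window`.  Minus-strand anchors are flipped so that matrix columns
#' always read in motif orientation.  Rows are sorted by total count,
#' descending.
#'
#' @param track A `cutsite_track`.
#' @param anchors Stranded interval tibble from [recenter_on_motif()];
#'   centers are interval midpoints.
#' @param half_window Window half-width (bp).
#' @return A `footprint_matrix`: list with `matrix` (anchors x positions,
#'   dimnames = anchor names / offsets), `half_window`.
#' @export
cut_matrix <- function(track, anchors, half_window = 250L) {
  stopifnot(inherits(track, "cutsite_track"))
  anchors <- as_bed(anchors)
  if (nrow(anchors) == 0) stop("anchors must be non-empty")
  w <- as.integer(half_window)
  centers <- (anchors$start + anchors$end) %/% 2L
  mat <- matrix(0L, nrow(anchors), 2L * w + 1L,
                dimnames = list(anchors$name,
                                as.character(seq(-w, w))))
  s <- track$sites
  base <- cut_bases(track)
  for (chr in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == chr)
    si <- which(s$chrom == chr)
    if (length(si) == 0) next
    b <- base[si]; cnt <- s$count[si]
    o <- order(b); b <- b[o]; cnt <- cnt[o]
    for (k in ai) {
      lo <- findInterval(centers[k] - w - 1L, b) + 1L
      hi <- findInterval(centers[k] + w, b)
      if (hi < lo) next
      off <- b[lo:hi] - centers[k]
      if (anchors$strand[k] == "-") off <- -off
      idx <- off + w + 1L
      tab <- tapply(cnt[lo:hi], idx, sum)
      mat[k, as.integer(names(tab))] <-
        mat[k, as.integer(names(tab))] + as.integer(tab)
    }
  }
  ord <- order(-rowSums(mat))
  structure(list(matrix = mat[ord, , drop = FALSE], half_window = w),
            class = "footprint_matrix")
}

#' Aggregate profile of a footprint matrix
#' @param fp A `footprint_matrix`.
#' @return Numeric vector (column sums), names = offsets.
#' @export
footprint_profile <- function(fp) {
  stopifnot(inherits(fp, "footprint_matrix"))
  colSums(fp$matrix)
}

#' Subtract a depth-matched background profile
#'
#' Scales the background profile to the total count of the signal profile,
#' then subtracts position-wise.  The background is built from the same
#' motif found in random regions, so shared sequence-driven cut bias
#' cancels and the bound-factor protection remains.
#'
#' @param signal,background Numeric profiles of equal length (same window).
#' @return Numeric corrected profile (may be negative).
#' @export
background_subtract <- function(signal, background) {
  if (length(signal) != length(background)) {
    stop("signal and background windows differ in size")
  }
  tb <- sum(background)
  if (tb == 0) stop("background profile has zero total count")
  signal - background * (sum(signal) / tb)
}

#' Footprint protection score
#'
#' Relative depletion of cut sites over the motif compared to its flanks:
#' `(mean flank - mean motif span) / mean flank`, where the flanks are the
#' 50 bp immediately outside the motif span on both sides.  A fully
#' protected motif scores 1, no protection scores 0, and enrichment over
#' the motif scores negative.
#'
#' @param profile Numeric profile whose names are offsets (as from
#'   [footprint_profile()]).
#' @param motif_span Integer vector of offsets covered by the motif,
#'   e.g. `-10:10`.
#' @param flank_bp Flank width on each side (default 50).
#' @return Single numeric score.
#' @export
protection_score <- function(profile, motif_span, flank_bp = 50L) {
  offs <- as.integer(names(profile))
  if (is.null(names(profile)) || any(is.na(offs))) {
    stop("profile must be named by integer offsets")
  }
  if (!all(motif_span %in% offs)) stop("motif_span outside the window")
  span_max <- max(abs(motif_span))
  flank <- offs[abs(offs) > span_max & abs(offs) <= span_max + flank_bp]
  if (length(flank) == 0) stop("no flank positions inside the window")
  mean_flank <- mean(profile[as.character(flank)])
  if (mean_flank == 0) stop("zero mean flank signal")
  mean_motif <- mean(profile[as.character(motif_span)])
  (mean_flank - mean_motif) / mean_flank
}

#' Draw motif-matched random background regions
#'
#' Samples regions of the same widths as the anchors uniformly from the
#' genome, excluding the anchor footprint, and keeps only draws containing
#' a PWM hit at least as strong as `threshold_bits` (rejection sampling,
#' capped at `max_tries` times the requested number).
#'
#' @param genome Named `DNAStringSet` (or character vector) of chromosome
#'   sequences.
#' @param anchors Interval tibble to match in number and width, and to
#'   exclude.
#' @param pwm A [pwm()] object.
#' @param threshold_bits Minimum best-hit score for acceptance.
#' @param seed Integer seed for reproducible draws.
#' @param max_tries Oversampling cap (default 50).
#' @return Interval tibble of accepted background regions (may be fewer
#'   than requested if the cap is hit, with a warning).
#' @export
random_background_regions <- function(genome, anchors, pwm,
                                      threshold_bits = 7, seed = 1L,
                                      max_tries = 50L) {
  seqs <- as.character(genome)
  anchors <- as_bed(anchors)
  n <- nrow(anchors)
  widths <- anchors$end - anchors$start
  chroms <- names(seqs)
  clen <- nchar(seqs)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- list(); got <- 0L; tries <- 0L
  while (got < n && tries < max_tries * n) {
    tries <- tries + 1L
    i <- ((got) %% n) + 1L   # cycle widths so each anchor width is matched
    w <- widths[i]
    ch <- sample(chroms, 1L, prob = clen / sum(clen))
    if (clen[[ch]] <= w) next
    st <- sample.int(clen[[ch]] - w, 1L) - 1L
    cand <- tibble::tibble(chrom = ch, start = st, end = st + w)
    if (nrow(bed_overlaps(cand, anchors)) > 0) next
    sq <- substr(seqs[[ch]], st + 1L, st + w)
    hit <- scan_best_hit(sq, pwm, threshold_bits)
    if (nrow(hit) == 0) next
    got <- got + 1L
    cand$name <- paste0("bg", got)
    cand$score <- hit$score
    cand$strand <- hit$strand
    out[[got]] <- cand
  }
  if (got < n) warning("only ", got, " of ", n,
                       " background regions found within the sampling cap")
  if (got == 0) return(as_bed(tibble::tibble(chrom = character(),
                                             start = integer(),
                                             end = integer())))
  as_bed(dplyr::bind_rows(out))
}
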