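#' Extract transposase/nuclease cut sites from aligned fragments
#'
#' ATAC-seq reads mark open chromatin at the base where the Tn5 transposase
#' inserted.  In `single_end` mode the cut site of each read is its 5' end:
#' the `start` coordinate for a `+` read and the `end` coordinate for a `-`
#' read (whose 5' base, in half-open convention, is `end - 1`).  In
#' `paired_end` mode both fragment ends are cut sites: `start` (recorded on
#' `+`) and `end` (recorded on `-`).
#'
#' No Tn5 +4/-5 offset correction is applied by default; set
#' `tn5_shift = TRUE` to shift `+` cuts by +4 bp and `-` cuts by -5 bp.
#'
#' @param fragments Interval tibble of reads or fragments (BED convention).
#' @param mode `"single_end"` or `"paired_end"`.
#' @param tn5_shift Apply the conventional Tn5 offset (default off).
#' @return A `cutsite_track`: a list with `sites` (tibble `chrom`, `pos`,
#'   `strand`, `count`, sorted) and `total_count`.  `pos` is the reported
#'   coordinate as above; the actual cut base is `pos` for `+` sites and
#'   `pos - 1` for `-` sites.
#' @export
extract_cutsites <- function(fragments, mode = c("single_end", "paired_end"),
                             tn5_shift = FALSE) {
  mode <- match.arg(mode)
  fragments <- as_bed(fragments)
  if (mode == "single_end") {
    if (any(!fragments$strand %in% c("+", "-"))) {
      bad <- which(!fragments$strand %in% c("+", "-"))[1]
      stop("single_end mode needs strand '+' or '-' (row ", bad, ")")
    }
    pos <- ifelse(fragments$strand == "+", fragments$start, fragments$end)
    strand <- fragments$strand
    chrom <- fragments$chrom
  } else {
    chrom <- rep(fragments$chrom, 2L)
    pos <- c(fragments$start, fragments$end)
    strand <- rep(c("+", "-"), each = nrow(fragments))
  }
  if (tn5_shift) pos <- pos + ifelse(strand == "+", 4L, -5L)
  sites <- dplyr::count(
    tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand),
    .data$chrom, .data$pos, .data$strand, name = "count"
  )
  sites <- dplyr::arrange(sites, .data$chrom, .data$pos, .data$strand)
  structure(list(sites = sites, total_count = sum(sites$count)),
            class = "cutsite_track")
}

#' @export
print.cutsite_track <- function(x, ...) {
  cat("<cutsite_track>", x$total_count, "cut sites on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

# Actual cut base of each site (half-open convention): pos for '+', pos-1
# for '-'.
cut_bases <- function(track) {
  s <- track$sites
  ifelse(s$strand == "-", s$pos - 1L, s$pos)
}

#' Per-base coverage of extended cut sites (bedGraph)
#'
#' Each cut site is extended by 5 bp on either side of the cut base, i.e. an
#' 11 bp half-open window `[base - 5, base + 6)` (for a `-` site recorded at
#' coordinate `pos = end`, the cut base is `pos - 1` and the window is
#' `[pos - 6, pos + 5)`).  Depth is multiplied by `scale`, typically the
#' reciprocal of the sample's size factor, so that tracks from libraries of
#' different depth are comparable.
#'
#' @param track A `cutsite_track`.
#' @param scale Positive multiplier applied to every depth value.
#' @return Tibble `chrom`, `start`, `end`, `value`: sorted, zero-depth runs
#'   omitted, adjacent runs with equal value merged.
#' @export
coverage_track <- function(track, scale = 1) {
  stopifnot(inherits(track, "cutsite_track"))
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop("scale must be a single positive number")
  }
  s <- track$sites
  base <- cut_bases(track)
  out <- lapply(split(seq_len(nrow(s)), s$chrom), function(idx) {
    lo <- pmax(base[idx] - 5L, 0L)
    hi <- base[idx] + 6L
    ev <- tibble::tibble(
      pos = c(lo, hi),
      d = c(s$count[idx], -s$count[idx])
    )
    ev <- dplyr::summarise(dplyr::group_by(ev, .data$pos),
                           d = sum(.data$d), .groups = "drop")
    ev <- dplyr::arrange(ev, .data$pos)
    depth <- cumsum(ev$d)
    n <- nrow(ev)
    runs <- tibble::tibble(
      chrom = s$chrom[idx[1]],
      start = ev$pos[-n], end = ev$pos[-1],
      value = depth[-n] * scale
    )
    # merge adjacent equal-value runs, drop zeros
    runs <- runs[runs$value != 0, , drop = FALSE]
    if (nrow(runs) > 1) {
      same <- c(FALSE, runs$value[-1] == runs$value[-nrow(runs)] &
                         runs$start[-1] == runs$end[-nrow(runs)])
      grp <- cumsum(!same)
      runs <- tibble::tibble(
        chrom = runs$chrom[1],
        start = as.vector(tapply(runs$start, grp, min)),
        end = as.vector(tapply(runs$end, grp, max)),
        value = as.vector(tapply(runs$value, grp, function(v) v[1])))
    }
    runs
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Aggregate cut-site signal around a set of anchors
#'
#' Sums cut-site counts at each offset relative to anchor centers
#' (midpoints; for stranded anchors such as TSSs the orientation of `-`
#' anchors is flipped before summing, so "downstream" is always to the
#' right).  This is the operation behind aggregate accessibility plots
#' around TSSs or motif centers.
#'
#' @param track A `cutsite_track`.
#' @param anchors Interval tibble; strand `-` flips orientation.
#' @param half_window Window half-width in bp.
#' @param normalize `"none"` or `"total_in_window"` (divide by the window
#'   sum so the profile sums to 1).
#' @return Numeric vector of length `2 * half_window + 1`, names are offsets.
#' @export
aggregate_profile <- function(track, anchors, half_window = 2500,
                              normalize = c("none", "total_in_window")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(track, "cutsite_track"))
  anchors <- as_bed(anchors)
  if (nrow(anchors) == 0) stop("anchors must be non-empty")
  centers <- (anchors$start + anchors$end) %/% 2L
  prof <- numeric(2L * half_window + 1L)
  s <- track$sites
  base <- cut_bases(track)
  for (chr in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == chr)
    si <- which(s$chrom == chr)
    if (length(si) == 0) next
    b <- base[si]; cnt <- s$count[si]
    o <- order(b); b <- b[o]; cnt <- cnt[o]
    for (k in ai) {
      c0 <- centers[k]
      lo <- findInterval(c0 - half_window - 1L, b) + 1L
      hi <- findInterval(c0 + half_window, b)
      if (hi < lo) next
      off <- b[lo:hi] - c0
      if (anchors$strand[k] == "-") off <- -off
      idx <- off + half_window + 1L
      prof[idx] <- prof[idx] + cnt[lo:hi]
    }
  }
  names(prof) <- as.character(seq(-half_window, half_window))
  if (normalize == "total_in_window") {
    tot <- sum(prof)
    if (tot == 0) stop("no signal within the window; cannot normalize")
    prof <- prof / tot
  }
  prof
}

#' Fragment-length histogram with nucleosome-periodic mode detection
#'
#' Computes the insert-size histogram of paired-end fragments and locates
#' its modes (local maxima of a moving-average-smoothed histogram).  In
#' chromatin data the modes fall near multiples of the nucleosome repeat:
#' a sub-nucleosomal peak plus mono-, di-, tri-nucleosome peaks.
#'
#' @param fragments Interval tibble of fragments; length is `end - start`.
#' @param smooth_window Moving-average window (odd, bp) applied before peak
#'   calling.
#' @param min_peak_frac Local maxima below this fraction of the tallest
#'   smoothed peak are discarded (guards against noise ripples).
#' @param max_length Fragments longer than this are discarded first.
#' @return List with `histogram` (tibble `length`, `count`), `n`, and
#'   `modes` (tibble `length`, `height` of each detected mode, increasing).
#' @export
fragment_length_histogram <- function(fragments, smooth_window = 31L,
                                      min_peak_frac = 0.05,
                                      max_length = 1500L) {
  fragments <- as_bed(fragments)
  len <- fragments$end - fragments$start
  len <- len[len <= max_length]
  if (length(len) == 0) stop("no fragments (after length filtering)")
  w <- as.integer(smooth_window)
  if (w %% 2L == 0L) w <- w + 1L
  # pad beyond the largest observed length so edge modes are not clipped
  tab <- tabulate(len, nbins = max(len) + w)
  hist <- tibble::tibble(length = seq_along(tab), count = tab)
  kern <- rep(1 / w, w)
  sm <- stats::filter(c(rep(0, w %/% 2), tab, rep(0, w %/% 2)), kern,
                      sides = 2)
  sm <- as.numeric(sm)[(w %/% 2 + 1):(w %/% 2 + length(tab))]
  # candidate maxima: no higher neighbor; plateaus collapse to their center
  half <- w %/% 2
  nL <- length(sm)
  left <- c(-Inf, sm[-nL]); right <- c(sm[-1], -Inf)
  cand <- which(sm > 0 & sm >= left & sm >= right)
  if (length(cand) > 1) {
    run <- cumsum(c(TRUE, !(diff(cand) == 1L &
                              sm[cand[-1]] == sm[cand[-length(cand)]])))
    cand <- vapply(split(cand, run),
                   function(p) as.integer(round(mean(p))), integer(1))
  }
  # keep only candidates that dominate their +/- half neighborhood
  peaks <- cand[vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(nL, i + half)
    sm[i] >= max(sm[lo:hi])
  }, logical(1))]
  if (length(peaks) > 0) {
    keep <- sm[peaks] >= min_peak_frac * max(sm[peaks])
    peaks <- peaks[keep]
    # collapse plateaus/neighbors closer than the window to one mode
    if (length(peaks) > 1) {
      grp <- cumsum(c(TRUE, diff(peaks) > half))
      peaks <- vapply(split(peaks, grp), function(p) {
        as.integer(round(mean(p[sm[p] == max(sm[p])])))
      }, integer(1))
    }
  }
  list(histogram = hist[hist$count > 0, ],
       n = length(len),
       modes = tibble::tibble(length = as.integer(peaks),
                              height = sm[peaks]))
}
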