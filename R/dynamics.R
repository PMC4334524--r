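#' Fisher's omnibus combination of p-values
#'
#' Combines k independent p-values into one via `X = -2 * sum(log(p))`,
#' which is chi-squared with 2k degrees of freedom under the global null.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return List with `statistic` (X) and `p` (combined p-value).
#' @export
fisher_omnibus <- function(pvalues) {
  if (length(pvalues) == 0) stop("need at least one p-value")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]; floor zero p-values upstream")
  }
  x <- -2 * sum(log(pvalues))
  list(statistic = x,
       p = stats::pchisq(x, df = 2 * length(pvalues), lower.tail = FALSE))
}

#' Classify region dynamics across a tumor time course
#'
#' Given two differential tables over the same regions — wild type vs early
#' tumor (`diff_we`) and early vs late tumor (`diff_el`) — labels each
#' region:
#' \describe{
#'   \item{stable}{opens early (`lfc_we > 1`) then plateaus
#'     (`-0.2 < lfc_el < 0.2`);}
#'   \item{gradual}{opens early (`lfc_we > 0`) and keeps opening
#'     (`lfc_el > 0.5`).}
#' }
#' All inequalities are strict, so boundary values fall to `none`; the two
#' classes are mutually exclusive because their `lfc_el` ranges are
#' disjoint.  If a third table comparing all wild type vs all tumor samples
#' is supplied, regions with `padj < global_padj` and `lfc > global_lfc`
#' there are additionally flagged `global_open`, and regions in no other
#' class take it as their class label.  Every region also receives the
#' Fisher's omnibus combination of its two p-values (floored at
#' `p_floor` first).
#'
#' @param diff_we,diff_el Differential tibbles from [differential_test()]
#'   (early-vs-WT and late-vs-early).
#' @param diff_global Optional all-tumor-vs-WT differential tibble.
#' @param thresholds Named list overriding any of `stable_lfc_we` (1),
#'   `stable_lfc_el` (0.2), `gradual_lfc_we` (0), `gradual_lfc_el` (0.5),
#'   `global_padj` (0.01), `global_lfc` (1).
#' @param omnibus_padj Optional cutoff on the omnibus p for the gradual
#'   class (default `NULL`, off).
#' @param p_floor Floor applied to p-values before the omnibus combination.
#' @return Tibble `region`, `lfc_we`, `lfc_el`, `p_we`, `p_el`,
#'   `omnibus_stat`, `omnibus_p`, `global_open` (logical), `class`.
#'   Regions missing from either table are dropped; their number is
#'   reported as attribute `n_dropped` (with a warning).
#' @export
classify_regions <- function(diff_we, diff_el, diff_global = NULL,
                             thresholds = list(), omnibus_padj = NULL,
                             p_floor = 1e-300) {
  th <- utils::modifyList(list(stable_lfc_we = 1, stable_lfc_el = 0.2,
                               gradual_lfc_we = 0, gradual_lfc_el = 0.5,
                               global_padj = 0.01, global_lfc = 1),
                          thresholds)
  we <- tibble::as_tibble(diff_we)[c("region", "log2fc", "p")]
  el <- tibble::as_tibble(diff_el)[c("region", "log2fc", "p")]
  names(we)[2:3] <- c("lfc_we", "p_we")
  names(el)[2:3] <- c("lfc_el", "p_el")
  n_in <- length(union(we$region, el$region))
  x <- dplyr::inner_join(we, el, by = "region")
  n_dropped <- n_in - nrow(x)
  if (n_dropped > 0) {
    warning(n_dropped, " region(s) missing from one table were dropped")
  }
  pw <- pmax(x$p_we, p_floor); pe <- pmax(x$p_el, p_floor)
  x$omnibus_stat <- -2 * (log(pw) + log(pe))
  x$omnibus_p <- stats::pchisq(x$omnibus_stat, df = 4, lower.tail = FALSE)
  stable <- x$lfc_we > th$stable_lfc_we &
    x$lfc_el > -th$stable_lfc_el & x$lfc_el < th$stable_lfc_el
  gradual <- x$lfc_we > th$gradual_lfc_we & x$lfc_el > th$gradual_lfc_el
  if (!is.null(omnibus_padj)) {
    gradual <- gradual & x$omnibus_p < omnibus_padj
  }
  x$global_open <- FALSE
  if (!is.null(diff_global)) {
    g <- tibble::as_tibble(diff_global)
    gsel <- g$region[!is.na(g$padj) & g$padj < th$global_padj &
                       g$log2fc > th$global_lfc]
    x$global_open <- x$region %in% gsel
  }
  x$class <- ifelse(stable, "stable",
                    ifelse(gradual, "gradual",
                           ifelse(x$global_open, "global_open", "none")))
  attr(x, "n_dropped") <- n_dropped
  x
}

#' Cluster differential peaks into unique candidate regions
#'
#' Single-linkage merge (>= 1 bp overlap) of differential peaks, typically
#' pooled from the ATAC and FAIRE calls, into unique candidate regulatory
#' regions.
#'
#' @param peaks Interval tibble or list of tibbles.
#' @return List with `regions` (merged interval tibble) and `n_clusters`.
#' @export
cluster_differential <- function(peaks) {
  m <- merge_intervals(peaks)
  list(regions = m, n_clusters = nrow(m))
}

#' Rank regions by signed p-value
#'
#' Scores each region `sign(log2fc) * -log10(p)` so strongly opening
#' regions rank first and strongly closing ones last, then returns the top
#' `top_n`.  Ties are broken by `|log2fc|` (descending), then region id.
#'
#' @param records Differential tibble with `region`, `log2fc`, `p`.
#' @param top_n Number of regions to return.
#' @param use_padj Rank on adjusted instead of raw p-values.
#' @return Tibble of the selected rows with a `signed_p` column, in rank
#'   order.
#' @export
rank_by_signed_p <- function(records, top_n = 250L, use_padj = FALSE) {
  x <- tibble::as_tibble(records)
  pcol <- if (use_padj) x$padj else x$p
  if (is.null(pcol)) stop("required p-value column is missing")
  x$signed_p <- sign(x$log2fc) * -log10(pmax(pcol, 1e-300))
  ord <- order(-x$signed_p, -abs(x$log2fc), x$region)
  x <- x[ord, ]
  if (top_n > nrow(x)) {
    warning("top_n exceeds number of records; returning all ", nrow(x))
    top_n <- nrow(x)
  }
  x[seq_len(top_n), ]
}
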