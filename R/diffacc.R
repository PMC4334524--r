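#' Count cut sites in non-overlapping regions
#'
#' Assigns each cut site to the region containing its cut base (half-open:
#' a site exactly at a region's `end` coordinate is outside).  Sites falling
#' in no region are dropped.  Regions must be non-overlapping (run
#' [merge_intervals()] first), otherwise assignment would be ambiguous and
#' an error is raised.
#'
#' @param track A `cutsite_track` from [extract_cutsites()].
#' @param regions Non-overlapping interval tibble with unique `name`s.
#' @return Named integer vector of counts, one per region (region order).
#' @export
count_in_regions <- function(track, regions) {
  stopifnot(inherits(track, "cutsite_track"))
  regions <- as_bed(regions)
  if (anyDuplicated(regions$name)) stop("region names must be unique")
  counts <- stats::setNames(integer(nrow(regions)), regions$name)
  s <- track$sites
  base <- cut_bases(track)
  for (chr in unique(regions$chrom)) {
    r <- regions[regions$chrom == chr, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)])) {
      stop("regions overlap on ", chr, "; merge them first")
    }
    si <- which(s$chrom == chr)
    if (length(si) == 0) next
    j <- findInterval(base[si], r$start)
    ok <- j > 0 & base[si] < r$end[pmax(j, 1L)]
    if (!any(ok)) next
    add <- tapply(s$count[si][ok], r$name[j[ok]], sum)
    counts[names(add)] <- counts[names(add)] + as.integer(add)
  }
  counts
}

#' Median-of-ratios size factors
#'
#' The per-sample scaling constants used throughout for normalization and
#' for scaling coverage tracks: each sample's factor is the median, over
#' regions with all-positive counts, of that sample's count divided by the
#' region's geometric mean across samples.
#'
#' @param counts Integer matrix, regions x samples.
#' @param pseudo_reference If no region has all-positive counts, setting
#'   this uses a pseudo-reference computed on `counts + 0.5` instead of
#'   failing.
#' @return Named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    if (!pseudo_reference) {
      stop("no region has all-positive counts; rerun with ",
           "pseudo_reference = TRUE")
    }
    lg <- log(counts + 0.5)
    geo <- exp(rowMeans(lg))
    ratios <- (counts + 0.5) / geo
    return(apply(ratios, 2, stats::median))
  }
  m <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  apply(m / geo, 2, stats::median)
}

# Method-of-moments dispersion from a fitted Poisson GLM: solves the
# moment equation sum((y - mu)^2 - mu) / mu^2 over residual df.
mom_dispersion <- function(y, mu, n_param) {
  df <- length(y) - n_param
  if (df <= 0) return(NA_real_)
  sum(((y - mu)^2 - mu) / mu^2) / df
}

#' Differential accessibility between two conditions
#'
#' Per-region negative binomial log-linear model
#' `log mu = log(size factor) + batch + condition`, fit by iteratively
#' reweighted least squares, with a Wald test on the condition coefficient.
#' The dispersion is a per-region method-of-moments estimate moderated by
#' shrinkage toward a mean-dispersion trend (`alpha ~ a0 + a1 / mean`),
#' with equal weight on the region estimate and the trend.  Because the
#' trend is estimated from all regions, the shrinkage adds information
#' beyond the per-region residual degrees of freedom; the Wald statistic
#' is therefore referred to a t distribution with moderated degrees of
#' freedom `df_residual + df_prior`, where
#' `df_prior = df_residual * (1 - shrink_weight) / shrink_weight`
#' (limma-style moderation; with the default equal weights the residual
#' df doubles).  P-values are Benjamini-Hochberg adjusted.  The batch
#' term is included whenever more than one batch (assay) is present among
#' the contrasted samples, so ATAC and FAIRE libraries can serve as
#' replicates of one another.
#'
#' @param counts Integer matrix, regions x samples.
#' @param design Tibble with `sample`, `condition`, `batch` rows matching
#'   columns of `counts`.
#' @param contrast Character vector `c(numerator, denominator)`: the
#'   reported `log2fc` is `contrast[1]` relative to `contrast[2]`.
#' @param sf Optional precomputed size factors; defaults to
#'   [size_factors()] on the contrasted columns.
#' @param shrink_weight Weight on the per-region dispersion estimate
#'   (remainder on the trend).
#' @return Tibble `region`, `base_mean`, `log2fc`, `p`, `padj`, `status`
#'   (`"ok"` or `"failed"`; failed fits report `p = 1`).
#' @export
differential_test <- function(counts, design, contrast, sf = NULL,
                              shrink_weight = 0.5) {
  counts <- as.matrix(counts)
  design <- tibble::as_tibble(design)
  stopifnot(length(contrast) == 2, all(c("sample", "condition", "batch")
                                       %in% names(design)))
  if (!all(contrast %in% design$condition)) {
    stop("contrast levels not all present in design")
  }
  design <- design[match(colnames(counts), design$sample), ]
  if (any(is.na(design$sample))) stop("design rows missing for some samples")
  use <- design$condition %in% contrast
  y <- counts[, use, drop = FALSE]
  d <- design[use, ]
  if (any(table(factor(d$condition, levels = contrast)) < 2)) {
    stop("need at least 2 samples per contrast level")
  }
  if (is.null(sf)) sf <- size_factors(y)
  off <- log(sf)
  cond <- as.integer(d$condition == contrast[1])   # numerator level
  use_batch <- length(unique(d$batch)) > 1
  X <- if (use_batch) {
    stats::model.matrix(~ factor(d$batch) + cond)
  } else {
    stats::model.matrix(~ cond)
  }
  n_param <- ncol(X)
  n_reg <- nrow(y)
  base_mean <- rowMeans(sweep(y, 2, sf, "/"))
  # stage 1: Poisson fits for the moment dispersion estimates
  alpha_mom <- rep(NA_real_, n_reg)
  mu_list <- vector("list", n_reg)
  for (i in seq_len(n_reg)) {
    if (all(y[i, ] == 0)) next
    fit <- suppressWarnings(try(stats::glm.fit(
      X, y[i, ], family = stats::poisson(), offset = off), silent = TRUE))
    if (inherits(fit, "try-error") || !fit$converged) next
    mu_list[[i]] <- fit$fitted.values
    alpha_mom[i] <- mom_dispersion(y[i, ], fit$fitted.values, n_param)
  }
  # dispersion trend: alpha ~ a0 + a1 / base_mean over usable regions
  ok <- is.finite(alpha_mom) & base_mean > 0
  alpha_trend <- rep(0.01, n_reg)
  if (sum(ok) >= 10) {
    tf <- stats::lm(pmax(alpha_mom[ok], 0) ~ I(1 / base_mean[ok]))
    alpha_trend <- pmax(cbind(1, 1 / pmax(base_mean, 1e-8)) %*%
                          stats::coef(tf), 1e-8)[, 1]
  }
  alpha <- shrink_weight * pmax(alpha_mom, 0) +
    (1 - shrink_weight) * alpha_trend
  alpha[!is.finite(alpha)] <- alpha_trend[!is.finite(alpha)]
  alpha <- pmax(alpha, 1e-8)
  cond_col <- n_param  # condition is the last model column
  df_resid <- max(ncol(y) - n_param, 1L)
  df_prior <- if (shrink_weight > 0) {
    df_resid * (1 - shrink_weight) / shrink_weight
  } else Inf
  df_mod <- df_resid + df_prior
  log2fc <- numeric(n_reg); pval <- rep(NA_real_, n_reg)
  status <- rep("ok", n_reg)
  for (i in seq_len(n_reg)) {
    if (all(y[i, ] == 0)) { status[i] <- "failed"; next }
    fam <- if (alpha[i] < 1e-6) stats::poisson() else
      MASS::negative.binomial(theta = 1 / alpha[i])
    yy <- y[i, ]
    fit <- suppressWarnings(try(stats::glm.fit(
      X, yy, family = fam, offset = off), silent = TRUE))
    sep <- !inherits(fit, "try-error") && min(fit$fitted.values) < 1e-3
    if (sep) {
      # complete separation (a group of all-zero counts): continuity-adjust
      yy <- y[i, ] + 0.5
      fit <- suppressWarnings(try(stats::glm.fit(
        X, yy, family = fam, offset = off), silent = TRUE))
    }
    if (inherits(fit, "try-error")) {
      status[i] <- "failed"; pval[i] <- 1; next
    }
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    cov <- try(solve(XtWX), silent = TRUE)
    if (inherits(cov, "try-error")) {
      status[i] <- "failed"; pval[i] <- 1; next
    }
    est <- fit$coefficients[cond_col]
    se <- sqrt(cov[cond_col, cond_col])
    log2fc[i] <- est / log(2)
    pval[i] <- 2 * stats::pt(-abs(est / se), df = df_mod)
  }
  padj <- rep(NA_real_, n_reg)
  has_p <- !is.na(pval)
  padj[has_p] <- stats::p.adjust(pval[has_p], method = "BH")
  tibble::tibble(region = rownames(y) %||% as.character(seq_len(n_reg)),
                 base_mean = base_mean, log2fc = log2fc, p = pval,
                 padj = padj, status = status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Squared correlation between two samples
#'
#' Pearson r-squared of `log1p` size-factor-normalized counts, the statistic
#' used to compare replicates within and across the ATAC and FAIRE assays.
#'
#' @param counts Integer matrix, regions x samples.
#' @param pair Two sample names (or column indices).
#' @param sf Optional size factors for all columns of `counts`.
#' @return Single numeric r-squared.
#' @export
sample_correlation <- function(counts, pair, sf = NULL) {
  counts <- as.matrix(counts)
  stopifnot(length(pair) == 2)
  if (is.null(sf)) sf <- size_factors(counts, pseudo_reference = TRUE)
  norm <- sweep(counts, 2, sf, "/")
  a <- log1p(norm[, pair[1]]); b <- log1p(norm[, pair[2]])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance sample in correlation")
  }
  stats::cor(a, b)^2
}
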