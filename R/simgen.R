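#' Configuration for the synthetic open-chromatin data generator
#'
#' Bundles and validates every knob of the simulator.  Defaults describe a
#' small but realistic two-condition accessibility experiment: negative
#' binomial region counts with a condition effect in a minority of regions,
#' a multiplicative assay (ATAC vs FAIRE) batch effect, >= 2-fold library
#' size variation, motif footprints that locally deplete transposase cut
#' sites, and a fragment-length mixture with sub-nucleosomal plus mono-,
#' di- and tri-nucleosome modes.
#'
#' @param seed Integer master seed; all generators derive from it, and an
#'   identical configuration reproduces byte-identical outputs.
#' @param n_chroms,chrom_length Number and length (bp) of simulated
#'   chromosomes.
#' @param n_regions Number of accessible regions, laid out on a regular grid
#'   with jitter.
#' @param region_width_mean Mean region width (bp).
#' @param n_samples_per_group Samples per condition; batches (ATAC/FAIRE)
#'   alternate within each condition so batch is never confounded with it.
#' @param dispersion Negative binomial dispersion (1/size); 0 degenerates to
#'   Poisson.
#' @param lfc_open True log2 fold change planted in "opening" regions
#'   (closing regions get its negative).
#' @param frac_open,frac_close Fractions of regions that open/close.
#' @param batch_lfc log2 offset applied to the FAIRE batch.
#' @param footprint_protection Fraction in `[0, 1]` by which the cut rate is
#'   reduced over motif instances (1 = complete protection).
#' @param fragment_modes Data frame `mean`, `sd`, `weight` describing the
#'   fragment-length mixture; weights must sum to 1.
#' @param gc Background GC content for simulated sequence.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 2e6,
                       n_regions = 500L,
                       region_width_mean = 500L,
                       n_samples_per_group = 3L,
                       dispersion = 0.1,
                       lfc_open = 2,
                       frac_open = 0.1,
                       frac_close = 0.1,
                       batch_lfc = 0.5,
                       footprint_protection = 0.5,
                       fragment_modes = data.frame(
                         mean = c(80, 200, 400, 600),
                         sd = c(20, 30, 40, 50),
                         weight = c(0.45, 0.30, 0.15, 0.10)),
                       gc = 0.5) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_regions = as.integer(n_regions),
              region_width_mean = as.integer(region_width_mean),
              n_samples_per_group = as.integer(n_samples_per_group),
              dispersion = dispersion, lfc_open = lfc_open,
              frac_open = frac_open, frac_close = frac_close,
              batch_lfc = batch_lfc,
              footprint_protection = footprint_protection,
              fragment_modes = fragment_modes, gc = gc)
  if (cfg$frac_open < 0 || cfg$frac_close < 0 ||
      cfg$frac_open + cfg$frac_close > 1) {
    stop("invalid proportions: need frac_open, frac_close >= 0 and ",
         "frac_open + frac_close <= 1")
  }
  if (cfg$region_width_mean <= 0 || cfg$chrom_length <= 0) {
    stop("widths and lengths must be positive")
  }
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$footprint_protection < 0 || cfg$footprint_protection > 1) {
    stop("footprint_protection must be in [0, 1]")
  }
  w <- cfg$fragment_modes$weight
  if (abs(sum(w) - 1) > 1e-6 || any(w < 0)) {
    stop("fragment_modes weights must be non-negative and sum to 1")
  }
  if (cfg$gc <= 0 || cfg$gc >= 1) stop("gc must be in (0, 1)")
  structure(cfg, class = "sim_config")
}

# Evaluate expr under a derived seed without disturbing the caller's RNG.
with_sim_seed <- function(cfg, offset, expr) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((cfg$seed + offset) %% .Machine$integer.max)
  force(expr)
}

# Regions on a jittered grid, clear of chromosome edges.
sim_regions <- function(cfg) {
  with_sim_seed(cfg, 0L, {
    n <- cfg$n_regions
    per_chrom <- ceiling(n / cfg$n_chroms)
    margin <- 2000L
    usable <- cfg$chrom_length - 2L * margin
    slot <- usable %/% per_chrom
    if (slot < cfg$region_width_mean + 10L) {
      stop("chromosomes too short to place ", n, " regions of width ~",
           cfg$region_width_mean)
    }
    rows <- list()
    id0 <- 0L
    for (ch in seq_len(cfg$n_chroms)) {
      k <- min(per_chrom, n - id0)
      if (k <= 0) break
      width <- pmax(50L, as.integer(round(stats::rnorm(
        k, cfg$region_width_mean, cfg$region_width_mean / 10))))
      width <- pmin(width, slot - 10L)
      jitter <- vapply(slot - width, function(m)
        sample.int(m, 1L) - 1L, integer(1))
      start <- margin + (seq_len(k) - 1L) * slot + jitter
      rows[[ch]] <- tibble::tibble(
        chrom = paste0("chr", ch),
        start = start, end = start + width,
        name = sprintf("r%05d", id0 + seq_len(k)),
        score = 0, strand = ".")
      id0 <- id0 + k
    }
    as_bed(dplyr::bind_rows(rows))
  })
}

#' Simulate a region-by-sample accessibility count matrix
#'
#' Counts follow a negative binomial model with per-region baselines drawn
#' log-normally, a planted condition effect (`+lfc_open` log2 units in
#' opening regions, `-lfc_open` in closing ones), a multiplicative batch
#' effect on the FAIRE samples, and deterministic per-sample depth factors
#' spanning more than 2-fold.
#'
#' @param config A [sim_config()].
#' @param conditions Two condition labels (reference first).
#' @return List with `counts` (integer matrix, regions x samples), `design`
#'   (tibble `sample`, `condition`, `batch`, `replicate`), `regions`
#'   (interval tibble) and `truth` (tibble `region`, `label`, `true_lfc`).
#' @export
simulate_counts <- function(config, conditions = c("WT", "TUM")) {
  stopifnot(inherits(config, "sim_config"), length(conditions) == 2)
  regions <- sim_regions(config)
  n <- nrow(regions)
  ns <- config$n_samples_per_group
  design <- tibble::tibble(
    sample = paste0(rep(conditions, each = ns), "_", rep(seq_len(ns), 2)),
    condition = rep(conditions, each = ns),
    batch = rep(rep(c("ATAC", "FAIRE"), length.out = ns), 2),
    replicate = as.character(rep(seq_len(ns), 2))
  )
  depth <- 2^seq(-0.55, 0.55, length.out = 2 * ns)
  with_sim_seed(config, 1L, {
    n_open <- round(config$frac_open * n)
    n_close <- round(config$frac_close * n)
    lab <- rep("null", n)
    pick <- sample.int(n, n_open + n_close)
    lab[pick[seq_len(n_open)]] <- "open"
    if (n_close > 0) lab[pick[n_open + seq_len(n_close)]] <- "close"
    true_lfc <- ifelse(lab == "open", config$lfc_open,
                       ifelse(lab == "close", -config$lfc_open, 0))
    base <- pmax(5, stats::rlnorm(n, meanlog = log(100), sdlog = 0.8))
    is_alt <- design$condition == conditions[2]
    is_faire <- design$batch == "FAIRE"
    mu <- outer(base, depth) *
      2^(outer(true_lfc, as.numeric(is_alt))) *
      2^(config$batch_lfc * matrix(is_faire, n, 2 * ns, byrow = TRUE))
    counts <- if (config$dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), n, 2 * ns)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / config$dispersion), n, 2 * ns)
    }
    storage.mode(counts) <- "integer"
    rownames(counts) <- regions$name
    colnames(counts) <- design$sample
    list(counts = counts, design = design, regions = regions,
         truth = tibble::tibble(region = regions$name, label = lab,
                                true_lfc = true_lfc, base_mean = base))
  })
}

#' Simulate cut-site fragments with motif footprints
#'
#' Cut sites are placed uniformly within the given (open) regions, except
#' over motif sites where the rate is multiplied by
#' `1 - footprint_protection` (thinning).  Each cut seeds a read/fragment
#' whose length is drawn from the configured mixture and whose strand is
#' assigned 50/50; the record's 5' end sits exactly on the cut base, and the
#' BED `name` column carries the fragment length.
#'
#' @param config A [sim_config()].
#' @param regions Interval tibble of accessible regions.
#' @param motif_sites Optional interval tibble of protected motif instances
#'   (must lie inside `regions`).
#' @param n_fragments Number of cut sites attempted before thinning.
#' @return Interval tibble of fragments (BED6; `name` = length).
#' @export
simulate_fragments <- function(config, regions, motif_sites = NULL,
                               n_fragments = 20000L) {
  stopifnot(inherits(config, "sim_config"))
  regions <- as_bed(regions)
  if (nrow(regions) == 0) stop("regions must be non-empty")
  if (!is.null(motif_sites) && nrow(motif_sites) > 0) {
    motif_sites <- as_bed(motif_sites)
    ov <- bed_overlaps(motif_sites, regions)
    inside <- ov$overlap == (motif_sites$end - motif_sites$start)[ov$a_idx]
    if (!all(seq_len(nrow(motif_sites)) %in% ov$a_idx[inside])) {
      stop("every motif site must lie inside a region")
    }
  }
  with_sim_seed(config, 2L, {
    w <- regions$end - regions$start
    ridx <- sample.int(nrow(regions), n_fragments, replace = TRUE,
                       prob = w / sum(w))
    pos <- regions$start[ridx] +
      floor(stats::runif(n_fragments) * w[ridx])
    keep <- rep(TRUE, n_fragments)
    if (!is.null(motif_sites) && nrow(motif_sites) > 0 &&
        config$footprint_protection > 0) {
      inmot <- rep(FALSE, n_fragments)
      for (chr in unique(motif_sites$chrom)) {
        mi <- motif_sites[motif_sites$chrom == chr, ]
        mi <- mi[order(mi$start), ]
        si <- which(regions$chrom[ridx] == chr)
        j <- findInterval(pos[si], mi$start)
        hit <- j > 0 & pos[si] < mi$end[pmax(j, 1L)]
        inmot[si[hit]] <- TRUE
      }
      drop <- inmot & stats::runif(n_fragments) < config$footprint_protection
      keep <- !drop
    }
    pos <- pos[keep]
    m <- config$fragment_modes
    comp <- sample.int(nrow(m), length(pos), replace = TRUE, prob = m$weight)
    len <- pmax(20L, as.integer(round(stats::rnorm(
      length(pos), m$mean[comp], m$sd[comp]))))
    strand <- sample(c("+", "-"), length(pos), replace = TRUE)
    start <- ifelse(strand == "+", pos, pos + 1L - len)
    start <- pmax(start, 0L)
    as_bed(tibble::tibble(
      chrom = regions$chrom[ridx][keep],
      start = as.integer(start),
      end = as.integer(start + len),
      name = as.character(len), score = 0, strand = strand))
  })
}

#' Simulate region sequences with planted motif instances
#'
#' Background bases are i.i.d. with the configured GC content; each
#' "bearing" region receives one motif instance sampled column-wise from the
#' PWM at a uniformly drawn, recorded offset.
#'
#' @param config A [sim_config()].
#' @param pwm A [pwm()] object.
#' @param bearing_ids Character vector of region names to receive an
#'   instance (may be empty).
#' @param regions Interval tibble (widths determine sequence lengths).
#' @return List with `sequences` (named `DNAStringSet`) and `truth`
#'   (tibble `region`, `offset` of planted instances; 0-based offsets).
#' @export
simulate_sequences <- function(config, pwm, bearing_ids, regions) {
  stopifnot(inherits(config, "sim_config"), inherits(pwm, "regland_pwm"))
  regions <- as_bed(regions)
  L <- nrow(pwm$matrix)
  widths <- regions$end - regions$start
  if (any(regions$name[widths < L] %in% bearing_ids)) {
    stop("motif longer than a bearing region")
  }
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
             (1 - config$gc) / 2)
  with_sim_seed(config, 3L, {
    seqs <- vapply(widths, function(w) {
      paste(sample(bases, w, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
    names(seqs) <- regions$name
    truth <- tibble::tibble(region = character(), offset = integer())
    for (id in intersect(bearing_ids, regions$name)) {
      w <- widths[match(id, regions$name)]
      off <- sample.int(w - L + 1L, 1L) - 1L
      inst <- paste(vapply(seq_len(L), function(i) {
        sample(bases, 1L, prob = pwm$matrix[i, ])
      }, character(1)), collapse = "")
      substr(seqs[id], off + 1L, off + L) <- inst
      truth <- dplyr::bind_rows(truth,
                                tibble::tibble(region = id, offset = off))
    }
    list(sequences = Biostrings::DNAStringSet(seqs), truth = truth)
  })
}

#' Simulate a motif-enrichment study with planted ground truth
#'
#' Builds everything the recovery-curve enrichment analysis needs,
#' offline: a fixed-width region database, a strong "planted" PWM, a
#' collection of decoy PWMs organized into families of correlated variants
#' (mirroring the redundancy of real motif collections, where most
#' transcription factors are represented by several near-identical
#' matrices), region sequences with the planted motif embedded in a known
#' subset of an input region set, and the truth.  Database regions share
#' one width so that no length-driven component is common to every
#' motif's ranking.
#'
#' @param config A [sim_config()]; the seed governs all draws.
#' @param n_input Size of the input region set (first `n_input` database
#'   regions).
#' @param n_bearing How many input regions carry the planted motif.
#' @param n_decoys Number of decoy PWMs (a multiple of `n_families`).
#' @param n_families Number of decoy families; each family's variants are
#'   Dirichlet draws concentrated around a common base matrix.
#' @param family_concentration Dirichlet concentration of variants around
#'   their family base (larger = more similar variants).
#' @param motif_length Planted motif length (bp).
#' @param region_width Database region width (bp).
#' @param consensus_prob Probability mass on the consensus base at each
#'   planted-motif position.
#' @return List: `regions`, `sequences`, `pwm` (planted, id `"M"`),
#'   `decoys` (named list), `pwms` (planted + decoys), `input_ids`,
#'   `bearing_ids`, `truth` (planted offsets).
#' @export
simulate_motif_study <- function(config, n_input = 100L, n_bearing = 80L,
                                 n_decoys = 20L, n_families = 5L,
                                 family_concentration = 400,
                                 motif_length = 10L,
                                 region_width = 500L,
                                 consensus_prob = 0.985) {
  stopifnot(inherits(config, "sim_config"), n_bearing <= n_input)
  regions <- sim_regions(config)
  regions$end <- regions$start + region_width
  stopifnot(n_input <= nrow(regions))
  planted <- with_sim_seed(config, 5L, {
    cons <- sample.int(4, motif_length, replace = TRUE)
    m <- matrix((1 - consensus_prob) / 3, motif_length, 4)
    m[cbind(seq_len(motif_length), cons)] <- consensus_prob
    pwm("M", m)
  })
  per_family <- n_decoys %/% n_families
  stopifnot(per_family * n_families == n_decoys)
  decoys <- with_sim_seed(config, 6L, {
    out <- list()
    for (f in seq_len(n_families)) {
      base <- matrix(stats::rgamma(4 * motif_length, shape = 1), ncol = 4)
      base <- base / rowSums(base)
      for (v in seq_len(per_family)) {
        m <- matrix(stats::rgamma(4 * motif_length,
                                  shape = family_concentration * base +
                                    1e-9), ncol = 4)
        id <- paste0("D", f, letters[v])
        out[[id]] <- pwm(id, m / rowSums(m))
      }
    }
    out
  })
  input_ids <- regions$name[seq_len(n_input)]
  bearing_ids <- input_ids[seq_len(n_bearing)]
  sq <- simulate_sequences(config, planted, bearing_ids, regions)
  list(regions = regions, sequences = sq$sequences, pwm = planted,
       decoys = decoys, pwms = c(list(M = planted), decoys),
       input_ids = input_ids, bearing_ids = bearing_ids,
       truth = sq$truth)
}

#' Simulate a toy gene annotation
#'
#' Tiles genes of fixed structure (three exons, two introns) along the
#' simulated chromosomes with alternating strand, for exercising
#' peak-to-gene assignment and genomic-location annotation.
#'
#' @param config A [sim_config()].
#' @param n_genes Number of genes.
#' @param gene_span Gene length (bp).
#' @return Gene models list as from [read_gene_models()].
#' @export
simulate_annotation <- function(config, n_genes = 40L, gene_span = 6000L) {
  stopifnot(inherits(config, "sim_config"))
  per_chrom <- ceiling(n_genes / config$n_chroms)
  slot <- (config$chrom_length - 4000L) %/% per_chrom
  if (slot < gene_span + 100L) stop("chromosomes too short for ", n_genes,
                                    " genes of span ", gene_span)
  rows <- list(); intr <- list(); id0 <- 0L
  for (ch in seq_len(config$n_chroms)) {
    k <- min(per_chrom, n_genes - id0)
    if (k <= 0) break
    start <- 2000L + (seq_len(k) - 1L) * slot
    gid <- sprintf("g%04d", id0 + seq_len(k))
    strand <- rep(c("+", "-"), length.out = k)
    rows[[ch]] <- tibble::tibble(
      gene_id = gid, chrom = paste0("chr", ch),
      start = start, end = start + gene_span, strand = strand,
      tss = ifelse(strand == "-", start + gene_span - 1L, start))
    # two introns at fixed relative positions
    e <- round(gene_span * c(0.15, 0.45, 0.60, 0.85))
    istart <- c(start + e[1], start + e[3])
    iend <- c(start + e[2], start + e[4])
    intr[[ch]] <- tibble::tibble(
      chrom = rep(paste0("chr", ch), 2L * k),
      start = istart, end = iend, name = rep(gid, 2))
    id0 <- id0 + k
  }
  list(genes = dplyr::bind_rows(rows),
       introns = as_bed(dplyr::bind_rows(intr)))
}

#' Simulate and write a complete dataset to a directory
#'
#' Materializes the full synthetic study: regions, fragments, genome
#' sequence, gene annotation, count matrix, sample design and the ground
#' truth, as the plain-text files the pipeline stages consume.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param n_fragments Fragments to simulate.
#' @return Invisibly, a character vector of the 7 file paths written.
#' @export
simulate_dataset <- function(config, dir, n_fragments = 20000L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_counts(config)
  frags <- simulate_fragments(config, sim$regions,
                              n_fragments = n_fragments)
  gene_span <- 6000L
  n_genes <- max(4L, min(40L, (config$n_chroms *
                                 (config$chrom_length - 4000L)) %/%
                           (2L * gene_span)))
  ann <- simulate_annotation(config, n_genes = n_genes,
                             gene_span = gene_span)
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
             (1 - config$gc) / 2)
  genome <- with_sim_seed(config, 4L, {
    g <- vapply(seq_len(config$n_chroms), function(i) {
      paste(sample(bases, config$chrom_length, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    names(g) <- paste0("chr", seq_len(config$n_chroms))
    Biostrings::DNAStringSet(g)
  })
  paths <- file.path(dir, c("regions.bed", "fragments.bed", "genome.fa",
                            "genes.gff3", "counts.tsv", "design.tsv",
                            "truth.json"))
  write_bed(sim$regions, paths[1])
  write_bed(frags, paths[2])
  Biostrings::writeXStringSet(genome, paths[3])
  write_gene_models(ann, paths[4])
  write_counts(sim$counts, paths[5])
  readr::write_tsv(sim$design, paths[6])
  jsonlite::write_json(list(truth = sim$truth, config = unclass(config)),
                       paths[7], digits = NA)
  invisible(paths)
}
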