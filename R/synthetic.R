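# Synthetic data generation: reference sequences, per-site methylation truth,
# event-aligned reads with state-dependent per-k-mer signal distributions,
# bisulfite tables, and mislabel injection. Every generator is a pure
# function of (config, seed).
#
# Signal model: each 5-mer sequence context carries a baseline current level
# drawn once from a seeded table; a methylated cytosine shifts the level of
# the bases within +/- `effect_width` of it by `delta`; per-signal Gaussian
# noise has standard deviation `sigma`; each read applies its own affine
# distortion (removed downstream by median/MAD normalization).

#' Synthetic dataset configuration
#'
#' @param genome_length Total reference length in bp.
#' @param n_contigs Number of contigs (length split evenly).
#' @param gc_fraction GC content of the reference (default 0.4, plant-like).
#' @param context_width Width of the sequence context determining the
#'   baseline signal level (default 5).
#' @param kmer_level_sd Spread of per-context baseline levels, in signal
#'   units (default 0.5): makes the current depend on sequence, not only on
#'   methylation state.
#' @param sigma Per-signal Gaussian noise standard deviation (default 0.25).
#' @param delta Current shift added near a methylated cytosine
#'   (default `3 * sigma`).
#' @param effect_width Methylation affects bases within this distance of the
#'   modified C (default 2).
#' @param signals_per_base_mean Mean of the (shifted) Poisson number of
#'   signals per base, minimum 1 (default 8, a typical dwell).
#' @param read_length Simulated read length in bp.
#' @param coverage Total read coverage across both strands (default 20).
#' @param freq_dist Named list per context of `c(p0, p1)`: the probability
#'   that a site is fully unmethylated / fully methylated; remaining mass is
#'   uniform on (0, 1).
#' @param bs_coverage Mean bisulfite coverage per site (Poisson).
#' @param conversion_error Bisulfite conversion failure rate: the chance an
#'   unmethylated cytosine reads as methylated (default 0.005).
#' @param mislabel_ratio Default mislabel injection ratio for
#'   [inject_mislabels()] experiments, in `[0, 0.2]`.
#' @param seed Integer master seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(genome_length = 10000L, n_contigs = 1L,
                             gc_fraction = 0.4, context_width = 5L,
                             kmer_level_sd = 0.5, sigma = 0.25,
                             delta = 3 * sigma, effect_width = 2L,
                             signals_per_base_mean = 8,
                             read_length = 1000L, coverage = 20,
                             freq_dist = list(CpG = c(p0 = 0.35, p1 = 0.45),
                                              CHG = c(p0 = 0.45, p1 = 0.35),
                                              CHH = c(p0 = 0.70, p1 = 0.10)),
                             bs_coverage = 30, conversion_error = 0.005,
                             mislabel_ratio = 0, seed = 1L) {
  if (sigma <= 0) stopf("sigma must be positive")
  if (delta < 0) stopf("delta must be >= 0")
  if (coverage < 1) stopf("coverage must be >= 1")
  if (mislabel_ratio < 0 || mislabel_ratio >= 1) stopf("mislabel_ratio must be in [0, 1)")
  for (ctx in CONTEXTS) {
    p <- freq_dist[[ctx]]
    if (is.null(p) || length(p) != 2L || sum(p) > 1 + 1e-9) {
      stopf("freq_dist$%s must be c(p0, p1) with p0 + p1 <= 1", ctx)
    }
  }
  structure(list(genome_length = as.integer(genome_length),
                 n_contigs = as.integer(n_contigs), gc_fraction = gc_fraction,
                 context_width = as.integer(context_width),
                 kmer_level_sd = kmer_level_sd, sigma = sigma, delta = delta,
                 effect_width = as.integer(effect_width),
                 signals_per_base_mean = signals_per_base_mean,
                 read_length = as.integer(read_length), coverage = coverage,
                 freq_dist = freq_dist, bs_coverage = bs_coverage,
                 conversion_error = conversion_error,
                 mislabel_ratio = mislabel_ratio, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a random reference genome
#'
#' @param cfg A [synthetic_config()].
#' @return Named character vector of contig sequences.
#' @export
generate_reference <- function(cfg) {
  set.seed(cfg$seed)
  per <- rep(cfg$genome_length %/% cfg$n_contigs, cfg$n_contigs)
  per[1] <- per[1] + cfg$genome_length %% cfg$n_contigs
  p <- c(A = (1 - cfg$gc_fraction) / 2, C = cfg$gc_fraction / 2,
         G = cfg$gc_fraction / 2, T = (1 - cfg$gc_fraction) / 2)
  seqs <- vapply(per, function(n) {
    paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  names(seqs) <- paste0("contig", seq_len(cfg$n_contigs))
  seqs
}

#' Generate per-site methylation truth and a read plan
#'
#' Each cytosine site (both strands) receives a true methylation frequency
#' from the per-context distribution; reads tile the genome at the
#' configured coverage on both strands; the methylation state of each site
#' in each read molecule is drawn Bernoulli(frequency).
#'
#' @param reference Named character vector from [generate_reference()].
#' @param cfg A [synthetic_config()].
#' @return List with `sites` (chrom, pos, strand, context, frequency),
#'   `reads` (read_id, chrom, strand, start, end) and `states`
#'   (read_id, chrom, pos, strand, state).
#' @export
generate_truth <- function(reference, cfg) {
  set.seed(cfg$seed + 1L)
  sites <- scan_cytosines(reference, k = 5L)[, c("chrom", "pos", "strand", "context")]
  freq <- numeric(nrow(sites))
  for (ctx in CONTEXTS) {
    sel <- sites$context == ctx
    n <- sum(sel)
    if (n == 0L) next
    p <- cfg$freq_dist[[ctx]]
    u <- stats::runif(n)
    f <- stats::runif(n)                 # intermediate frequencies
    f[u < p[1]] <- 0
    f[u >= p[1] & u < p[1] + p[2]] <- 1
    freq[sel] <- f
  }
  sites$frequency <- freq

  contig_len <- nchar(reference)
  n_reads_per_strand <- stats::setNames(
    pmax(1L, ceiling(cfg$coverage * contig_len /
                       (2 * pmin(cfg$read_length, contig_len)))),
    names(contig_len))
  reads <- do.call(rbind, lapply(names(reference), function(chrom) {
    L <- contig_len[[chrom]]
    rl <- min(cfg$read_length, L)
    nr <- n_reads_per_strand[[chrom]]
    do.call(rbind, lapply(c("+", "-"), function(strand) {
      start <- sample.int(L - rl + 1L, nr, replace = TRUE) - 1L
      data.frame(chrom = chrom, strand = strand, start = start,
                 end = start + rl, stringsAsFactors = FALSE)
    }))
  }))
  reads$read_id <- sprintf("read%05d", seq_len(nrow(reads)))
  reads <- reads[, c("read_id", "chrom", "strand", "start", "end")]

  states <- do.call(rbind, lapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    s <- sites[sites$chrom == r$chrom & sites$strand == r$strand &
                 sites$pos >= r$start & sites$pos < r$end, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    data.frame(read_id = r$read_id, chrom = s$chrom, pos = s$pos,
               strand = s$strand,
               state = stats::rbinom(nrow(s), 1L, s$frequency),
               stringsAsFactors = FALSE)
  }))
  list(sites = sites, reads = reads, states = states)
}

# Baseline current level per sequence context, drawn once from a seeded
# table indexed by the strand-oriented context k-mer.
kmer_level_table <- function(cfg) {
  w <- cfg$context_width
  kmers <- do.call(paste0, expand.grid(rep(list(BASES), w), stringsAsFactors = FALSE))
  set.seed(cfg$seed + 2L)
  stats::setNames(stats::rnorm(length(kmers), 0, cfg$kmer_level_sd), sort(kmers))
}

#' Generate event-aligned reads with state-dependent signals
#'
#' For every base of every planned read, the number of current samples is
#' drawn as 1 + Poisson(mean - 1) and their values as Normal(level, sigma),
#' where the level is the context baseline plus `delta` when a methylated
#' cytosine of the molecule lies within `effect_width` bases. Each read's
#' values then pass through a read-specific affine distortion.
#'
#' @param reference Named character vector of contig sequences.
#' @param truth Truth object from [generate_truth()].
#' @param cfg A [synthetic_config()].
#' @return List of raw (unnormalized) [event_read()] objects.
#' @export
generate_event_reads <- function(reference, truth, cfg) {
  set.seed(cfg$seed + 3L)
  levels <- kmer_level_table(cfg)
  w2 <- cfg$context_width %/% 2L
  lam <- max(cfg$signals_per_base_mean - 1, 0)
  st <- truth$states
  st_by_read <- split(seq_len(nrow(st)), st$read_id)
  lapply(seq_len(nrow(truth$reads)), function(i) {
    r <- truth$reads[i, ]
    contig <- reference[[r$chrom]]
    L <- nchar(contig)
    n <- r$end - r$start
    pos <- r$start:(r$end - 1L)                       # 0-based
    # context k-mer per base, strand-oriented; contig edges padded with A
    lo <- pmax(pos - w2 + 1L, 1L)
    hi <- pmin(pos + w2 + 1L, L)
    ctx <- substring(contig, lo, hi)
    pad_l <- strrep("A", pmax(0L, w2 - pos))
    pad_r <- strrep("A", pmax(0L, pos + w2 - (L - 1L)))
    ctx <- paste0(pad_l, ctx, pad_r)
    if (r$strand == "-") ctx <- revcomp(ctx)
    level <- as.numeric(levels[ctx])
    level[is.na(level)] <- 0
    # methylation shift near methylated cytosines of this molecule
    rows <- st_by_read[[r$read_id]]
    if (!is.null(rows)) {
      mpos <- st$pos[rows][st$state[rows] == 1L]
      if (length(mpos) > 0L) {
        hit <- unique(unlist(lapply(mpos, function(q) {
          (q - cfg$effect_width):(q + cfg$effect_width)
        })))
        level[pos %in% hit] <- level[pos %in% hit] + cfg$delta
      }
    }
    counts <- 1L + stats::rpois(n, lam)
    a <- stats::runif(1, 0.9, 1.1)
    b <- stats::rnorm(1, 0, 1)
    signals <- lapply(seq_len(n), function(j) {
      a * stats::rnorm(counts[j], level[j], cfg$sigma) + b
    })
    event_read(r$read_id, r$chrom, r$strand, r$start,
               substr(contig, r$start + 1L, r$end), signals)
  })
}

#' Generate a bisulfite report from the truth
#'
#' Coverage is Poisson(`bs_coverage`); the methylated count is binomial with
#' probability `frequency + (1 - frequency) * conversion_error` (conversion
#' failures read as methylated). Zero-coverage sites are emitted.
#'
#' @param truth Truth object from [generate_truth()].
#' @param reference Named character vector of contig sequences (for the
#'   trinucleotide column).
#' @param cfg A [synthetic_config()].
#' @return data.frame in bisulfite-report form (see
#'   [read_bisulfite_report()]).
#' @export
generate_bisulfite_table <- function(truth, reference, cfg) {
  set.seed(cfg$seed + 4L)
  s <- truth$sites
  cov <- stats::rpois(nrow(s), cfg$bs_coverage)
  p_obs <- s$frequency + (1 - s$frequency) * cfg$conversion_error
  n_meth <- stats::rbinom(nrow(s), cov, p_obs)
  tri <- vapply(seq_len(nrow(s)), function(i) {
    contig <- reference[[s$chrom[i]]]
    L <- nchar(contig)
    if (s$strand[i] == "+") {
      hi <- min(s$pos[i] + 3L, L)
      t0 <- substr(contig, s$pos[i] + 1L, hi)
      paste0(t0, strrep("N", 3L - nchar(t0)))
    } else {
      lo <- max(s$pos[i] - 1L, 1L)
      t0 <- revcomp(substr(contig, lo, s$pos[i] + 1L))
      paste0(t0, strrep("N", 3L - nchar(t0)))
    }
  }, character(1))
  data.frame(chrom = s$chrom, pos = s$pos, strand = s$strand,
             count_methylated = n_meth, count_unmethylated = cov - n_meth,
             context = s$context, trinucleotide = tri, stringsAsFactors = FALSE)
}

#' Inject false-positive mislabels into a labelled sample set
#'
#' Replaces a fraction `ratio` of the positive samples by truly-unmethylated
#' samples (drawn from the negatives, copied and relabelled positive). The
#' returned injected ids identify the corrupted samples for recovery
#' scoring; they are disjoint from the genuine positives, and the mislabel
#' ratio (injected / total positives) equals `ratio` up to rounding.
#'
#' @param samples Labelled `site_samples`.
#' @param ratio Fraction of positives to replace, in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `samples` (corrupted set) and `injected_ids`
#'   (character vector of injected sample ids).
#' @export
inject_mislabels <- function(samples, ratio, seed = 1L) {
  if (ratio < 0 || ratio >= 1) stopf("ratio must be in [0, 1)")
  if (ratio == 0) return(list(samples = samples, injected_ids = character()))
  set.seed(seed)
  pos_idx <- which(samples$info$label == 1L)
  neg_idx <- which(samples$info$label == 0L)
  n_inj <- round(ratio * length(pos_idx))
  if (n_inj == 0L) return(list(samples = samples, injected_ids = character()))
  if (n_inj > length(neg_idx)) stopf("not enough negatives to inject %d mislabels", n_inj)
  drop_pos <- sample(pos_idx, n_inj)
  src_neg <- sample(neg_idx, n_inj)
  injected <- subset_samples(samples, src_neg)
  injected$info$label <- 1L
  injected$info$sample_id <- paste0(injected$info$sample_id, "#inj", seq_len(n_inj))
  keep <- setdiff(seq_len(n_samples(samples)), drop_pos)
  out <- bind_samples(subset_samples(samples, keep), injected)
  list(samples = out, injected_ids = injected$info$sample_id)
}

#' Simulate a complete fixture dataset on disk
#'
#' Writes the reference FASTA, raw event-aligned reads (JSON-lines), the
#' bisulfite report TSV, and the truth tables (sites, reads, states) as TSVs
#' into a directory.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reference <- generate_reference(cfg)
  truth <- generate_truth(reference, cfg)
  reads <- generate_event_reads(reference, truth, cfg)
  bs <- generate_bisulfite_table(truth, reference, cfg)
  paths <- list(
    reference = file.path(dir, "reference.fa"),
    events = file.path(dir, "events.jsonl"),
    bisulfite = file.path(dir, "bisulfite.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_reads = file.path(dir, "truth_reads.tsv"),
    truth_states = file.path(dir, "truth_states.tsv"))
  write_fasta(reference, paths$reference)
  write_event_reads(reads, paths$events)
  write_bisulfite_report(bs, paths$bisulfite)
  data.table::fwrite(truth$sites, paths$truth_sites, sep = "\t")
  data.table::fwrite(truth$reads, paths$truth_reads, sep = "\t")
  data.table::fwrite(truth$states, paths$truth_states, sep = "\t")
  invisible(paths)
}
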