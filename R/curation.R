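# Training-set curation: high-confidence site selection from bisulfite
# reports, k-mer-aware balancing of negative samples, iterative
# cross-prediction denoising of mislabelled positives, and subsampling.

#' Curation configuration
#'
#' @param min_coverage Minimum bisulfite read coverage for a high-confidence
#'   site (default 5).
#' @param meth_freq_min Minimum methylation frequency of a high-confidence
#'   methylated site (default 0.9).
#' @param unmeth_freq_max Maximum frequency of a high-confidence unmethylated
#'   site (default 0: fully unmethylated).
#' @param replicate_rule Named list giving, per context, how high-confidence
#'   methylated sites are combined across bisulfite replicates:
#'   `"intersection"` (CpG) or `"union"` (CHG, CHH).
#' @param max_samples Cap on the training-set size for
#'   [subsample_training_set()] (default 2e7, half positive / half negative).
#' @param iterations,rounds,epochs Denoising loop controls (defaults
#'   I = 10, R = 3, E = 3).
#' @param retention_stop Stop denoising once the fraction of positives
#'   retained in an iteration reaches this value (default 0.99).
#' @return Object of class `curation_config`.
#' @export
curation_config <- function(min_coverage = 5L, meth_freq_min = 0.9,
                            unmeth_freq_max = 0,
                            replicate_rule = list(CpG = "intersection",
                                                  CHG = "union", CHH = "union"),
                            max_samples = 2e7, iterations = 10L, rounds = 3L,
                            epochs = 3L, retention_stop = 0.99) {
  if (!(unmeth_freq_max >= 0 && unmeth_freq_max < meth_freq_min && meth_freq_min <= 1)) {
    stopf("need 0 <= unmeth_freq_max < meth_freq_min <= 1")
  }
  if (iterations < 1L || rounds < 1L || epochs < 1L) stopf("iterations, rounds, epochs must be >= 1")
  structure(list(min_coverage = as.integer(min_coverage),
                 meth_freq_min = meth_freq_min, unmeth_freq_max = unmeth_freq_max,
                 replicate_rule = replicate_rule, max_samples = max_samples,
                 iterations = as.integer(iterations), rounds = as.integer(rounds),
                 epochs = as.integer(epochs), retention_stop = retention_stop),
            class = "curation_config")
}

#' Select high-confidence training sites from bisulfite replicates
#'
#' A site is high-confidence methylated when its coverage is at least
#' `min_coverage` and its frequency at least `meth_freq_min`; methylated sets
#' are combined across replicates by intersection (CpG) or union (CHG/CHH).
#' A site is high-confidence unmethylated when, in every replicate, it has
#' coverage at least `min_coverage` and frequency at most `unmeth_freq_max`
#' (zero by default). The two sets are disjoint.
#'
#' @param reports A bisulfite report data.frame (see
#'   [read_bisulfite_report()]) or a list of them, one per replicate.
#' @param context `"CpG"`, `"CHG"` or `"CHH"`.
#' @param cfg A [curation_config()].
#' @return List with data.frames `methylated` and `unmethylated`, each with
#'   columns `chrom`, `pos`, `strand`.
#' @export
select_high_confidence_sites <- function(reports, context, cfg = curation_config()) {
  if (is.data.frame(reports)) reports <- list(reports)
  if (!context %in% CONTEXTS) stopf("unknown context '%s'", context)
  rule <- cfg$replicate_rule[[context]] %||% "union"
  per_rep <- lapply(reports, function(rep) {
    rep <- rep[rep$context == context, , drop = FALSE]
    cov <- rep$count_methylated + rep$count_unmethylated
    freq <- ifelse(cov > 0, rep$count_methylated / cov, NA_real_)
    keys <- site_key(rep$chrom, rep$pos, rep$strand)
    list(meth = keys[which(cov >= cfg$min_coverage & freq >= cfg$meth_freq_min)],
         unmeth = keys[which(cov >= cfg$min_coverage & freq <= cfg$unmeth_freq_max)])
  })
  meth_sets <- lapply(per_rep, `[[`, "meth")
  meth <- if (rule == "intersection") Reduce(intersect, meth_sets) else Reduce(union, meth_sets)
  unmeth <- Reduce(intersect, lapply(per_rep, `[[`, "unmeth"))
  unmeth <- setdiff(unmeth, meth)
  list(methylated = keys_to_sites(meth), unmethylated = keys_to_sites(unmeth))
}

keys_to_sites <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[[`, character(1), 1),
             pos = as.integer(vapply(parts, `[[`, character(1), 2)),
             strand = vapply(parts, `[[`, character(1), 3),
             stringsAsFactors = FALSE)
}

#' Label samples as positive/negative from high-confidence site sets
#'
#' Every read-level sample at a high-confidence methylated site is labelled 1
#' and at a high-confidence unmethylated site 0; samples at other sites are
#' dropped.
#'
#' @param samples A `site_samples` object.
#' @param hc List from [select_high_confidence_sites()] (or several such
#'   lists, one per context, combined by the caller).
#' @return Labelled `site_samples` restricted to high-confidence sites.
#' @export
label_from_high_confidence <- function(samples, hc) {
  keys <- site_key(samples$info$chrom, samples$info$pos, samples$info$strand)
  mk <- site_key(hc$methylated$chrom, hc$methylated$pos, hc$methylated$strand)
  uk <- site_key(hc$unmethylated$chrom, hc$unmethylated$pos, hc$unmethylated$strand)
  lab <- rep(NA_integer_, length(keys))
  lab[keys %in% mk] <- 1L
  lab[keys %in% uk] <- 0L
  out <- subset_samples(samples, !is.na(lab))
  out$info$label <- lab[!is.na(lab)]
  out
}

# Core of the balancing step: indices into `kmer_neg` such that, per k-mer
# shared with the positives, at most as many negatives as positives are kept,
# with any deficit filled from k-mers private to the negative set.
balance_negative_indices <- function(kmer_pos, kmer_neg) {
  if (length(kmer_pos) == 0L || length(kmer_neg) == 0L) return(integer())
  knum_pos <- table(kmer_pos)
  neg_by_kmer <- split(seq_along(kmer_neg), kmer_neg)
  k_comm <- intersect(names(neg_by_kmer), names(knum_pos))
  picked <- integer()
  for (km in k_comm) {
    avail <- neg_by_kmer[[km]]
    take <- min(knum_pos[[km]], length(avail))
    picked <- c(picked, if (length(avail) == 1L) avail else sample(avail, take))
  }
  deficit <- length(kmer_pos) - length(picked)
  if (deficit > 0L) {
    pool <- unlist(neg_by_kmer[setdiff(names(neg_by_kmer), k_comm)], use.names = FALSE)
    if (length(pool) > 0L) {
      take <- min(deficit, length(pool))
      picked <- c(picked, if (length(pool) == 1L) pool else sample(pool, take))
    }
  }
  sort(picked)
}

#' Balance negative samples against the k-mer spectrum of the positives
#'
#' For every k-mer shared by the positive and negative sets, at most as many
#' negatives as there are positives of that k-mer are kept (drawn at random);
#' if the kept set is still smaller than the positive set, the deficit is
#' filled at random from negatives whose k-mers do not occur among the
#' positives. The output never exceeds the positive set in size unless the
#' negative pool is exhausted first.
#'
#' @param pos,neg Labelled `site_samples` sets (positives / negative pool).
#' @param seed Integer seed.
#' @return `site_samples`: the balanced negative subset.
#' @export
balance_negative_samples <- function(pos, neg, seed = 1L) {
  set.seed(seed)
  idx <- balance_negative_indices(pos$info$kmer, neg$info$kmer)
  subset_samples(neg, idx)
}

#' Trainer contract for denoising
#'
#' Returns a closure `function(train, score, seed)` that builds a fresh
#' model from `cfg` (reseeded with `seed`), trains it for `epochs` epochs
#' without early stopping or validation, and returns the methylation
#' probability of every sample in `score`. The published procedure uses the
#' signal-features-only model variant for denoising.
#'
#' @param cfg A [model_config()] (typically `mode = "signal_only"`).
#' @param epochs Training epochs per fold (E; default 3).
#' @return A trainer closure for [denoise_samples()].
#' @export
make_denoise_trainer <- function(cfg, epochs = 3L) {
  force(cfg); force(epochs)
  function(train, score, seed) {
    cfg$seed <- as.integer(seed)
    cfg$early_stopping <- FALSE
    model <- build_model(cfg)
    model <- train_model(model, train, valid_samples = NULL, epochs = epochs)
    predict(model, score)$p_methylated
  }
}

#' Iteratively denoise a labelled training set
#'
#' Runs up to `iterations` iterations; in each, `rounds` rounds of two-fold
#' cross-prediction are performed: the current sample set is split at random
#' into two halves, a fresh model is trained on each half and scores the
#' other, and each sample's methylation probabilities are accumulated across
#' rounds. Positives whose mean score falls below 0.5 are removed, the
#' negatives are rebalanced against the remaining positives by
#' [balance_negative_samples()] drawing from the original negative pool, and
#' the loop stops early once the fraction of positives retained in an
#' iteration reaches `retention_stop`.
#'
#' @param samples Labelled `site_samples` (positives and negatives).
#' @param trainer A trainer closure, e.g. from [make_denoise_trainer()].
#' @param iterations Maximum iterations I (default 10).
#' @param rounds Cross-prediction rounds R per iteration (default 3).
#' @param retention_stop Early-stop retention fraction (default 0.99).
#' @param seed Integer seed controlling splits and per-fold model seeds.
#' @param verbose Print per-iteration retention to stderr.
#' @return List with `samples` (the denoised set), `removed_ids` (sample ids
#'   of all removed positives) and `history` (per-iteration data.frame with
#'   positive counts and retained fraction).
#' @export
denoise_samples <- function(samples, trainer, iterations = 10L, rounds = 3L,
                            retention_stop = 0.99, seed = 1L, verbose = FALSE) {
  if (anyNA(samples$info$label)) stopf("denoising requires fully labelled samples")
  if (!any(samples$info$label == 1L) || !any(samples$info$label == 0L)) {
    stopf("denoising requires both positive and negative samples")
  }
  set.seed(seed)
  fold_seeds <- matrix(sample.int(.Machine$integer.max - 1L, iterations * rounds * 2L),
                       nrow = iterations)
  neg_pool <- subset_samples(samples, samples$info$label == 0L)
  S <- samples
  removed_ids <- character()
  hist <- data.frame(iteration = integer(), n_pos_before = integer(),
                     n_pos_after = integer(), retained = numeric(), n_neg = integer())
  for (i in seq_len(iterations)) {
    n <- n_samples(S)
    scores <- matrix(NA_real_, n, rounds)
    for (r in seq_len(rounds)) {
      perm <- sample.int(n)
      h <- n %/% 2L
      idx1 <- perm[seq_len(h)]
      idx2 <- perm[(h + 1L):n]
      s1 <- subset_samples(S, idx1)
      s2 <- subset_samples(S, idx2)
      scores[idx2, r] <- trainer(s1, s2, fold_seeds[i, 2L * r - 1L])
      scores[idx1, r] <- trainer(s2, s1, fold_seeds[i, 2L * r])
    }
    mean_score <- rowMeans(scores)
    pos_idx <- which(S$info$label == 1L)
    p_total <- length(pos_idx)
    if (p_total == 0L) break
    keep <- pos_idx[mean_score[pos_idx] >= 0.5]
    dropped <- setdiff(pos_idx, keep)
    removed_ids <- c(removed_ids, S$info$sample_id[dropped])
    s_pos <- subset_samples(S, keep)
    s_neg <- balance_negative_samples(s_pos, neg_pool,
                                      seed = fold_seeds[i, 1L] %% 1000000L + i)
    S <- bind_samples(s_pos, s_neg)
    retained <- length(keep) / p_total
    hist <- rbind(hist, data.frame(iteration = i, n_pos_before = p_total,
                                   n_pos_after = length(keep), retained = retained,
                                   n_neg = n_samples(s_neg)))
    if (verbose) {
      message(sprintf("denoise iteration %d: retained %d/%d positives (%.3f)",
                      i, length(keep), p_total, retained))
    }
    if (retained >= retention_stop) break
  }
  list(samples = S, removed_ids = removed_ids, history = hist)
}

#' Subsample a class-balanced training set
#'
#' Draws at most `max_samples` samples, half positive and half negative where
#' availability allows; when one class is exhausted the other is still capped
#' at `max_samples / 2`, preserving class balance.
#'
#' @param pos,neg `site_samples` sets of positives / negatives.
#' @param max_samples Total cap (default 2e7).
#' @param seed Integer seed.
#' @return A `site_samples` object with the retained positives followed by
#'   the retained negatives.
#' @export
subsample_training_set <- function(pos, neg, max_samples = 2e7, seed = 1L) {
  set.seed(seed)
  half <- floor(max_samples / 2)
  np <- min(n_samples(pos), half)
  nn <- min(n_samples(neg), half)
  bind_samples(subset_samples(pos, sort(sample.int(n_samples(pos), np))),
               subset_samples(neg, sort(sample.int(n_samples(neg), nn))))
}
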