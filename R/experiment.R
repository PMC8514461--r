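# Packaged denoising-recovery experiment: builds a separable two-class
# training set from the synthetic generator, injects a known fraction of
# false-positive mislabels, runs the iterative cross-prediction denoiser,
# and scores how many injected mislabels were removed.

#' Drop negatives contaminated by a methylated neighbor
#'
#' In simulated molecules the methylation signal shift extends
#' `effect_width` bases around each methylated cytosine, so an unmethylated
#' site whose close neighbor is methylated on the same molecule carries a
#' methylation-like signal. For experiments that require a separable
#' two-class sample set, such negatives are excluded.
#'
#' @param samples Labelled `site_samples`.
#' @param truth Truth object from [generate_truth()].
#' @param effect_width Neighborhood half-width in bp (match the generator's).
#' @return The filtered `site_samples`.
#' @export
filter_separable_samples <- function(samples, truth, effect_width = 2L) {
  st <- truth$states
  meth_keys <- paste(st$read_id, st$chrom, st$pos, st$strand, sep = ":")[st$state == 1L]
  info <- samples$info
  neg <- which(info$label == 0L)
  if (length(neg) == 0L) return(samples)
  contaminated <- rep(FALSE, length(neg))
  for (d in seq(-effect_width, effect_width)) {
    if (d == 0L) next
    keys <- paste(info$read_id[neg], info$chrom[neg], info$pos[neg] + d,
                  info$strand[neg], sep = ":")
    contaminated <- contaminated | keys %in% meth_keys
  }
  drop <- neg[contaminated]
  keep <- setdiff(seq_len(n_samples(samples)), drop)
  subset_samples(samples, keep)
}

#' Denoising-recovery experiment on synthetic data
#'
#' Generates a separable synthetic training set (two-class per-base Gaussian
#' signals with mean separation `delta = 3 * sigma`; per-site methylation
#' frequencies restricted to 0 or 1; neighbor-contaminated negatives
#' excluded), balances negatives against the positive k-mer spectrum,
#' relabels a known fraction of clean negatives as methylated, runs
#' [denoise_samples()] with the signal-features-only model, and reports the
#' fraction of injected mislabels removed.
#'
#' @param mislabel_ratio Fraction of positives replaced by mislabelled
#'   negatives (0-0.2 range).
#' @param seed Integer master seed.
#' @param genome_length,coverage Generator scale controls; the defaults
#'   yield > 20,000 training samples.
#' @param rounds Cross-prediction rounds per iteration (R, default 3).
#' @param epochs Training epochs per fold (E, default 2).
#' @param iterations Maximum denoising iterations (I, default 10).
#' @param hidden Hidden width of the signal-only trainer model.
#' @param verbose Print per-iteration retention.
#' @return List with `recovery` (fraction of injected mislabels removed),
#'   `n_injected`, `n_samples`, and the denoiser `history`.
#' @export
denoise_experiment <- function(mislabel_ratio, seed = 1L,
                               genome_length = 4600L, coverage = 30,
                               rounds = 3L, epochs = 2L, iterations = 10L,
                               hidden = 32L, verbose = FALSE) {
  cfg <- synthetic_config(
    genome_length = genome_length, coverage = coverage,
    kmer_level_sd = 0,  # two-class per-base Gaussians, separation delta = 3 sigma
    freq_dist = list(CpG = c(p0 = 0.5, p1 = 0.5), CHG = c(p0 = 0.5, p1 = 0.5),
                     CHH = c(p0 = 0.6, p1 = 0.4)),
    seed = seed)
  reference <- generate_reference(cfg)
  truth <- generate_truth(reference, cfg)
  reads <- lapply(generate_event_reads(reference, truth, cfg), normalize_read)
  sites <- scan_cytosines(reference, 13L)
  ss <- label_samples(extract_site_samples(reads, sites, feature_config()), truth$states)
  ss <- subset_samples(ss, !is.na(ss$info$label))
  ss <- filter_separable_samples(ss, truth, cfg$effect_width)
  pos <- subset_samples(ss, ss$info$label == 1L)
  neg <- subset_samples(ss, ss$info$label == 0L)
  train_set <- bind_samples(pos, balance_negative_samples(pos, neg, seed = seed + 10L))
  inj <- inject_mislabels(train_set, mislabel_ratio, seed = seed + 20L)
  trainer_cfg <- model_config(
    mode = "signal_only", branch_hidden = hidden, merged_hidden = hidden,
    merged_layers = 1L, dropout_rate = 0.1, batch_size = 128L,
    learning_rate = 0.01, max_epochs = epochs, early_stopping = FALSE,
    seed = seed)
  dn <- denoise_samples(inj$samples, make_denoise_trainer(trainer_cfg, epochs),
                        iterations = iterations, rounds = rounds,
                        seed = seed + 30L, verbose = verbose)
  removed_inj <- intersect(dn$removed_ids, inj$injected_ids)
  list(recovery = length(removed_inj) / length(inj$injected_ids),
       n_injected = length(inj$injected_ids),
       n_samples = n_samples(inj$samples),
       history = dn$history)
}

#' End-to-end parameter-recovery experiment on synthetic data
#'
#' Simulates a reference, event-aligned reads (context-dependent baseline
#' currents, methylation shift `delta = 3 * sigma` unless `null_model`), and
#' a bisulfite report; selects high-confidence training sites from the
#' bisulfite table; trains the two-branch model on balanced samples; calls
#' every read and aggregates per-site frequencies. Reports the Pearson
#' correlation between called and true per-site frequencies (coverage >= 5)
#' and read-level metrics on samples from fully methylated / fully
#' unmethylated truth sites.
#'
#' @param seed Integer master seed.
#' @param genome_length Reference length (default 3000 bp).
#' @param coverage Total read coverage across both strands (default 20).
#' @param null_model Negative control isolating the current-signal channel:
#'   the methylation signal shift is set to zero, baseline levels are made
#'   context-independent, class frequencies are balanced, and the
#'   signal-only model is trained — its inputs then carry no information
#'   about the labels and read-level AUC is expected near 0.5. (With the
#'   full model and context-dependent baselines an above-chance AUC would
#'   reflect genuine sequence-frequency associations, not signal.)
#' @param epochs,hidden Training scale of the full model.
#' @param verbose Print progress.
#' @return List with `pearson_r`, `n_sites`, `read_level` (mean metrics),
#'   `n_read_samples`, and the trained model's `history`.
#' @export
pipeline_experiment <- function(seed = 1L, genome_length = 3000L, coverage = 20,
                                null_model = FALSE, epochs = 12L, hidden = 48L,
                                verbose = FALSE) {
  cfg <- synthetic_config(genome_length = genome_length, coverage = coverage,
                          seed = seed)
  if (null_model) {
    cfg$delta <- 0
    cfg$kmer_level_sd <- 0
    cfg$freq_dist <- list(CpG = c(p0 = 0.5, p1 = 0.5), CHG = c(p0 = 0.5, p1 = 0.5),
                          CHH = c(p0 = 0.5, p1 = 0.5))
  }
  reference <- generate_reference(cfg)
  truth <- generate_truth(reference, cfg)
  reads <- lapply(generate_event_reads(reference, truth, cfg), normalize_read)
  sites <- scan_cytosines(reference, 13L)
  ss <- extract_site_samples(reads, sites, feature_config())
  bs <- generate_bisulfite_table(truth, reference, cfg)
  hc_all <- lapply(CONTEXTS, function(ctx) select_high_confidence_sites(bs, ctx))
  hc <- list(methylated = do.call(rbind, lapply(hc_all, `[[`, "methylated")),
             unmethylated = do.call(rbind, lapply(hc_all, `[[`, "unmethylated")))
  lab <- label_from_high_confidence(ss, hc)
  pos <- subset_samples(lab, lab$info$label == 1L)
  neg <- subset_samples(lab, lab$info$label == 0L)
  train_set <- bind_samples(pos, balance_negative_samples(pos, neg, seed = seed + 1L))
  parts <- split_train_valid(train_set, 0.95, seed = seed + 2L)
  mc <- model_config(mode = if (null_model) "signal_only" else "full",
                     branch_hidden = hidden, merged_hidden = hidden,
                     merged_layers = 1L, dropout_rate = 0.1, batch_size = 128L,
                     learning_rate = 0.01, max_epochs = epochs,
                     early_stopping = FALSE, seed = seed + 3L)
  model <- train_model(build_model(mc), parts$train, parts$valid)
  if (verbose) message("validation accuracy: ",
                       paste(round(model$history$valid_acc, 3), collapse = " "))
  calls <- call_reads(model, ss)
  freqs <- aggregate_frequencies(calls)
  tkey <- site_key(truth$sites$chrom, truth$sites$pos, truth$sites$strand)
  fkey <- site_key(freqs$chrom, freqs$pos, freqs$strand)
  mm <- match(fkey, tkey)
  sel <- freqs$coverage >= 5L & !is.na(mm)
  # constant calls (e.g. the null control) make the correlation undefined
  pearson_r <- suppressWarnings(
    stats::cor(freqs$frequency[sel], truth$sites$frequency[mm[sel]]))
  ssl <- label_samples(ss, truth$states)
  skey <- site_key(ssl$info$chrom, ssl$info$pos, ssl$info$strand)
  tf <- truth$sites$frequency[match(skey, tkey)]
  sel01 <- !is.na(ssl$info$label) & !is.na(tf) & (tf == 0 | tf == 1)
  pr <- predict(model, subset_samples(ssl, sel01))
  rl <- read_level_metrics(pr$p_methylated, ssl$info$label[sel01],
                           n_subsample = 2000L, repeats = 5L, seed = seed + 4L)
  list(pearson_r = pearson_r, n_sites = sum(sel), read_level = rl$mean,
       n_read_samples = sum(sel01), history = model$history)
}
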