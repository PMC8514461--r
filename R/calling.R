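# Per-read methylation calls, per-site frequency aggregation, binning.

#' Call per-read methylation status
#'
#' Predicts (P_m, P_um) for every sample and calls a site methylated in a
#' read iff P_m > P_um (a tie is called unmethylated).
#'
#' @param model A trained `methyl_model`.
#' @param samples A `site_samples` object.
#' @param ref_lengths Optional named vector of contig lengths used to fill
#'   the `pos_in_strand` column (the coordinate on the C's own strand axis);
#'   without it, minus-strand `pos_in_strand` is `-1`.
#' @return data.frame of call records with columns `chrom`, `pos`, `strand`,
#'   `pos_in_strand`, `read_id`, `prob_unmeth`, `prob_meth`, `call`, `kmer`.
#' @export
call_reads <- function(model, samples, ref_lengths = NULL) {
  pr <- predict(model, samples)
  info <- samples$info
  pis <- info$pos
  minus <- info$strand == "-"
  if (!is.null(ref_lengths)) {
    pis[minus] <- as.integer(ref_lengths[info$chrom[minus]]) - 1L - info$pos[minus]
  } else {
    pis[minus] <- -1L
  }
  data.frame(chrom = info$chrom, pos = info$pos, strand = info$strand,
             pos_in_strand = pis, read_id = info$read_id,
             prob_unmeth = pr$p_unmethylated, prob_meth = pr$p_methylated,
             call = as.integer(pr$p_methylated > pr$p_unmethylated),
             kmer = info$kmer, stringsAsFactors = FALSE)
}

#' Aggregate per-read calls into per-site methylation frequencies
#'
#' For each genomic cytosine (chrom, pos, strand), coverage is the number of
#' call records, `n_meth` the number called methylated, and the frequency
#' their ratio. Frequencies are reported per strand; no CpG strand merging is
#' performed. The context is derived from the k-mer.
#'
#' @param records data.frame of call records (see [call_reads()]).
#' @param contexts Optional subset of contexts to retain.
#' @return data.frame with columns `chrom`, `pos`, `strand`, `context`,
#'   `coverage`, `n_meth`, `frequency`.
#' @export
aggregate_frequencies <- function(records, contexts = CONTEXTS) {
  dt <- data.table::as.data.table(records)
  agg <- dt[, list(context = context_from_kmer(kmer[1]),
                   coverage = .N, n_meth = sum(call == 1L)),
            by = c("chrom", "pos", "strand")]
  agg[, "frequency" := agg$n_meth / agg$coverage]
  agg <- agg[agg$context %in% contexts]
  data.table::setorderv(agg, c("chrom", "pos", "strand"))
  as.data.frame(agg)
}

#' Bin sites into low / intermediate / high methylation classes
#'
#' After filtering to sites with at least `min_coverage` mapped reads, a site
#' is lowly methylated when its frequency is at most 0.3, highly methylated
#' when at least 0.7, and intermediately methylated strictly between.
#'
#' @param freqs data.frame from [aggregate_frequencies()] (or any table with
#'   `coverage` and `frequency` columns).
#' @param min_coverage Coverage filter (default 5).
#' @param low,high Bin boundaries (defaults 0.3 and 0.7).
#' @return `freqs` restricted to covered sites, with a `bin` column taking
#'   values `"low"`, `"intermediate"`, `"high"`.
#' @export
bin_sites <- function(freqs, min_coverage = 5L, low = 0.3, high = 0.7) {
  out <- freqs[freqs$coverage >= min_coverage, , drop = FALSE]
  out$bin <- ifelse(out$frequency <= low, "low",
                    ifelse(out$frequency >= high, "high", "intermediate"))
  rownames(out) <- NULL
  out
}
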