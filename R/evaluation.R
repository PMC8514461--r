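# Site-level and read-level evaluation against bisulfite truth.

#' Area under the ROC curve (rank-based)
#'
#' Wilcoxon/Mann-Whitney formulation with midranks for ties: equivalent to
#' the trapezoidal area over all thresholds.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 truth labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stopf("AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

metrics_one <- function(x, y) {
  data.frame(n_sites = length(x),
             pearson_r = stats::cor(x, y),
             r_squared = stats::cor(x, y)^2,
             spearman_rho = stats::cor(x, y, method = "spearman"),
             rmse = sqrt(mean((x - y)^2)))
}

#' Compare Nanopore frequencies with bisulfite frequencies
#'
#' Inner-joins the two tables on (chrom, pos, strand), keeps sites with at
#' least `min_coverage` mapped reads on both sides, and reports Pearson r,
#' r-squared, Spearman rho and RMSE, overall and per context. With several
#' bisulfite replicates the metrics are averaged across replicates.
#'
#' @param nanopore data.frame from [aggregate_frequencies()].
#' @param bisulfite A bisulfite report data.frame (see
#'   [read_bisulfite_report()]) or a list of replicate reports.
#' @param min_coverage Coverage filter applied to both sides (default 5).
#' @return List with `overall` (one-row data.frame) and `per_context`
#'   (data.frame with a `context` column); both carry the metric columns
#'   `n_sites`, `pearson_r`, `r_squared`, `spearman_rho`, `rmse`.
#' @export
compare_frequencies <- function(nanopore, bisulfite, min_coverage = 5L) {
  if (is.data.frame(bisulfite)) bisulfite <- list(bisulfite)
  np <- nanopore[nanopore$coverage >= min_coverage, , drop = FALSE]
  np_keys <- site_key(np$chrom, np$pos, np$strand)
  per_rep <- lapply(bisulfite, function(bs) {
    cov <- bs$count_methylated + bs$count_unmethylated
    bs <- bs[cov >= min_coverage, , drop = FALSE]
    bs_freq <- bs_frequency(bs)
    m <- match(np_keys, site_key(bs$chrom, bs$pos, bs$strand))
    sel <- !is.na(m)
    if (sum(sel) < 2L) stopf("fewer than 2 joined sites: correlation undefined")
    data.frame(context = np$context[sel],
               nano = np$frequency[sel], bs = bs_freq[m[sel]],
               stringsAsFactors = FALSE)
  })
  avg <- function(ctx_filter) {
    reps <- lapply(per_rep, function(j) {
      jj <- if (is.null(ctx_filter)) j else j[j$context == ctx_filter, , drop = FALSE]
      if (nrow(jj) < 2L) return(NULL)
      metrics_one(jj$nano, jj$bs)
    })
    reps <- reps[!vapply(reps, is.null, logical(1))]
    if (length(reps) == 0L) return(NULL)
    out <- Reduce(`+`, reps) / length(reps)
    out$n_sites <- as.integer(round(out$n_sites))
    out
  }
  overall <- avg(NULL)
  per_ctx <- lapply(CONTEXTS, function(ctx) {
    m <- avg(ctx)
    if (is.null(m)) return(NULL)
    cbind(data.frame(context = ctx, stringsAsFactors = FALSE), m)
  })
  per_ctx <- do.call(rbind, per_ctx[!vapply(per_ctx, is.null, logical(1))])
  list(overall = overall, per_context = per_ctx)
}

#' Read-level classification metrics with class-balanced subsampling
#'
#' Emulates read-level benchmarking against fully methylated / fully
#' unmethylated truth sites: per repeat, up to `n_subsample` samples are
#' drawn from each class without replacement and accuracy, sensitivity,
#' specificity and AUC are computed; means and standard deviations across
#' repeats are reported.
#'
#' @param p_methylated Numeric methylation probabilities.
#' @param labels 0/1 truth labels.
#' @param n_subsample Per-class subsample size (default 100000).
#' @param repeats Number of subsampling repeats (default 5).
#' @param seed Integer seed.
#' @return List with `per_repeat` (data.frame of the four metrics per
#'   repeat), `mean` and `sd` (named numeric vectors).
#' @export
read_level_metrics <- function(p_methylated, labels, n_subsample = 100000L,
                               repeats = 5L, seed = 1L) {
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (length(pos) == 0L || length(neg) == 0L) stopf("both classes must be present")
  set.seed(seed)
  rows <- lapply(seq_len(repeats), function(rep_i) {
    ip <- if (length(pos) > n_subsample) sample(pos, n_subsample) else pos
    in_ <- if (length(neg) > n_subsample) sample(neg, n_subsample) else neg
    idx <- c(ip, in_)
    y <- labels[idx]
    p <- p_methylated[idx]
    call <- as.integer(p > 0.5)
    data.frame(repeat_i = rep_i,
               accuracy = mean(call == y),
               sensitivity = mean(call[y == 1L] == 1L),
               specificity = mean(call[y == 0L] == 0L),
               auc = auc_score(p, y))
  })
  per_repeat <- do.call(rbind, rows)
  m <- colMeans(per_repeat[, -1, drop = FALSE])
  s <- apply(per_repeat[, -1, drop = FALSE], 2, stats::sd)
  list(per_repeat = per_repeat, mean = m, sd = s)
}
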