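# Sequence- and signal-feature extraction for cytosine sites in reads.
#
# For one cytosine in one read the features are
#   * a k x 4 sequence-feature matrix: base code (A=0,C=1,G=2,T=3), mean of
#     the base's normalized signals, population standard deviation, and the
#     number of signals of the base;
#   * a k x m signal-feature matrix of subsampled normalized signal values,
#     zero-padded on the right for bases with fewer than m signals.
# Rows run 5'->3' on the site's strand; minus-strand sites use the
# reverse-complemented k-mer and base-reversed rows.

#' Feature extraction configuration
#'
#' @param k Odd k-mer length centered on the target cytosine (default 13).
#' @param m Number of signal values retained per base (default 16).
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(k = 13L, m = 16L) {
  k <- as.integer(k); m <- as.integer(m)
  if (k < 3L || k %% 2L == 0L) stopf("k must be an odd integer >= 3, got %d", k)
  if (m < 1L) stopf("m must be >= 1, got %d", m)
  structure(list(k = k, m = m), class = "feature_config")
}

#' Subsample a base's signals to a fixed length
#'
#' Returns the signals unchanged when there are exactly `m`; selects `m`
#' values at evenly spaced indices `floor(i * n / m)`, i = 0..m-1, when there
#' are more; pads with trailing zeros when there are fewer.
#'
#' @param signals Non-empty numeric vector.
#' @param m Target length.
#' @return Numeric vector of length `m`.
#' @export
sample_signals <- function(signals, m) {
  n <- length(signals)
  if (n == 0L) stopf("cannot sample from an empty signal vector")
  if (n == m) return(as.numeric(signals))
  if (n > m) return(as.numeric(signals[floor((0:(m - 1L)) * n / m) + 1L]))
  c(as.numeric(signals), rep(0, m - n))
}

# Per-read summaries reused across all sites of the read.
read_base_stats <- function(read, m) {
  list(mean = vapply(read$signals, function(s) sum(s) / length(s), numeric(1)),
       sd = vapply(read$signals, pop_sd, numeric(1)),
       count = lengths(read$signals),
       sig = t(vapply(read$signals, sample_signals, numeric(m), m = m)))
}

#' Extract the feature matrices for one cytosine in one read
#'
#' @param read A normalized [event_read()] whose strand matches the site's.
#' @param site One-row data.frame (or list) with `chrom`, `pos`, `strand`,
#'   `kmer` as produced by [scan_cytosines()].
#' @param cfg A [feature_config()].
#' @return List with `chrom`, `pos`, `strand`, `read_id`, `kmer`,
#'   `seq_features` (k x 4 matrix: code, mean, sd, count) and
#'   `signal_features` (k x m matrix), or `NULL` when the read does not cover
#'   the full k-window of the site.
#' @export
extract_site_sample <- function(read, site, cfg = feature_config()) {
  k2 <- cfg$k %/% 2L
  read_end <- read$start + length(read$signals)
  if (site$chrom != read$chrom || site$strand != read$strand ||
      site$pos - k2 < read$start || site$pos + k2 >= read_end) {
    return(NULL)
  }
  st <- read_base_stats(read, cfg$m)
  idx <- (site$pos - k2):(site$pos + k2) - read$start + 1L
  if (site$strand == "-") idx <- rev(idx)
  seqf <- cbind(code = as.numeric(BASE_CODE[strsplit(site$kmer, "")[[1]]]),
                mean = st$mean[idx], sd = st$sd[idx], count = as.numeric(st$count[idx]))
  dimnames(seqf) <- list(NULL, c("code", "mean", "sd", "count"))
  list(chrom = site$chrom, pos = site$pos, strand = site$strand,
       read_id = read$read_id, kmer = site$kmer,
       seq_features = seqf,
       signal_features = st$sig[idx, , drop = FALSE])
}

#' Construct a columnar set of site samples
#'
#' `site_samples` stores many per-(read, site) feature samples in parallel
#' arrays for efficient batching: an `info` data.frame (sample_id, chrom,
#' pos, strand, read_id, kmer, label), integer base codes (n x k), the three
#' numeric sequence features (n x k each) and the signal features
#' (n x k x m array). Labels are 1 = methylated, 0 = unmethylated,
#' `NA` = unlabelled.
#'
#' @param info data.frame as described above.
#' @param seq_code,seq_mean,seq_sd,seq_count n x k matrices.
#' @param signal n x k x m array.
#' @return Object of class `site_samples`.
#' @export
site_samples <- function(info, seq_code, seq_mean, seq_sd, seq_count, signal) {
  n <- nrow(info)
  stopifnot(nrow(seq_code) == n, nrow(seq_mean) == n, nrow(seq_sd) == n,
            nrow(seq_count) == n, dim(signal)[1] == n)
  if (is.null(info$label)) info$label <- NA_integer_
  structure(list(info = info, seq_code = seq_code, seq_mean = seq_mean,
                 seq_sd = seq_sd, seq_count = seq_count, signal = signal),
            class = "site_samples")
}

#' Number of samples in a `site_samples` set
#' @param x A `site_samples` object.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$info)

#' @export
print.site_samples <- function(x, ...) {
  k <- ncol(x$seq_code); m <- dim(x$signal)[3]
  lab <- x$info$label
  cat(sprintf("<site_samples: %d samples, k=%d, m=%d; %d pos / %d neg / %d unlabelled>\n",
              n_samples(x), k, m, sum(lab == 1L, na.rm = TRUE),
              sum(lab == 0L, na.rm = TRUE), sum(is.na(lab))))
  invisible(x)
}

#' Subset a `site_samples` set by index
#' @param x A `site_samples` object.
#' @param idx Integer or logical index vector.
#' @return The subset, a `site_samples` object.
#' @export
subset_samples <- function(x, idx) {
  site_samples(x$info[idx, , drop = FALSE],
               x$seq_code[idx, , drop = FALSE], x$seq_mean[idx, , drop = FALSE],
               x$seq_sd[idx, , drop = FALSE], x$seq_count[idx, , drop = FALSE],
               x$signal[idx, , , drop = FALSE])
}

#' Concatenate `site_samples` sets
#' @param ... `site_samples` objects with identical k and m.
#' @return The row-bound `site_samples` object.
#' @export
bind_samples <- function(...) {
  xs <- list(...)
  xs <- xs[vapply(xs, function(x) n_samples(x) > 0L, logical(1))]
  if (length(xs) == 0L) return(list(...)[[1]])
  if (length(xs) == 1L) return(xs[[1]])
  sig <- do.call(abind3, lapply(xs, `[[`, "signal"))
  site_samples(do.call(rbind, lapply(xs, `[[`, "info")),
               do.call(rbind, lapply(xs, `[[`, "seq_code")),
               do.call(rbind, lapply(xs, `[[`, "seq_mean")),
               do.call(rbind, lapply(xs, `[[`, "seq_sd")),
               do.call(rbind, lapply(xs, `[[`, "seq_count")),
               sig)
}

# bind 3D arrays along the first dimension
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(x) dim(x)[1], integer(1)))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0L
  for (x in xs) {
    nx <- dim(x)[1]
    if (nx > 0L) out[at + seq_len(nx), , ] <- x
    at <- at + nx
  }
  out
}

#' Set sample labels from per-molecule truth
#'
#' Joins samples against a table of per-(read, site) methylation states and
#' stores the state as the label.
#'
#' @param samples A `site_samples` object.
#' @param states data.frame with columns `read_id`, `chrom`, `pos`, `strand`,
#'   `state` (0/1).
#' @return `samples` with labels filled where a state was found.
#' @export
label_samples <- function(samples, states) {
  key_s <- paste(samples$info$read_id, samples$info$chrom,
                 samples$info$pos, samples$info$strand, sep = ":")
  key_t <- paste(states$read_id, states$chrom, states$pos, states$strand, sep = ":")
  samples$info$label <- as.integer(states$state[match(key_s, key_t)])
  samples
}

#' Extract feature samples for all covered (read, site) pairs
#'
#' Emits one sample per read and per cytosine site whose full k-window the
#' read covers on the matching strand; sites with partial window coverage are
#' skipped (counted, not fatal). Reads must already be normalized
#' (see [normalize_read()]).
#'
#' @param reads List of normalized [event_read()] objects.
#' @param sites data.frame from [scan_cytosines()] (same k as `cfg`).
#' @param cfg A [feature_config()].
#' @return A `site_samples` object with attribute `n_skipped`: the number of
#'   (read, overlapping site) pairs dropped for lacking the full window.
#' @export
extract_site_samples <- function(reads, sites, cfg = feature_config()) {
  k <- cfg$k; m <- cfg$m; k2 <- k %/% 2L
  per_read <- vector("list", length(reads))
  n_skipped <- 0L
  for (ri in seq_along(reads)) {
    read <- reads[[ri]]
    len <- length(read$signals)
    read_end <- read$start + len
    cand <- sites$chrom == read$chrom & sites$strand == read$strand &
      sites$pos >= read$start & sites$pos < read_end
    if (!any(cand)) next
    sr <- sites[cand, , drop = FALSE]
    full <- sr$pos - k2 >= read$start & sr$pos + k2 < read_end
    n_skipped <- n_skipped + sum(!full)
    sr <- sr[full, , drop = FALSE]
    ns <- nrow(sr)
    if (ns == 0L) next
    st <- read_base_stats(read, m)
    # n_s x k matrix of per-row reference offsets within the read
    off <- outer(sr$pos - read$start + 1L, (-k2):k2, `+`)
    minus <- sr$strand == "-"
    if (any(minus)) off[minus, ] <- off[minus, k:1, drop = FALSE]
    code <- matrix(BASE_CODE[unlist(strsplit(sr$kmer, ""), use.names = FALSE)],
                   nrow = ns, ncol = k, byrow = TRUE)
    sig <- array(t(st$sig[t(off), , drop = FALSE]), dim = c(m, k, ns))
    sig <- aperm(sig, c(3, 2, 1))
    info <- data.frame(
      sample_id = paste(read$read_id, sr$chrom, sr$pos, sr$strand, sep = ":"),
      chrom = sr$chrom, pos = sr$pos, strand = sr$strand,
      read_id = read$read_id, kmer = sr$kmer, label = NA_integer_,
      stringsAsFactors = FALSE)
    per_read[[ri]] <- site_samples(
      info, code,
      matrix(st$mean[off], ns, k), matrix(st$sd[off], ns, k),
      matrix(as.numeric(st$count[off]), ns, k), sig)
  }
  per_read <- per_read[!vapply(per_read, is.null, logical(1))]
  if (length(per_read) == 0L) {
    out <- empty_site_samples(k, m)
  } else {
    out <- do.call(bind_samples, per_read)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_site_samples <- function(k, m) {
  site_samples(
    data.frame(sample_id = character(), chrom = character(), pos = integer(),
               strand = character(), read_id = character(), kmer = character(),
               label = integer(), stringsAsFactors = FALSE),
    matrix(integer(), 0, k), matrix(numeric(), 0, k),
    matrix(numeric(), 0, k), matrix(numeric(), 0, k),
    array(numeric(), dim = c(0, k, m)))
}
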