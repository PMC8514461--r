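# Differential-methylation analysis between members of repeat pairs
# (near-identical intervals from a self-alignment of the reference).

#' Filter repeat pairs by length, identity and cytosine content
#'
#' Keeps pairs whose alignment length and identity meet the (inclusive)
#' thresholds; when a reference is supplied, pairs without a single cytosine
#' (C or G base, i.e. a cytosine on either strand) in either member are
#' dropped.
#'
#' @param pairs data.frame from [read_repeat_coords()].
#' @param min_length Minimum alignment length in bp (default 100).
#' @param min_identity Minimum alignment identity as a fraction
#'   (default 0.99).
#' @param reference Optional named character vector of contig sequences.
#' @return The filtered data.frame.
#' @export
filter_pairs <- function(pairs, min_length = 100L, min_identity = 0.99,
                         reference = NULL) {
  keep <- pairs$length >= min_length & pairs$identity >= min_identity
  out <- pairs[keep, , drop = FALSE]
  if (!is.null(reference) && nrow(out) > 0L) {
    has_c <- vapply(seq_len(nrow(out)), function(i) {
      a <- substr(reference[[out$chrom_a[i]]], out$start_a[i] + 1L, out$end_a[i])
      b <- substr(reference[[out$chrom_b[i]]], out$start_b[i] + 1L, out$end_b[i])
      grepl("[CG]", a) || grepl("[CG]", b)
    }, logical(1))
    out <- out[has_c, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Match cytosines between the two members of a repeat pair
#'
#' Cytosines are paired by identical offset from each member's start
#' (gap-free pairing within the aligned interval). For reverse-orientation
#' pairs, offset o in member A maps to offset (length - 1 - o) in member B
#' and the strand flips. An offset is retained only when both members carry
#' a frequency with at least `min_coverage` reads at the matched positions.
#'
#' @param pair One row of a pairs data.frame (as a data.frame or list).
#' @param freqs data.frame from [aggregate_frequencies()].
#' @param reference Named character vector of contig sequences (used for the
#'   context of the member-A cytosine).
#' @param min_coverage Minimum call coverage for a frequency to participate
#'   (default 5).
#' @return List of class `pair_profile` with the pair and a `matched`
#'   data.frame (`offset`, `strand`, `context`, `freq_a`, `freq_b`).
#' @export
match_cytosines <- function(pair, freqs, reference, min_coverage = 5L) {
  len_a <- pair$end_a - pair$start_a
  len_b <- pair$end_b - pair$start_b
  L <- min(len_a, len_b)
  fr <- freqs[freqs$coverage >= min_coverage, , drop = FALSE]
  fkey <- site_key(fr$chrom, fr$pos, fr$strand)
  lookup <- function(chrom, pos, strand) {
    i <- match(site_key(chrom, pos, strand), fkey)
    ifelse(is.na(i), NA_real_, fr$frequency[i])
  }
  flip <- function(s) ifelse(s == "+", "-", "+")
  rows <- lapply(c("+", "-"), function(s) {
    off <- 0:(L - 1L)
    pos_a <- pair$start_a + off
    if (pair$orient == "+") {
      pos_b <- pair$start_b + off
      s_b <- s
    } else {
      pos_b <- pair$end_b - 1L - off
      s_b <- flip(s)
    }
    fa <- lookup(pair$chrom_a, pos_a, s)
    fb <- lookup(pair$chrom_b, pos_b, s_b)
    ok <- !is.na(fa) & !is.na(fb)
    if (!any(ok)) return(NULL)
    ctx <- fr$context[match(site_key(pair$chrom_a, pos_a[ok], s), fkey)]
    data.frame(offset = off[ok], strand = s, context = ctx,
               freq_a = fa[ok], freq_b = fb[ok], stringsAsFactors = FALSE)
  })
  matched <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(matched)) {
    matched <- data.frame(offset = integer(), strand = character(),
                          context = character(), freq_a = numeric(),
                          freq_b = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(pair = pair, matched = matched), class = "pair_profile")
}

#' Classify a repeat pair as differentially methylated
#'
#' A matched cytosine is differentially methylated when
#' `|freq_a - freq_b| >= diff_threshold`. The pair is differentially
#' methylated for a class (all cytosines, or CpG / CHG / CHH independently)
#' when at least `fraction_threshold` of the matched cytosines of that class
#' are differential. Classes with no matched cytosines get an `NA` flag.
#'
#' @param profile A `pair_profile` from [match_cytosines()].
#' @param diff_threshold Per-cytosine frequency difference (default 0.5).
#' @param fraction_threshold Fraction of differential cytosines required
#'   (default 0.10).
#' @return The profile with added `counts` (data.frame per class: matched,
#'   differential, flag).
#' @export
classify_pair <- function(profile, diff_threshold = 0.5, fraction_threshold = 0.10) {
  m <- profile$matched
  # small epsilon so boundary differences (e.g. 0.7 - 0.2) are not lost to
  # floating-point representation
  diff <- abs(m$freq_a - m$freq_b) >= diff_threshold - 1e-9
  one <- function(class, sel) {
    n <- sum(sel)
    nd <- sum(diff[sel])
    data.frame(class = class, matched = n, differential = nd,
               flag = if (n == 0L) NA else nd / n >= fraction_threshold,
               stringsAsFactors = FALSE)
  }
  profile$counts <- rbind(one("allC", rep(TRUE, nrow(m))),
                          one("CpG", m$context == "CpG"),
                          one("CHG", m$context == "CHG"),
                          one("CHH", m$context == "CHH"))
  profile
}

#' @export
print.pair_profile <- function(x, ...) {
  cat(sprintf("<pair_profile %s:%d-%d ~ %s:%d-%d (%s), %d matched cytosines>\n",
              x$pair$chrom_a, x$pair$start_a, x$pair$end_a,
              x$pair$chrom_b, x$pair$start_b, x$pair$end_b,
              x$pair$orient, nrow(x$matched)))
  if (!is.null(x$counts)) print(x$counts)
  invisible(x)
}

#' Profile and classify all repeat pairs
#'
#' @param pairs data.frame of (already filtered) repeat pairs.
#' @param freqs data.frame from [aggregate_frequencies()].
#' @param reference Named character vector of contig sequences.
#' @param min_coverage,diff_threshold,fraction_threshold See
#'   [match_cytosines()] and [classify_pair()].
#' @return data.frame with one row per pair: coordinates plus per-class
#'   matched/differential counts and flags.
#' @export
repeat_pair_report <- function(pairs, freqs, reference, min_coverage = 5L,
                               diff_threshold = 0.5, fraction_threshold = 0.10) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- classify_pair(
      match_cytosines(pairs[i, , drop = FALSE], freqs, reference, min_coverage),
      diff_threshold, fraction_threshold)
    cnt <- pr$counts
    vals <- list()
    for (j in seq_len(nrow(cnt))) {
      cl <- cnt$class[j]
      vals[[paste0("matched_", cl)]] <- cnt$matched[j]
      vals[[paste0("diff_", cl)]] <- cnt$differential[j]
      vals[[paste0("flag_", cl)]] <- cnt$flag[j]
    }
    wide <- as.data.frame(vals)
    cbind(pairs[i, c("chrom_a", "start_a", "end_a", "chrom_b", "start_b",
                     "end_b", "orient", "length", "identity")], wide)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
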