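# Readers and writers for every external format the tool touches.
#
# Dialects:
#   * Reference genome: FASTA (via Biostrings).
#   * Bisulfite cytosine report (Bismark-style), TSV, 1-based positions:
#       chrom  pos  strand  count_methylated  count_unmethylated  context  trinucleotide
#   * Event-aligned reads: JSON-lines, one read per line with fields
#       read_id, chrom, strand, start (0-based), bases (string),
#       signals (list of per-base numeric arrays).
#   * Per-read calls, TSV (0-based pos):
#       chrom  pos  strand  pos_in_strand  read_id  prob_unmeth  prob_meth  call  kmer
#   * Site frequencies, TSV (0-based pos):
#       chrom  pos  strand  context  coverage  n_meth  frequency
#   * Repeat coordinates (show-coords-style), TSV with header, 1-based
#       inclusive intervals:
#       start_a  end_a  start_b  end_b  len_a  len_b  identity  chrom_a  chrom_b

#' Read a reference genome FASTA
#'
#' @param path Path to a FASTA file.
#' @return Named character vector mapping contig name (first whitespace-token
#'   of the header) to its uppercase sequence.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stopf("FASTA file '%s' contains no records", path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    stopf("FASTA contig '%s' contains letters other than A,C,G,T,N",
          names(out)[which(bad)[1]])
  }
  out
}

#' Write contig sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a bisulfite cytosine report
#'
#' Parses a Bismark-style per-cytosine TSV (no header) with columns
#' chrom, 1-based position, strand, methylated count, unmethylated count,
#' context class, trinucleotide. Positions are converted to 0-based.
#' Records with zero coverage are retained (parsing does not filter).
#'
#' @param path Path to the report.
#' @return `data.frame` with columns `chrom`, `pos` (0-based), `strand`,
#'   `count_methylated`, `count_unmethylated`, `context`, `trinucleotide`.
#' @export
read_bisulfite_report <- function(path) {
  cols <- c("chrom", "pos", "strand", "count_methylated",
            "count_unmethylated", "context", "trinucleotide")
  empty <- isTRUE(file.size(path) == 0)
  dt <- if (empty) data.table::data.table() else {
    data.table::fread(path, sep = "\t", header = FALSE,
                      colClasses = list(character = c(1, 3, 6, 7)))
  }
  if (nrow(dt) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(), strand = character(),
                      count_methylated = integer(), count_unmethylated = integer(),
                      context = character(), trinucleotide = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (ncol(dt) != 7L) stopf("bisulfite report '%s': expected 7 columns, found %d", path, ncol(dt))
  data.table::setnames(dt, cols)
  bad_strand <- which(!dt$strand %in% c("+", "-"))
  if (length(bad_strand)) stopf("bisulfite report '%s' line %d: unknown strand '%s'",
                                path, bad_strand[1], dt$strand[bad_strand[1]])
  for (cc in c("pos", "count_methylated", "count_unmethylated")) {
    v <- dt[[cc]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v)) ||
        any(v < ifelse(cc == "pos", 1, 0))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))) | is.na(v))
      stopf("bisulfite report '%s' line %d: non-integer %s", path,
            if (length(bad)) bad[1] else which(v != floor(v) | v < 0)[1], cc)
    }
  }
  ctx <- dt$context
  ctx[ctx %in% c("CG", "CpG")] <- "CpG"
  bad_ctx <- which(!ctx %in% CONTEXTS)
  if (length(bad_ctx)) stopf("bisulfite report '%s' line %d: unknown context '%s'",
                             path, bad_ctx[1], ctx[bad_ctx[1]])
  data.frame(chrom = dt$chrom, pos = as.integer(dt$pos) - 1L, strand = dt$strand,
             count_methylated = as.integer(dt$count_methylated),
             count_unmethylated = as.integer(dt$count_unmethylated),
             context = ctx, trinucleotide = dt$trinucleotide,
             stringsAsFactors = FALSE)
}

#' Write a bisulfite cytosine report
#'
#' Inverse of [read_bisulfite_report()]; emits 1-based positions.
#'
#' @param records data.frame as returned by [read_bisulfite_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bisulfite_report <- function(records, path) {
  dt <- data.table::data.table(
    chrom = records$chrom, pos = records$pos + 1L, strand = records$strand,
    count_methylated = records$count_methylated,
    count_unmethylated = records$count_unmethylated,
    context = records$context, trinucleotide = records$trinucleotide)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Methylation frequency of bisulfite records
#'
#' @param records data.frame from [read_bisulfite_report()].
#' @return Numeric vector `count_methylated / coverage`; `NA` where coverage
#'   is zero.
#' @export
bs_frequency <- function(records) {
  cov <- records$count_methylated + records$count_unmethylated
  ifelse(cov > 0, records$count_methylated / cov, NA_real_)
}

#' Construct an event-aligned read
#'
#' An event-aligned read maps one Nanopore read to a contiguous reference
#' interval; every reference base carries the list of normalized (or raw)
#' current values assigned to it by re-squiggling. Bases are stored on the
#' forward reference axis regardless of read strand.
#'
#' @param read_id Read identifier.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"` (strand of the sequenced molecule).
#' @param start 0-based reference start of the mapped interval.
#' @param bases Character scalar: reference-forward bases of the interval.
#' @param signals List of non-empty numeric vectors, one per base.
#' @return An object of class `event_read`.
#' @export
event_read <- function(read_id, chrom, strand, start, bases, signals) {
  if (!strand %in% c("+", "-")) stopf("read '%s': strand must be + or -", read_id)
  if (nchar(bases) != length(signals)) {
    stopf("read '%s': %d bases but %d signal groups declared",
          read_id, nchar(bases), length(signals))
  }
  if (any(lengths(signals) == 0L)) {
    stopf("read '%s': empty signal array at base %d", read_id,
          which(lengths(signals) == 0L)[1])
  }
  structure(list(read_id = read_id, chrom = chrom, strand = strand,
                 start = as.integer(start), bases = toupper(bases),
                 signals = lapply(signals, as.numeric)),
            class = "event_read")
}

#' @export
print.event_read <- function(x, ...) {
  cat(sprintf("<event_read %s %s:%d-%d (%s), %d bases, %d signals>\n",
              x$read_id, x$chrom, x$start, x$start + nchar(x$bases),
              x$strand, nchar(x$bases), sum(lengths(x$signals))))
  invisible(x)
}

#' Read event-aligned reads from JSON-lines
#'
#' @param path Path to a JSON-lines file, one read per line.
#' @return List of [event_read()] objects.
#' @export
read_event_reads <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE)
    sig <- rec$signals
    if (is.matrix(sig)) sig <- lapply(seq_len(nrow(sig)), function(r) sig[r, ])
    if (!is.list(sig)) sig <- as.list(sig)
    tryCatch(
      event_read(rec$read_id, rec$chrom, rec$strand, rec$start, rec$bases, sig),
      error = function(e) stopf("event reads '%s' line %d: %s", path, i, conditionMessage(e)))
  })
}

#' Write event-aligned reads to JSON-lines
#'
#' @param reads List of [event_read()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_reads <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in reads) {
    writeLines(jsonlite::toJSON(
      list(read_id = r$read_id, chrom = r$chrom, strand = r$strand,
           start = r$start, bases = r$bases, signals = r$signals),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

CALL_COLS <- c("chrom", "pos", "strand", "pos_in_strand", "read_id",
               "prob_unmeth", "prob_meth", "call", "kmer")

#' Write per-read methylation calls
#'
#' @param records data.frame of call records (see [call_reads()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_records <- function(records, path) {
  dt <- data.table::as.data.table(records)[, CALL_COLS, with = FALSE]
  data.table::fwrite(dt, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read per-read methylation calls
#'
#' @param path Path to a call TSV written by [write_call_records()].
#' @return data.frame of call records.
#' @export
read_call_records <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "strand", "read_id", "kmer")))
  if (!identical(names(dt), CALL_COLS)) {
    stopf("call file '%s': expected columns %s", path, paste(CALL_COLS, collapse = ", "))
  }
  as.data.frame(dt)
}

FREQ_COLS <- c("chrom", "pos", "strand", "context", "coverage", "n_meth", "frequency")

#' Write per-site methylation frequencies
#'
#' @param freqs data.frame of site frequencies (see [aggregate_frequencies()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_frequencies <- function(freqs, path) {
  dt <- data.table::as.data.table(freqs)[, FREQ_COLS, with = FALSE]
  data.table::fwrite(dt, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read per-site methylation frequencies
#'
#' @param path Path to a TSV written by [write_site_frequencies()].
#' @return data.frame of site frequencies.
#' @export
read_site_frequencies <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "strand", "context")))
  if (!identical(names(dt), FREQ_COLS)) {
    stopf("frequency file '%s': expected columns %s", path, paste(FREQ_COLS, collapse = ", "))
  }
  as.data.frame(dt)
}

#' Read self-alignment repeat coordinates
#'
#' Parses a show-coords-style TSV (with header) of a reference aligned to
#' itself. Intervals are 1-based inclusive in the file and converted to
#' 0-based half-open; a `b` interval with `end_b < start_b` denotes a
#' reverse-orientation alignment. Identity is given in percent and stored as
#' a fraction. Rows aligning an interval to itself are discarded.
#'
#' @param path Path to the coordinates TSV.
#' @return data.frame with columns `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`, `orient` (`"+"`/`"-"`), `length`, `identity`.
#' @export
read_repeat_coords <- function(path) {
  need <- c("start_a", "end_a", "start_b", "end_b", "len_a", "len_b",
            "identity", "chrom_a", "chrom_b")
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(need %in% names(dt))) {
    stopf("repeat coords '%s': expected columns %s", path, paste(need, collapse = ", "))
  }
  if (nrow(dt) == 0L) return(empty_repeat_pairs())
  if (any(dt$identity < 0 | dt$identity > 100)) {
    stopf("repeat coords '%s' line %d: identity outside [0,100]",
          path, which(dt$identity < 0 | dt$identity > 100)[1])
  }
  orient <- ifelse(dt$end_b >= dt$start_b, "+", "-")
  b_lo <- pmin(dt$start_b, dt$end_b)
  b_hi <- pmax(dt$start_b, dt$end_b)
  out <- data.frame(
    chrom_a = as.character(dt$chrom_a),
    start_a = as.integer(dt$start_a) - 1L, end_a = as.integer(dt$end_a),
    chrom_b = as.character(dt$chrom_b),
    start_b = as.integer(b_lo) - 1L, end_b = as.integer(b_hi),
    orient = orient,
    length = as.integer(dt$len_a),
    identity = dt$identity / 100,
    stringsAsFactors = FALSE)
  self <- out$chrom_a == out$chrom_b & out$start_a == out$start_b & out$end_a == out$end_b
  out <- out[!self, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_repeat_pairs <- function() {
  data.frame(chrom_a = character(), start_a = integer(), end_a = integer(),
             chrom_b = character(), start_b = integer(), end_b = integer(),
             orient = character(), length = integer(), identity = numeric(),
             stringsAsFactors = FALSE)
}
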