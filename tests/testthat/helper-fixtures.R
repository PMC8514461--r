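# Shared fixtures, built in code at test time.

CODE_TO_BASE <- c("A", "C", "G", "T")

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A random event-aligned read over a given contig window.
make_test_read <- function(contig, chrom = "c1", strand = "+", start = 0L,
                           len = nchar(contig) - start, read_id = "r1",
                           max_sig = 6L, seed = 1L) {
  set.seed(seed)
  bases <- substr(contig, start + 1L, start + len)
  signals <- lapply(seq_len(len), function(i) rnorm(sample.int(max_sig, 1L), 0, 1))
  event_read(read_id, chrom, strand, start, bases, signals)
}

# Naive both-strand cytosine enumeration with explicit reverse complement:
# the independent oracle for scan_cytosines().
naive_scan <- function(seq, k) {
  k2 <- k %/% 2L
  n <- nchar(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- strsplit(seq, "")[[1]]
  rc <- function(x) paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  rows <- list()
  for (i in seq_len(n)) {
    for (strand in c("+", "-")) {
      if (strand == "+") {
        if (ch[i] != "C") next
        if (i + 2L > n || i - k2 < 1L || i + k2 > n) next
        b1 <- ch[i + 1L]; b2 <- ch[i + 2L]
        kmer <- substr(seq, i - k2, i + k2)
      } else {
        if (ch[i] != "G") next
        if (i - 2L < 1L || i - k2 < 1L || i + k2 > n) next
        b1 <- comp[[ch[i - 1L]]]; b2 <- comp[[ch[i - 2L]]]
        kmer <- rc(substr(seq, i - k2, i + k2))
      }
      if (grepl("N", kmer) || b1 == "N" || b2 == "N") next
      ctx <- if (b1 == "G") "CpG" else if (b2 == "G") "CHG" else "CHH"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "c1", pos = i - 1L, strand = strand, context = ctx,
        kmer = kmer, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out <- out[order(out$chrom, out$pos, out$strand), ]
  rownames(out) <- NULL
  out
}

# Two-class Gaussian toy sample set: every base of a positive sample is
# shifted by delta. Feature matrices are internally consistent (mean/sd/count
# recomputed from the signal rows).
make_toy_samples <- function(n, delta = 0.75, sigma = 0.25, k = 13L, m = 16L,
                             seed = 1L) {
  set.seed(seed)
  lab <- rep(c(0L, 1L), length.out = n)
  code <- matrix(sample(0:3, n * k, replace = TRUE), n, k)
  code[, (k + 1L) %/% 2L] <- 1L  # center base is C
  sig <- array(rnorm(n * k * m, 0, sigma), dim = c(n, k, m)) + rep(lab * delta, k * m)
  kmer <- apply(code, 1, function(cc) paste(CODE_TO_BASE[cc + 1L], collapse = ""))
  info <- data.frame(
    sample_id = sprintf("s%05d", seq_len(n)), chrom = "c1",
    pos = seq_len(n), strand = "+", read_id = sprintf("r%05d", seq_len(n)),
    kmer = kmer, label = lab, stringsAsFactors = FALSE)
  site_samples(info, code,
               seq_mean = apply(sig, c(1, 2), mean),
               seq_sd = apply(sig, c(1, 2), function(x) sqrt(mean((x - mean(x))^2))),
               seq_count = matrix(m, n, k), signal = sig)
}

# Sample set with given kmers and labels (feature content irrelevant):
# for balancing/subsampling tests.
make_kmer_samples <- function(kmers, labels, k = 5L, m = 4L) {
  n <- length(kmers)
  km <- vapply(kmers, function(s) {
    paste(rep(s, length.out = k), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  info <- data.frame(sample_id = sprintf("s%04d", seq_len(n)),
                     chrom = rep("c1", n), pos = seq_len(n),
                     strand = rep("+", n),
                     read_id = sprintf("r%04d", seq_len(n)), kmer = km,
                     label = labels, stringsAsFactors = FALSE)
  site_samples(info, matrix(0L, n, k), matrix(0, n, k), matrix(0, n, k),
               matrix(1, n, k), array(0, dim = c(n, k, m)))
}
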