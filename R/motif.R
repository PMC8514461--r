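# Enumerate cytosine sites and their CpG/CHG/CHH context on both strands.

#' Scan a reference for cytosine sites in CpG/CHG/CHH contexts
#'
#' Emits every cytosine on either strand of every contig together with its
#' sequence context and the strand-oriented k-mer centered on the C. A
#' minus-strand cytosine appears as a G on the forward sequence; its k-mer is
#' reverse-complemented so the center always reads C and rows run 5'->3' on
#' the C-bearing strand. Sites are skipped when the k-mer window or the
#' 2-base downstream context window overruns the contig, or when any base of
#' either window is N.
#'
#' @param reference Named character vector of contig sequences
#'   (as from [read_fasta()]).
#' @param k Odd integer window size (>= 3).
#' @return data.frame with columns `chrom`, `pos` (0-based, forward axis),
#'   `strand`, `context`, `kmer`, sorted by chrom, pos, strand.
#' @export
scan_cytosines <- function(reference, k = 13L) {
  if (k %% 2L == 0L || k < 3L) stopf("k must be an odd integer >= 3, got %s", k)
  k2 <- k %/% 2L
  out <- lapply(names(reference), function(chrom) {
    s <- reference[[chrom]]
    n <- nchar(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]

    scan_one <- function(strand) {
      if (strand == "+") {
        i <- which(ch == "C")
        i <- i[i + 2L <= n & i - k2 >= 1L & i + k2 <= n]
        if (!length(i)) return(NULL)
        b1 <- ch[i + 1L]; b2 <- ch[i + 2L]
        kmer <- substring(s, i - k2, i + k2)
      } else {
        i <- which(ch == "G")
        i <- i[i - 2L >= 1L & i - k2 >= 1L & i + k2 <= n]
        if (!length(i)) return(NULL)
        b1 <- comp_chr(ch[i - 1L]); b2 <- comp_chr(ch[i - 2L])
        kmer <- revcomp(substring(s, i - k2, i + k2))
      }
      keep <- !grepl("N", kmer, fixed = TRUE) & b1 %in% BASES & b2 %in% BASES
      i <- i[keep]; b1 <- b1[keep]; b2 <- b2[keep]; kmer <- kmer[keep]
      if (!length(i)) return(NULL)
      ctx <- ifelse(b1 == "G", "CpG", ifelse(b2 == "G", "CHG", "CHH"))
      data.frame(chrom = chrom, pos = i - 1L, strand = strand,
                 context = ctx, kmer = kmer, stringsAsFactors = FALSE)
    }
    rbind(scan_one("+"), scan_one("-"))
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), strand = character(),
                      context = character(), kmer = character(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
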