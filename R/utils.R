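# Shared small helpers. Coordinates are 0-based half-open everywhere inside the
# package; 1-based columns exist only at serialization boundaries.

BASES <- c("A", "C", "G", "T")
BASE_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L)
CONTEXTS <- c("CpG", "CHG", "CHH")

comp_chr <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_chr(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

site_key <- function(chrom, pos, strand) paste(chrom, pos, strand, sep = ":")

#' Classify the sequence context of a centered k-mer
#'
#' The context of a cytosine is defined by the two bases 3' of the C on its
#' own strand: `CpG` if the next base is G, `CHG` if the base after next is G,
#' `CHH` otherwise (H = A, C or T). The k-mer must be strand-oriented with the
#' C at its center and long enough (k >= 5) to contain both downstream bases.
#'
#' @param kmer Character vector of odd-length uppercase k-mers centered on a C.
#' @return Character vector with values `"CpG"`, `"CHG"`, `"CHH"`, or `NA` when
#'   the downstream bases are unavailable or ambiguous.
#' @export
context_from_kmer <- function(kmer) {
  k <- nchar(kmer)
  ctr <- (k + 1L) %/% 2L
  b1 <- substr(kmer, ctr + 1L, ctr + 1L)
  b2 <- substr(kmer, ctr + 2L, ctr + 2L)
  out <- ifelse(b1 == "G", "CpG", ifelse(b2 == "G", "CHG", "CHH"))
  out[k < 5L | !(b1 %in% BASES) | !(b2 %in% BASES)] <- NA_character_
  out
}

# population (biased, divisor n) standard deviation
pop_sd <- function(x) {
  n <- length(x)
  if (n == 1L) return(0)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
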