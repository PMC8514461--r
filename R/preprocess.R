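# Signal normalization of event-aligned reads.

#' Median/MAD normalization of a read's current signals
#'
#' Replaces every raw current value x of the read by `(x - median) / MAD`,
#' where the median and the median absolute deviation are computed over all
#' signal values of the whole read. No consistency constant is applied to the
#' MAD and no outlier clipping is performed. The per-base grouping of signals
#' is preserved, so normalization is idempotent and invariant to positive
#' affine transforms of the raw current.
#'
#' @param read An [event_read()].
#' @return The read with normalized signals.
#' @export
normalize_read <- function(read) {
  all_sig <- unlist(read$signals, use.names = FALSE)
  med <- stats::median(all_sig)
  mad0 <- stats::median(abs(all_sig - med))
  if (mad0 == 0) {
    stopf("read '%s': degenerate signal (median absolute deviation is zero)",
          read$read_id)
  }
  read$signals <- lapply(read$signals, function(s) (s - med) / mad0)
  read
}
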