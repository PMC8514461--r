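Package: squigglemeth
Title: Plant 5mC Methylation Calling from Event-Aligned Nanopore Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects 5-methylcytosine (5mC) in CpG, CHG and CHH sequence
    contexts from event-aligned Nanopore current signals. Implements
    median/MAD signal normalization, per-site sequence and signal feature
    extraction, a two-branch bidirectional LSTM classifier trained with
    adaptive-moment gradient descent, k-mer-aware balancing of negative
    training samples, iterative cross-prediction denoising of mislabelled
    positives, per-read calling, per-site methylation frequency
    aggregation, evaluation against bisulfite cytosine reports, and
    differential-methylation analysis of near-identical repeat pairs.
    Includes a synthetic data generator emulating event-aligned reads with
    state-dependent per-k-mer signal distributions for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
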