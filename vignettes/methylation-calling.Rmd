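---
title: "Calling plant 5mC from Nanopore signals: model, training-set curation, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling plant 5mC from Nanopore signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In plants, cytosine methylation (5mC) occurs in three sequence contexts —
CpG, CHG and CHH (H = A, C or T) — with distinct regulatory roles. Nanopore
sequencing reads native DNA, so methylation leaves its trace directly in the
ionic current: a modified base perturbs the current of the k-mers passing
through the pore. `squigglemeth` classifies, for every cytosine in every
read, whether the underlying molecule was methylated, then aggregates
read-level calls into per-site methylation frequencies and compares them
with bisulfite sequencing.

The package operates on *event-aligned* reads: reads whose raw current
samples have already been assigned to individual reference bases by
re-squiggling. Event alignment itself (basecalling, mapping, signal
re-annotation) is out of scope; reads enter through a documented JSON-lines
dialect (`read_event_reads()`), one record per read, with per-base signal
arrays.

## Signal normalization

Raw currents differ between pores and over time, so each read is normalized
independently: every value x becomes (x − median) / MAD, with the median and
the median absolute deviation taken over all signal values of the whole read
(`normalize_read()`). No consistency constant (1.4826) is applied to the MAD
— the scale is arbitrary as long as training and calling agree — and no
outlier clipping is performed. Normalization is idempotent and invariant
under positive affine distortions of the raw current, which is exactly the
class of per-read nuisance the pore introduces; both properties are
property-tested. A read with zero MAD (constant signal) is rejected as
degenerate rather than silently producing NaNs.

## Features

For a cytosine centered in a k-mer (k = 13 by default), two matrices are
built per read (`extract_site_samples()`):

* **sequence features** (k × 4): per k-mer position, the base identity
  (coded A = 0, C = 1, G = 2, T = 3), the mean and the population standard
  deviation of the base's normalized signals, and the signal count (the
  dwell time in samples);
* **signal features** (k × m, m = 16 by default): m signal values per base.
  Bases with more than m signals are subsampled at evenly spaced indices
  floor(i·n/m) — deterministic, preserving the temporal span, unlike random
  subsampling which would break reproducibility — and bases with fewer are
  zero-padded on the right.

Rows always run 5'→3' on the cytosine's own strand: minus-strand sites use
the reverse-complemented k-mer and base-reversed rows, so the model sees a
single orientation convention. Sites whose k-mer window is not fully covered
by a read are skipped and counted, not fatal. Population (divisor-n)
standard deviation is used consistently; the choice is arbitrary but must
match between training and calling, so it is fixed once.

## The classifier

The model (`build_model()`) is a two-branch bidirectional LSTM:

* the sequence branch embeds the base code (dimension 4) and appends the
  numeric columns (mean, sd, log1p(count) — the count is log-compressed at
  the model boundary so dwell outliers do not dominate the input scale),
  runs a BiLSTM over the k positions, then a per-position fully connected
  ReLU layer;
* the signal branch runs a BiLSTM over the k rows of the signal matrix,
  then its own fully connected layer;
* the per-position outputs are concatenated and passed through a stack of
  bidirectional LSTM layers (3 × 256 hidden units by default, following the
  published architecture); the final hidden states of both directions feed
  two fully connected layers and a softmax that returns
  (P_unmethylated, P_methylated), summing to one.

`mode = "signal_only"` or `"sequence_only"` drops the other branch; the
signal-only variant is used for training-set denoising (below), where it
performed best in the original work.

Training (`train_model()`) minimizes cross-entropy with Adam at learning
rate 0.001 (default). Dropout is applied to LSTM outputs and the penultimate
fully connected layer during training only. With a validation set (99:1
split by default, `split_train_valid()`), the best-scoring parameters are
retained and training stops early as soon as an epoch's validation accuracy
falls below the best seen — accuracy is used as the selection metric, a
choice this package fixes where the original description says only "best
performance". All randomness (initialization, shuffling, dropout) derives
from the configuration seed, so training is bit-reproducible on one device.

The whole network, including backpropagation through the bidirectional
recurrence, is implemented in R on BLAS matrix operations; the analytic
gradients are validated against finite differences in the test suite. The
branch hidden width, dropout rate, embedding dimension and batch size are
not fixed by the published description and are exposed as configuration
(defaults: 256, 0.5, 4, 512).

## Training-set curation

Training labels come from bisulfite sequencing
(`select_high_confidence_sites()`): a cytosine with coverage ≥ 5 and
frequency ≥ 0.9 is high-confidence methylated; coverage ≥ 5 and frequency 0
in *every* replicate is high-confidence unmethylated. Methylated sets are
combined across replicates by intersection for CpG and by union for CHG and
CHH, whose methylated sites are scarcer. Every read covering such a site
contributes one training sample with the site's label
(`label_from_high_confidence()`) — which is precisely why label noise
arises: at a site with frequency 0.9, one read in ten carries an
unmethylated molecule yet is labelled methylated.

Two curation steps follow:

* **k-mer balancing** (`balance_negative_samples()`): for every k-mer
  present in both classes, at most as many negatives as positives are kept;
  any deficit is filled from k-mers private to the negative pool. This
  prevents the model from using k-mer composition as a proxy for the label.
* **iterative denoising** (`denoise_samples()`): up to I = 10 iterations,
  each performing R = 3 rounds of two-fold cross-prediction (fresh model per
  fold so scores never come from a model that saw the sample), accumulating
  each sample's mean methylation probability; positives with mean score
  below 0.5 are removed, negatives are rebalanced against the surviving
  positives by drawing from the original negative pool, and the loop stops
  once an iteration retains at least 99% of its positives. The positive set
  shrinks monotonically; removals accumulate across iterations.

`subsample_training_set()` caps the training set (default 2 × 10⁷, half
positive and half negative); when one class is exhausted the other remains
capped at half the budget, preserving balance.

## Calling, aggregation, evaluation

A site in a read is called methylated iff P_m > P_um — a tie counts as
unmethylated, reading the rule strictly (`call_reads()`).
`aggregate_frequencies()` computes per-site coverage, methylated-read count
and frequency, per strand (no CpG strand merging, matching how both strands
are evaluated independently). `bin_sites()` classifies covered sites (≥ 5
reads) as lowly (≤ 0.3), intermediately, or highly (≥ 0.7) methylated, with
inclusive boundaries.

`compare_frequencies()` inner-joins Nanopore and bisulfite tables on
(chrom, pos, strand), filters both sides to coverage ≥ 5 (the threshold is a
parameter; low-coverage bisulfite data may warrant 10), and reports Pearson
r, r², Spearman ρ and RMSE, averaged across replicates when several are
given. `read_level_metrics()` follows the read-level benchmarking protocol:
truth labels are taken only from fully methylated / fully unmethylated
sites, classes are subsampled to equal size (default 100,000, repeated 5
times), and accuracy, sensitivity, specificity and AUC are reported with
across-repeat dispersion. AUC uses the Wilcoxon/midrank formulation,
equivalent to the trapezoidal area; ties get midranks.

## Repeat pairs

Near-identical duplicated regions are read from a self-alignment coordinate
table (`read_repeat_coords()`). Pairs with length ≥ 100 bp and identity
≥ 0.99 are kept — the thresholds are read inclusively where the source
material is internally inconsistent about strictness — and must contain at
least one cytosine. Cytosines are matched by identical offset from each
member's start, strand-flipped for reverse-orientation alignments; the
pairing is gap-free, which at ≥ 99% identity misassigns at most a handful of
offsets and avoids embedding an aligner. A matched cytosine is differential
when its two frequencies differ by ≥ 0.5 (with a 10⁻⁹ epsilon so boundary
differences survive floating point); a pair is differentially methylated for
a class (all cytosines, or each context separately) when ≥ 10% of its
matched cytosines of that class are differential. Classes with no matched
cytosine get an NA flag rather than a silent FALSE.

## The synthetic generator

`synthetic_config()` + `simulate_dataset()` emulate everything the pipeline
consumes. The signal model: each 5-mer context carries a baseline current
level drawn once from a seeded table (sd 0.5 signal units by default, so
current depends on sequence, not only on state — without this the sequence
branch would be untestable); a methylated cytosine adds `delta` to the
levels of bases within ±2 bp (pore current integrates a k-mer, so the
perturbation is spatially extended); per-signal Gaussian noise has sd
`sigma` (default 0.25, with `delta = 3·sigma`); dwell is 1 + Poisson(7)
signals per base; and each read applies its own affine distortion, which
MAD normalization must remove. Per-site true frequencies are drawn from
per-context mixtures of fully unmethylated, fully methylated and uniform
intermediate sites (defaults CpG 35/45%, CHG 45/35%, CHH 70/10% zero/one
mass — CHH methylation is rare in plants); molecule states are Bernoulli
draws, and bisulfite counts are binomial with a 0.5% conversion-error rate.

What the generator does *not* emulate: realistic pore physics (signal
levels are Gaussian, real k-mer current tables are not), basecalling and
alignment errors, re-squiggle misassignment, coverage biases, or long-range
methylation correlation along molecules. Passing tests therefore show that
the algorithms recover planted structure under the stated signal model, not
that the defaults would reach any particular accuracy on real plant
genomes.

## Desk-scale experiments

Two packaged experiments drive the acceptance checks, at sizes chosen to
run on one CPU in minutes:

* `denoise_experiment()`: a 4,600 bp genome at 30× coverage yields >20,000
  balanced training samples; per-site frequencies are restricted to 0/1 and
  per-5-mer baseline spread is set to zero, realizing the prescribed
  separable two-class condition (per-base class separation exactly 3σ);
  negatives whose neighborhood contains a methylated cytosine of the same
  molecule are excluded, since their signal genuinely carries the
  methylation shift. A known 10–20% of positives are replaced by relabelled
  clean negatives; denoising runs with the signal-only model (hidden width
  32, one merged layer, E = 2 epochs per fold, batch 128, learning rate
  0.01 — at a few thousand updates per fold the default 0.001 underfits),
  R = 3, I ≤ 10. The fraction of injected mislabels removed is the reported
  recovery.
* `pipeline_experiment()`: 3,000 bp at 20× total coverage under the default
  (context-dependent) signal model; training labels from the simulated
  bisulfite table's high-confidence sites; full two-branch model (hidden 48,
  one merged layer, 12 epochs). Reports the Pearson correlation between
  called and true per-site frequencies (coverage ≥ 5) and read-level
  metrics on fully methylated/unmethylated truth sites. With
  `null_model = TRUE` the methylation shift is zero and read-level AUC
  collapses to chance, confirming the pipeline does not manufacture signal.

## Numerical and degenerate-input choices

* Ties in calling (P_m = P_um) are unmethylated; ties in AUC get midranks.
* Odd-sized sets split into ⌊n/2⌋/⌈n/2⌉ halves during cross-prediction.
* A zero-MAD read, an empty signal vector, an empty training set, a
  single-class read-level evaluation, and a correlation over fewer than two
  joined sites are errors, not warnings.
* Zero-coverage bisulfite rows are parsed and retained; filtering is the
  consumer's decision.
* The forget-gate bias is initialized to 1 (standard practice for LSTM
  gradient flow); other weights are uniform in ±1/√hidden.

## Known limitations

The pure-R network trains comfortably at desk scale (10³–10⁵ samples,
hidden widths ≤ 64) but is not suited to genome-scale training; the
published task used GPU-scale data (hundreds of millions of samples) that
this package does not attempt. The gap-free repeat-pair matching slightly
undercounts matched cytosines in pairs containing indels. FAST5/HDF5
ingestion is deliberately absent — event-aligned reads arrive through the
JSON-lines dialect.

A note on the null control: with context-dependent baseline levels and the
full model, a zero-shift run still yields above-chance read-level AUC,
because per-site methylation frequency correlates with sequence context and
a kilobase-scale genome lets the sequence branch memorize site identity.
That is genuine structure in the data, not methylation signal — so the
packaged null control removes it (context-independent baselines, balanced
class frequencies, signal-only model) to test exactly the claim that
matters: without a current shift, the signal pathway detects nothing.
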