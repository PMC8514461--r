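make_report <- function(df) {
  n <- length(df$pos)
  data.frame(chrom = rep("c1", n), pos = df$pos, strand = rep("+", n),
             count_methylated = df$m, count_unmethylated = df$u,
             context = df$ctx, trinucleotide = rep("CGA", n),
             stringsAsFactors = FALSE)
}

test_that("high-confidence selection applies coverage and frequency rules", {
  rep1 <- make_report(data.frame(pos = 1:4, m = c(10, 4, 0, 9), u = c(0, 0, 10, 1),
                                 ctx = "CHH"))
  hc <- select_high_confidence_sites(rep1, "CHH")
  # pos 1: cov 10 freq 1 -> methylated; pos 2: cov 4 fails coverage;
  # pos 3: freq 0 -> unmethylated; pos 4: freq 0.9 -> methylated
  expect_setequal(hc$methylated$pos, c(1L, 4L))
  expect_equal(hc$unmethylated$pos, 3L)

  empty <- make_report(data.frame(pos = integer(), m = integer(), u = integer(),
                                  ctx = character()))
  hc0 <- select_high_confidence_sites(empty, "CpG")
  expect_equal(nrow(hc0$methylated), 0L)
})

test_that("replicate combination: intersection for CpG, union for CHH; sets match brute force", {
  set.seed(7)
  n <- 400
  reps <- lapply(1:3, function(i) {
    cov <- rpois(n, 8)
    f <- sample(c(0, 0.5, 0.92, 1), n, TRUE)
    make_report(data.frame(pos = 1:n, m = round(cov * f), u = cov - round(cov * f),
                           ctx = "CpG"))
  })
  # brute-force oracle by explicit set algebra
  per <- lapply(reps, function(r) {
    cov <- r$count_methylated + r$count_unmethylated
    f <- ifelse(cov > 0, r$count_methylated / cov, NA)
    list(m = r$pos[cov >= 5 & !is.na(f) & f >= 0.9],
         u = r$pos[cov >= 5 & !is.na(f) & f == 0])
  })
  want_m_int <- Reduce(intersect, lapply(per, `[[`, "m"))
  want_u <- setdiff(Reduce(intersect, lapply(per, `[[`, "u")), want_m_int)
  hc_cpg <- select_high_confidence_sites(reps, "CpG")
  expect_setequal(hc_cpg$methylated$pos, want_m_int)
  expect_setequal(hc_cpg$unmethylated$pos, want_u)

  reps_chh <- lapply(reps, function(r) { r$context <- "CHH"; r })
  want_m_uni <- Reduce(union, lapply(per, `[[`, "m"))
  hc_chh <- select_high_confidence_sites(reps_chh, "CHH")
  expect_setequal(hc_chh$methylated$pos, want_m_uni)
  expect_length(intersect(hc_chh$methylated$pos, hc_chh$unmethylated$pos), 0)
})

test_that("negative balancing reproduces the worked hand-trace", {
  pos <- make_kmer_samples(rep(c("A", "B"), c(3, 2)), rep(1L, 5))
  neg <- make_kmer_samples(rep(c("A", "B", "C"), c(10, 1, 4)), rep(0L, 15))
  bal <- balance_negative_samples(pos, neg, seed = 5)
  km <- substr(bal$info$kmer, 1, 1)
  expect_equal(as.vector(table(km)[c("A", "B", "C")]), c(3L, 1L, 1L))
  expect_equal(n_samples(bal), 5L)

  # negatives identical to positives -> everything kept
  neg2 <- make_kmer_samples(rep(c("A", "B"), c(3, 2)), rep(0L, 5))
  expect_equal(n_samples(balance_negative_samples(pos, neg2, seed = 1)), 5L)

  # empty positive set -> empty output
  empty_pos <- make_kmer_samples(character(), integer())
  expect_equal(n_samples(balance_negative_samples(empty_pos, neg, seed = 1)), 0L)
})

test_that("per-kmer negative counts never exceed positive counts (property)", {
  set.seed(11)
  kmers <- LETTERS[1:6]
  for (i in 1:1000) {
    kp <- sample(kmers, sample.int(30, 1), replace = TRUE)
    kn <- sample(kmers, sample.int(40, 1), replace = TRUE)
    idx <- squigglemeth:::balance_negative_indices(kp, kn)
    tk <- table(kn[idx])
    tp <- table(kp)
    common <- intersect(names(tk), names(tp))
    expect_true(all(tk[common] <= tp[common]))
    expect_true(length(idx) <= length(kp) || length(idx) <= length(kn))
  }
})

test_that("subsampling caps both classes at half the budget", {
  pos <- make_kmer_samples(rep("A", 100), rep(1L, 100))
  neg <- make_kmer_samples(rep("B", 100), rep(0L, 100))
  out <- subsample_training_set(pos, neg, max_samples = 50, seed = 3)
  expect_equal(as.vector(table(out$info$label)), c(25L, 25L))

  pos10 <- make_kmer_samples(rep("A", 10), rep(1L, 10))
  out2 <- subsample_training_set(pos10, neg, max_samples = 50, seed = 3)
  # positives exhausted at 10; negatives still capped at half = 25
  expect_equal(sum(out2$info$label == 1), 10L)
  expect_equal(sum(out2$info$label == 0), 25L)

  out3 <- subsample_training_set(pos, neg, max_samples = 50, seed = 3)
  expect_equal(out$info$sample_id, out3$info$sample_id)  # seed-stable
})

test_that("denoising removes only positives and respects the retention stop", {
  toy <- make_toy_samples(400, delta = 2, sigma = 0.2, seed = 13)
  # oracle trainer: scores by the mean signal level, no model involved
  mean_trainer <- function(train, score, seed) {
    as.numeric(rowMeans(score$signal) > 1)
  }
  dn <- denoise_samples(toy, mean_trainer, iterations = 5L, rounds = 2L, seed = 17)
  # clean separable data: stops in iteration 1 with every positive retained
  expect_equal(nrow(dn$history), 1L)
  expect_gte(dn$history$retained[1], 0.99)
  expect_length(dn$removed_ids, 0L)

  # corrupt 15% of positives; the oracle trainer must expose them
  inj <- inject_mislabels(toy, 0.15, seed = 19)
  dn2 <- denoise_samples(inj$samples, mean_trainer, iterations = 5L,
                         rounds = 2L, seed = 17)
  expect_true(all(dn2$removed_ids %in%
                    inj$samples$info$sample_id[inj$samples$info$label == 1L]))
  expect_setequal(dn2$removed_ids, inj$injected_ids)
  # negatives in the output are a subset of input negatives
  in_neg <- inj$samples$info$sample_id[inj$samples$info$label == 0L]
  out_neg <- dn2$samples$info$sample_id[dn2$samples$info$label == 0L]
  expect_true(all(out_neg %in% in_neg))
  # positive count shrinks weakly across iterations
  expect_true(all(diff(dn2$history$n_pos_after) <= 0))
})
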