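test_that("reference generation is seed-deterministic with controlled GC", {
  cfg <- synthetic_config(genome_length = 100000L, gc_fraction = 0.5, seed = 71L)
  ref1 <- generate_reference(cfg)
  ref2 <- generate_reference(cfg)
  expect_identical(ref1, ref2)
  gc <- sum(strsplit(ref1[[1]], "")[[1]] %in% c("G", "C"))
  # binomial 3-sigma bound around 0.5 * 1e5
  expect_lt(abs(gc - 50000), 3 * sqrt(100000 * 0.25))

  cfg2 <- synthetic_config(genome_length = 2000L, n_contigs = 2L, seed = 3L)
  expect_length(generate_reference(cfg2), 2L)
})

test_that("truth frequencies drive molecule states", {
  cfg <- synthetic_config(genome_length = 1500L, coverage = 100, seed = 73L,
                          read_length = 500L)
  ref <- generate_reference(cfg)
  truth <- generate_truth(ref, cfg)
  # site context assignment agrees with the motif scan
  sc <- scan_cytosines(ref, 5L)
  expect_equal(truth$sites[, c("chrom", "pos", "strand", "context")], sc[, 1:4])
  # frequency-0 sites have exclusively unmethylated molecules
  key <- paste(truth$states$chrom, truth$states$pos, truth$states$strand)
  tkey <- paste(truth$sites$chrom, truth$sites$pos, truth$sites$strand)
  f <- truth$sites$frequency[match(key, tkey)]
  expect_true(all(truth$states$state[f == 0] == 0L))
  expect_true(all(truth$states$state[f == 1] == 1L))
  # empirical molecule frequency tracks the true frequency within binomial error
  agg <- tapply(truth$states$state, key, mean)
  n_mol <- tapply(truth$states$state, key, length)
  ftrue <- truth$sites$frequency[match(names(agg), tkey)]
  deep <- n_mol >= 40
  err <- abs(agg[deep] - ftrue[deep])
  bound <- 4 * sqrt(pmax(ftrue[deep] * (1 - ftrue[deep]), 0.01) / n_mol[deep])
  expect_gt(mean(err <= bound), 0.95)
})

test_that("event reads are seed-deterministic and signal shifts follow delta", {
  cfg <- synthetic_config(genome_length = 800L, coverage = 6, seed = 77L,
                          read_length = 400L)
  ref <- generate_reference(cfg)
  truth <- generate_truth(ref, cfg)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_event_reads(generate_event_reads(ref, truth, cfg), p1)
  write_event_reads(generate_event_reads(ref, truth, cfg), p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical

  # delta = 0 makes the two classes indistinguishable at the signal level
  cfg0 <- synthetic_config(genome_length = 2000L, coverage = 20, seed = 79L,
                           kmer_level_sd = 0, delta = 0,
                           freq_dist = list(CpG = c(p0 = 0.5, p1 = 0.5),
                                            CHG = c(p0 = 0.5, p1 = 0.5),
                                            CHH = c(p0 = 0.5, p1 = 0.5)))
  ref0 <- generate_reference(cfg0)
  truth0 <- generate_truth(ref0, cfg0)
  reads0 <- lapply(generate_event_reads(ref0, truth0, cfg0), normalize_read)
  ss0 <- label_samples(extract_site_samples(reads0, scan_cytosines(ref0, 13L),
                                            feature_config()), truth0$states)
  keep <- !is.na(ss0$info$label)
  score <- rowMeans(ss0$seq_mean[keep, 5:9])  # center window mean level
  expect_lt(abs(auc_score(score, ss0$info$label[keep]) - 0.5), 0.05)

  # delta = 3 sigma separates them strongly
  cfg3 <- cfg0; cfg3$delta <- 3 * cfg3$sigma; cfg3$seed <- 81L
  ref3 <- generate_reference(cfg3)
  truth3 <- generate_truth(ref3, cfg3)
  reads3 <- lapply(generate_event_reads(ref3, truth3, cfg3), normalize_read)
  ss3 <- label_samples(extract_site_samples(reads3, scan_cytosines(ref3, 13L),
                                            feature_config()), truth3$states)
  keep3 <- !is.na(ss3$info$label)
  score3 <- rowMeans(ss3$seq_mean[keep3, 5:9])
  expect_gt(auc_score(score3, ss3$info$label[keep3]), 0.9)
})

test_that("bisulfite tables reflect the truth within binomial error", {
  cfg <- synthetic_config(genome_length = 3000L, bs_coverage = 100,
                          conversion_error = 0, seed = 83L)
  ref <- generate_reference(cfg)
  truth <- generate_truth(ref, cfg)
  bs <- generate_bisulfite_table(truth, ref, cfg)
  expect_equal(nrow(bs), nrow(truth$sites))
  cov <- bs$count_methylated + bs$count_unmethylated
  # frequency-1 sites with zero conversion error are fully methylated
  f1 <- truth$sites$frequency == 1 & cov > 0
  expect_true(all(bs$count_unmethylated[f1] == 0L))
  obs <- ifelse(cov > 0, bs$count_methylated / cov, NA)
  deep <- cov >= 50
  err <- abs(obs[deep] - truth$sites$frequency[deep])
  bound <- 4 * sqrt(pmax(truth$sites$frequency[deep] *
                           (1 - truth$sites$frequency[deep]), 0.01) / cov[deep])
  expect_gt(mean(err <= bound), 0.95)
  # zero-coverage rows are retained
  cfg0 <- cfg; cfg0$bs_coverage <- 0.5
  bs0 <- generate_bisulfite_table(truth, ref, cfg0)
  expect_true(any(bs0$count_methylated + bs0$count_unmethylated == 0L))
})

test_that("mislabel injection replaces the stated fraction of positives", {
  toy <- make_toy_samples(1000, seed = 87)  # 500 positives
  inj0 <- inject_mislabels(toy, 0, seed = 1)
  expect_identical(inj0$samples, toy)
  inj <- inject_mislabels(toy, 0.1, seed = 1)
  expect_length(inj$injected_ids, 50L)
  expect_equal(sum(inj$samples$info$label == 1L), 500L)  # positive count unchanged
  genuine <- toy$info$sample_id[toy$info$label == 1L]
  expect_length(intersect(inj$injected_ids, genuine), 0L)
  expect_true(all(inj$injected_ids %in% inj$samples$info$sample_id))
})

test_that("simulate_dataset writes a complete, reloadable fixture directory", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(genome_length = 400L, coverage = 4, read_length = 200L,
                          seed = 89L)
  paths <- simulate_dataset(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  ref <- read_fasta(paths$reference)
  expect_equal(nchar(ref[[1]]), 400L)
  reads <- read_event_reads(paths$events)
  expect_gt(length(reads), 0L)
  bs <- read_bisulfite_report(paths$bisulfite)
  expect_gt(nrow(bs), 0L)
})
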