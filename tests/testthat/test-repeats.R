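mk_pair <- function(chrom_a = "c1", start_a, end_a, chrom_b = "c1", start_b,
                    end_b, orient = "+", identity = 1) {
  data.frame(chrom_a = chrom_a, start_a = start_a, end_a = end_a,
             chrom_b = chrom_b, start_b = start_b, end_b = end_b,
             orient = orient, length = end_a - start_a, identity = identity,
             stringsAsFactors = FALSE)
}

freq_table <- function(chrom, pos, strand, f, cov = 10L, ctx = "CpG") {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = ctx,
             coverage = cov, n_meth = round(f * cov), frequency = f,
             stringsAsFactors = FALSE)
}

test_that("pair filtering applies inclusive length/identity thresholds", {
  pairs <- rbind(mk_pair(start_a = 0, end_a = 100, start_b = 500, end_b = 600,
                         identity = 0.99),
                 mk_pair(start_a = 0, end_a = 99, start_b = 500, end_b = 599,
                         identity = 1),
                 mk_pair(start_a = 0, end_a = 150, start_b = 500, end_b = 650,
                         identity = 0.98))
  kept <- filter_pairs(pairs)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$end_a, 100)

  # cytosine-content filter: an A/T-only pair is dropped when reference given
  ref <- c(c1 = paste0(strrep("AT", 100), strrep("CG", 100), strrep("AT", 150)))
  p_at <- mk_pair(start_a = 0, end_a = 120, start_b = 400, end_b = 520)
  expect_equal(nrow(filter_pairs(p_at, reference = ref)), 0L)
  p_cg <- mk_pair(start_a = 150, end_a = 280, start_b = 200, end_b = 330)
  expect_equal(nrow(filter_pairs(p_cg, reference = ref)), 1L)
})

test_that("identical members with identical frequencies give zero differential", {
  ref <- c(c1 = random_dna(700, seed = 61))
  # same frequencies at the same offsets in both members
  pos_a <- 100:299; pos_b <- 400:599
  set.seed(62)
  f <- runif(200)
  fq <- rbind(freq_table("c1", pos_a, "+", f), freq_table("c1", pos_b, "+", f))
  pair <- mk_pair(start_a = 100, end_a = 300, start_b = 400, end_b = 600)
  prof <- classify_pair(match_cytosines(pair, fq, ref))
  expect_equal(nrow(prof$matched), 200L)
  expect_equal(prof$counts$differential[prof$counts$class == "allC"], 0L)
  expect_false(prof$counts$flag[prof$counts$class == "allC"])
})

test_that("offsets lacking coverage in one member are excluded; count matches brute force", {
  ref <- c(c1 = random_dna(700, seed = 63))
  set.seed(64)
  pos_a <- sample(100:299, 120)
  pos_b <- sample(400:599, 130)
  fq <- rbind(freq_table("c1", pos_a, "+", runif(120)),
              freq_table("c1", pos_b, "+", runif(130)))
  pair <- mk_pair(start_a = 100, end_a = 300, start_b = 400, end_b = 600)
  prof <- match_cytosines(pair, fq, ref)
  want <- length(intersect(pos_a - 100, pos_b - 400))  # brute-force offset intersection
  expect_equal(nrow(prof$matched), want)

  # coverage below threshold excludes the offset
  fq2 <- fq
  fq2$coverage[1] <- 4L
  prof2 <- match_cytosines(pair, fq2, ref)
  expect_lte(nrow(prof2$matched), want)
})

test_that("classification threshold: 10% differential at |delta| >= 0.5", {
  ref <- c(c1 = random_dna(500, seed = 65))
  pair <- mk_pair(start_a = 0, end_a = 100, start_b = 200, end_b = 300)
  f_a <- rep(0.2, 10); f_b <- f_a
  f_b[1] <- 0.7  # exactly |delta| = 0.5 at one of 10 sites -> 10%
  fq <- rbind(freq_table("c1", 0:9, "+", f_a), freq_table("c1", 200:209, "+", f_b))
  prof <- classify_pair(match_cytosines(pair, fq, ref))
  expect_true(prof$counts$flag[prof$counts$class == "allC"])

  f_b2 <- f_a + 0.49  # below the difference threshold everywhere
  fq2 <- rbind(freq_table("c1", 0:9, "+", f_a), freq_table("c1", 200:209, "+", f_b2))
  prof2 <- classify_pair(match_cytosines(pair, fq2, ref))
  expect_false(prof2$counts$flag[prof2$counts$class == "allC"])
})

test_that("flags equal a brute-force recount and are symmetric in member order", {
  ref <- c(c1 = random_dna(900, seed = 66))
  set.seed(67)
  for (i in 1:10) {
    pos_a <- sort(sample(0:199, 60)); f_a <- runif(60)
    pos_b <- pos_a + 500; f_b <- runif(60)
    ctx <- sample(c("CpG", "CHG", "CHH"), 60, TRUE)
    fq <- rbind(freq_table("c1", pos_a, "+", f_a, ctx = ctx),
                freq_table("c1", pos_b, "+", f_b, ctx = ctx))
    pair <- mk_pair(start_a = 0, end_a = 200, start_b = 500, end_b = 700)
    prof <- classify_pair(match_cytosines(pair, fq, ref))
    # brute-force recount
    diff <- abs(f_a - f_b) >= 0.5
    expect_equal(prof$counts$differential[prof$counts$class == "allC"], sum(diff))
    for (cl in c("CpG", "CHG", "CHH")) {
      nd <- sum(diff[ctx == cl]); nm <- sum(ctx == cl)
      row <- prof$counts[prof$counts$class == cl, ]
      expect_equal(row$differential, nd)
      if (nm > 0) expect_equal(row$flag, nd / nm >= 0.10) else expect_true(is.na(row$flag))
    }
    # allC differential = sum of per-context differentials
    expect_equal(prof$counts$differential[1], sum(prof$counts$differential[2:4]))
    # symmetry under member swap
    pair_sw <- mk_pair(start_a = 500, end_a = 700, start_b = 0, end_b = 200)
    prof_sw <- classify_pair(match_cytosines(pair_sw, fq, ref))
    expect_equal(prof_sw$counts$flag, prof$counts$flag)
  }
})
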