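test_that("e-locus enumeration slides a 4-CpG window within the span limit", {
  cpgs <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40, 200))
  el <- enumerate_eloci(cpgs, max_span = 100)
  expect_equal(el$elocus_id, "chr1:10-40")
  expect_equal(el$span, 30)

  # exactly 4 CpGs -> one e-locus
  expect_equal(nrow(enumerate_eloci(data.frame(chrom = "chr2", pos = c(1, 5, 9, 13)))), 1L)

  # 6 CpGs within span -> 3 overlapping windows
  el6 <- enumerate_eloci(data.frame(chrom = "chr1", pos = seq(0, 50, by = 10)))
  expect_equal(el6$pos1, c(0, 10, 20))
  expect_equal(el6$pos4, c(30, 40, 50))

  expect_error(enumerate_eloci(data.frame(chrom = "chr1", pos = c(20, 10, 30, 40))),
               "sorted")
})

test_that("SNP-site CpGs are removed before enumeration", {
  cpgs <- data.frame(chrom = "chr1", pos = c(100, 200))
  expect_equal(remove_snp_cpgs(cpgs, data.frame(chrom = character(),
                                                start = integer(), end = integer())),
               cpgs)
  snps <- data.frame(chrom = "chr1", start = 100, end = 101)
  expect_equal(remove_snp_cpgs(cpgs, snps)$pos, 200)
  # SNP at 101 does not hit CpG at 100 (half-open)
  expect_equal(remove_snp_cpgs(cpgs, data.frame(chrom = "chr1", start = 101, end = 102))$pos,
               c(100, 200))
})

test_that("pattern counting requires complete coverage of all four CpGs", {
  eloci <- enumerate_eloci(data.frame(chrom = "chr1", pos = c(10, 20, 30, 40)))
  mk_read <- function(id, calls, npos = 4) {
    data.frame(read_id = id, sample_id = "S1", chrom = "chr1",
               pos = c(10, 20, 30, 40)[seq_len(npos)], call = calls[seq_len(npos)])
  }
  # 5 fully methylated reads
  rc <- do.call(rbind, lapply(1:5, function(i) mk_read(paste0("r", i), c(1, 1, 1, 1))))
  cnt <- count_patterns(rc, eloci)
  expect_equal(cnt$n15, 5L)
  expect_equal(cnt$depth, 5L)
  expect_equal(sum(as.matrix(cnt[paste0("n", 0:14)])), 0)

  # mixed patterns 1111, 0000, 0000
  rc2 <- rbind(mk_read("a", c(1, 1, 1, 1)), mk_read("b", c(0, 0, 0, 0)),
               mk_read("c", c(0, 0, 0, 0)))
  cnt2 <- count_patterns(rc2, eloci)
  expect_equal(cnt2$n15, 1L)
  expect_equal(cnt2$n0, 2L)

  # a read covering only 3 CpGs contributes nothing
  rc3 <- mk_read("partial", c(1, 1, 1), npos = 3)
  expect_equal(nrow(count_patterns(rc3, eloci)), 0L)
})

test_that("round trip: pattern counts -> reads -> pattern counts", {
  cfg <- simulation_config(seed = 7, n_patients = 2, regions_per_patient = 2,
                           n_normal = 2, n_eloci = 10)
  sim <- simulate_epiallele_data(cfg)
  rc <- pattern_counts_to_reads(sim$counts, sim$eloci)
  back <- count_patterns(rc, sim$eloci)
  o1 <- sim$counts[order(sim$counts$elocus_id, sim$counts$sample_id), ]
  o2 <- back[order(back$elocus_id, back$sample_id), ]
  expect_equal(unname(as.matrix(o2[paste0("n", 0:15)])),
               unname(as.matrix(o1[paste0("n", 0:15)])))
})

test_that("epipolymorphism matches its closed form and boundary values", {
  single <- c(7, rep(0, 15))
  expect_equal(epipolymorphism(single), 0)
  expect_equal(epipolymorphism(rep(1, 16)), 0.9375)
  # 8x 0000, 4x 1000, 2x 1100, 2x 1110
  v <- rep(0, 16); v[1] <- 8; v[9] <- 4; v[13] <- 2; v[15] <- 2
  expect_equal(epipolymorphism(v), 0.65625)
  expect_true(is.na(epipolymorphism(rep(0, 16))))
})

test_that("epipolymorphism equals the Monte-Carlo pair-difference probability", {
  set.seed(11)
  for (i in 1:25) {
    v <- random_count_vector()
    p <- v / sum(v)
    expect_lt(abs(epipolymorphism(v) - mc_pair_epipolymorphism(p)), 0.005)
  }
})

test_that("duplicating a majority pattern never increases epipolymorphism", {
  set.seed(12)
  for (i in 1:50) {
    v <- random_count_vector()
    maj <- which.max(v)
    v2 <- v; v2[maj] <- v2[maj] + 5
    expect_lte(epipolymorphism(v2), epipolymorphism(v) + 1e-12)
  }
})

test_that("average methylation matches per-CpG column oracle and boundaries", {
  allm <- rep(0, 16); allm[16] <- 9
  expect_equal(avg_methylation(allm), 1)
  half <- rep(0, 16); half[1] <- 5; half[16] <- 5
  expect_equal(avg_methylation(half), 0.5)
  v <- rep(0, 16); v[9] <- 4; v[13] <- 4 # 1000 x4, 1100 x4
  expect_equal(avg_methylation(v), 0.375)
  set.seed(13)
  for (i in 1:50) {
    v <- random_count_vector()
    expect_equal(avg_methylation(v), column_avg_methylation(v), tolerance = 1e-12)
  }
  expect_true(is.na(avg_methylation(rep(0, 16))))
})

test_that("reversing CpG order relabels patterns but preserves both statistics", {
  rev_code <- vapply(0:15, function(p) {
    bits <- as.integer(bitwAnd(p, c(8L, 4L, 2L, 1L)) > 0L)
    sum(rev(bits) * c(8L, 4L, 2L, 1L))
  }, integer(1))
  set.seed(14)
  for (i in 1:25) {
    v <- random_count_vector()
    vr <- numeric(16); vr[rev_code + 1L] <- v
    expect_equal(epipolymorphism(vr), epipolymorphism(v))
    expect_equal(avg_methylation(vr), avg_methylation(v))
  }
})

test_that("coverage filter applies the >=75%-of-samples-at->=10x rule inclusively", {
  prof <- utils::read.table(extdata("toy_profiles.tsv"), header = TRUE, sep = "\t")
  kept <- filter_eloci(prof, samples = paste0("S", 1:8))
  # L1: 6/8 = 0.75 exactly -> retained; L2: 5/8 -> dropped; L3: 8/8 -> retained
  expect_setequal(kept, c("L1", "L3"))
  expect_error(filter_eloci(prof, samples = character()), "empty")
})
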