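test_that("top-variance selection keeps ceiling(fraction * m) with deterministic ties", {
  beta <- as.matrix(utils::read.table(extdata("toy_beta.tsv"), header = TRUE,
                                      row.names = 1, sep = "\t"))
  top1 <- select_top_variance(beta, 0.10, tumour_samples = c("T1", "T2", "T3"))
  # f01 and f02 tie for the highest variance; lower coordinate wins
  expect_equal(rownames(top1), "f01")
  top2 <- select_top_variance(beta, 0.20, tumour_samples = c("T1", "T2", "T3"))
  expect_equal(rownames(top2), c("f01", "f02"))
  low <- select_top_variance(beta, 0.10, direction = "lowest",
                             tumour_samples = c("T1", "T2", "T3"))
  expect_equal(rownames(low), "f04") # zero-variance block, first coordinate
  expect_error(select_top_variance(beta[, 1, drop = FALSE], 0.1), ">= 2")
})

test_that("APITH is the mean over all sample pairs and order invariant", {
  # two identical samples -> 0
  m <- matrix(c(0.2, 0.4, 0.2, 0.4), 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(apith(m)$apith, 0)
  # n = 2 equals the single pairwise distance
  m2 <- matrix(c(0, 0, 1, 1), 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(apith(m2)$apith, 1)
  expect_equal(apith(m2, metric = "euclidean")$apith, sqrt(2))
  # 3 points on a line at 0, 1, 3 (one feature): pairwise 1, 2, 3 -> mean 2
  m3 <- matrix(c(0, 1, 3), 1)
  expect_equal(apith(m3)$apith, 2)
  # sample order invariance
  set.seed(51)
  m4 <- matrix(runif(40), 8)
  expect_equal(apith(m4)$apith, apith(m4[, sample(5)])$apith)
  # n < 2 -> NA
  expect_true(is.na(apith(matrix(1, 2, 1))$apith))
})

test_that("APITH expectation is stable across subsample sizes (exchangeable pool)", {
  set.seed(52)
  pool <- matrix(runif(8 * 20), 20)
  mean_over_subsets <- function(size) {
    mean(utils::combn(8, size, function(ix) apith(pool[, ix])$apith))
  }
  expect_equal(mean_over_subsets(3), mean_over_subsets(5), tolerance = 1e-12)
})

test_that("PCAR homogeneity uses a strict 30% relative-difference bound", {
  ages <- utils::read.table(extdata("toy_ages.tsv"), header = TRUE, sep = "\t")
  ps <- pcar_summary(ages)
  expect_equal(ps$samples$pcar[ps$samples$sample_id == "PA_T2"], 1.3)
  pa <- ps$patients[ps$patients$patient_id == "PA", ]
  pb <- ps$patients[ps$patients$patient_id == "PB", ]
  pc <- ps$patients[ps$patients$patient_id == "PC", ]
  expect_equal(pa$max_pcar_diff, 0.3)
  expect_false(pa$homogeneous)    # exactly 30% fails the strict < bound
  expect_equal(pb$max_pcar_diff, 0.25)
  expect_true(pb$homogeneous)
  expect_true(pc$homogeneous)     # single sample, by convention
  expect_equal(pc$n_samples, 1L)
  # normal sample excluded from the per-patient tumour summary
  expect_equal(pa$n_samples, 2L)
  expect_error(pcar_summary(transform(ages, chrono_age = 0)), "> 0")
})

test_that("methylation distance matrices behave for all metrics", {
  b <- cbind(s1 = c(0, 0, 1, rep(0.5, 9)), s2 = c(1, 0, 1, rep(0.5, 9)))
  expect_equal(methylation_distance_matrix(b)["s1", "s2"], 1)
  expect_equal(methylation_distance_matrix(b, "manhattan")["s1", "s2"], 1)
  # identical columns -> 0
  bb <- cbind(a = runif(12), b = 0)
  bb[, "b"] <- bb[, "a"]
  expect_equal(methylation_distance_matrix(bb)["a", "b"], 0)
  # perfectly anti-correlated columns -> 1 - (-1) = 2
  x <- seq(0, 1, length.out = 12)
  expect_equal(methylation_distance_matrix(cbind(a = x, b = 1 - x), "pearson")["a", "b"], 2)
  # too few shared features errors
  sparse <- cbind(a = c(runif(5), rep(NA, 7)), b = c(rep(NA, 7), runif(5)))
  expect_error(methylation_distance_matrix(sparse), "fewer than")
})

test_that("triangle inequality holds for euclidean and manhattan metrics", {
  set.seed(53)
  for (i in 1:10) {
    d <- methylation_distance_matrix(matrix(runif(60), 12),
                                     metric = sample(c("euclidean", "manhattan"), 1))
    n <- ncol(d)
    for (a in 1:n) for (b in 1:n) for (cc in 1:n) {
      expect_lte(d[a, b], d[a, cc] + d[cc, b] + 1e-9)
    }
  }
})

test_that("neighbor joining recovers a known 4-taxon additive tree exactly", {
  # tree ((A:1,B:2):1,C:3,D:4) -> hand-built path-length matrix
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- neighbor_joining(d)
  truth <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_equal(robinson_foulds(tr, truth)$rf, 0)
  expect_equal(stats::cophenetic(tr)[rownames(d), colnames(d)], d, tolerance = 1e-10)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa|symmetric")
})

test_that("3-taxon NJ branch lengths follow the three-point formulas", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  len <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len["a"]), (5 + 9 - 10) / 2)
  expect_equal(unname(len["b"]), (5 + 10 - 9) / 2)
  expect_equal(unname(len["c"]), (9 + 10 - 5) / 2)
})

test_that("NJ output is invariant to input taxon order", {
  td <- simulate_tree_data(7, seed = 54)
  perm <- sample(rownames(td$dist))
  t1 <- neighbor_joining(td$dist)
  t2 <- neighbor_joining(td$dist[perm, perm])
  expect_equal(robinson_foulds(t1, t2)$rf, 0)
  expect_equal(stats::cophenetic(t2)[rownames(td$dist), colnames(td$dist)],
               stats::cophenetic(t1)[rownames(td$dist), colnames(td$dist)],
               tolerance = 1e-9)
})

test_that("Robinson-Foulds counts discordant bipartitions symmetrically", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  t2 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);")
  expect_equal(robinson_foulds(t1, t1)$rf, 0)
  rf <- robinson_foulds(t1, t2)
  expect_equal(rf$rf, 2)
  expect_equal(rf$rf_normalized, 1)
  expect_equal(robinson_foulds(t2, t1)$rf, rf$rf)
  t3 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,e:1):1);")
  expect_error(robinson_foulds(t1, t3), "leaf set")
})
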