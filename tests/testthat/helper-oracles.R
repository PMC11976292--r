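# Shared oracles and small generators used across test files.

# Monte-Carlo pair-difference oracle for epipolymorphism: draws `n_pairs`
# iid epiallele pairs from pattern distribution p as one multinomial over the
# 256 joint (x, y) categories and returns the fraction of discordant pairs.
mc_pair_epipolymorphism <- function(p, n_pairs = 1e6) {
  joint <- as.vector(outer(p, p))
  cnt <- stats::rmultinom(1, n_pairs, joint)[, 1]
  same <- sum(cnt[seq(1, 256, by = 17)]) # diagonal cells (x == y)
  1 - same / n_pairs
}

# Per-CpG column oracle for average methylation: fraction methylated at each
# of the four CpGs (weighted by reads), averaged over CpGs.
column_avg_methylation <- function(counts) {
  counts <- as.numeric(counts)
  bits <- t(vapply(0:15, function(p) as.integer(bitwAnd(p, c(8L, 4L, 2L, 1L)) > 0L),
                   integer(4)))
  mean(colSums(counts * bits) / sum(counts))
}

# random 16-pattern count vector with depth >= 1
random_count_vector <- function(max_depth = 200) {
  depth <- sample.int(max_depth, 1)
  alpha <- stats::rgamma(16, shape = stats::runif(1, 0.1, 2))
  stats::rmultinom(1, depth, alpha / sum(alpha))[, 1]
}

# all permutations of 1..k (k small)
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# proportion MAE after the best component permutation
permuted_mae <- function(A_hat, A_true) {
  k <- nrow(A_true)
  min(apply(all_permutations(k), 1, function(p) mean(abs(A_hat[p, , drop = FALSE] - A_true))))
}

extdata <- function(f) system.file("extdata", f, package = "epipoly")
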