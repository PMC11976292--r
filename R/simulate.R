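# Synthetic data generators emulating a multi-region tumour/normal bisulfite
# study: read-level epiallele counts with planted disorder differences,
# expression linked to methylation and epipolymorphism, cell-type mixtures,
# and trees with Brownian-evolved features.

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults emulate the study
#' design this package targets: 18 patients with 6 multi-region tumour samples
#' each plus 28 normal kidney samples (136 samples in total).
#'
#' @param seed integer root seed; a fixed seed makes every generator
#'   byte-identical across runs.
#' @param n_patients,regions_per_patient,n_normal cohort layout.
#' @param n_eloci number of simulated e-loci.
#' @param frac_differential fraction of e-loci with a planted tumour/normal
#'   epipolymorphism difference.
#' @param disorder_high Dirichlet concentration for disordered loci (pattern
#'   probabilities drawn around the uniform base measure; larger = closer to
#'   uniform, epipolymorphism near 0.9375).
#' @param disorder_low Dirichlet concentration for ordered loci (drawn around
#'   a base measure with 95% mass on a single pole pattern).
#' @param coverage_mean,coverage_dispersion negative-binomial read depth
#'   (`mu`, `size`); loci drawing depth 0 in a sample are emitted as missing.
#' @param beta_meth,beta_epi,noise_sd expression-model coefficients (log2
#'   units per unit methylation / epipolymorphism) and residual SD.
#' @param k_true,mixing_concentration mixture components and Dirichlet
#'   concentration of per-sample proportions for [simulate_mixture()].
#' @param mixture_noise_sd technical noise SD added to mixed beta values.
#' @return validated list of class `epipoly_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_patients = 18L, regions_per_patient = 6L,
                              n_normal = 28L,
                              n_eloci = 2000L, frac_differential = 0.1,
                              disorder_high = 50, disorder_low = 50,
                              coverage_mean = 30, coverage_dispersion = 5,
                              beta_meth = -2, beta_epi = -3, noise_sd = 0.5,
                              k_true = 3L, mixing_concentration = 1,
                              mixture_noise_sd = 0.02) {
  cfg <- list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    regions_per_patient = as.integer(regions_per_patient),
    n_normal = as.integer(n_normal), n_eloci = as.integer(n_eloci),
    frac_differential = frac_differential,
    disorder_high = disorder_high, disorder_low = disorder_low,
    coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
    beta_meth = beta_meth, beta_epi = beta_epi, noise_sd = noise_sd,
    k_true = as.integer(k_true), mixing_concentration = mixing_concentration,
    mixture_noise_sd = mixture_noise_sd
  )
  counts <- c("n_patients", "regions_per_patient", "n_normal", "n_eloci", "k_true")
  if (any(vapply(cfg[counts], function(x) x < 1L, logical(1))))
    stop("all counts must be positive")
  if (frac_differential < 0 || frac_differential > 1)
    stop("frac_differential must be in [0,1]")
  if (disorder_high <= 0 || disorder_low <= 0 || mixing_concentration <= 0)
    stop("Dirichlet concentrations must be positive")
  if (coverage_mean <= 0 || coverage_dispersion <= 0 || noise_sd < 0 ||
      mixture_noise_sd < 0)
    stop("invalid coverage or noise parameters")
  class(cfg) <- "epipoly_config"
  cfg
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), ncol = n)
  sweep(x, 2, colSums(x), "/")
}

# base measures on the 16 patterns: uniform (disordered) and 95%-pole (ordered)
.base_uniform <- rep(1 / 16, 16)
.base_pole <- function(pole) {
  b <- rep(0.05 / 15, 16)
  b[pole + 1L] <- 0.95
  b
}

#' Simulate multi-region tumour/normal epiallele data
#'
#' For each e-locus a 16-pattern probability vector is drawn per group.
#' Non-differential loci share one vector across groups: 75% are ordered
#' (mass concentrated on one pole pattern; most genomic e-loci carry fully
#' concordant methylation) and 25% disordered. Differential loci receive a
#' disordered, near-uniform vector in one group and an ordered vector
#' concentrated on a pole pattern (all-methylated or all-unmethylated, split
#' 50/50) in the other; the disordered group is tumour or normal with equal
#' probability, so planted differences occur in both directions. Per sample,
#' read depth is negative binomial and pattern counts multinomial; depth-0
#' (e-locus, sample) pairs are omitted (missing, not zero).
#'
#' @param config a [simulation_config()].
#' @return list with `eloci` (catalog on a synthetic chromosome), `samples`
#'   (sample metadata: `sample_id`, `patient_id`, `group`), `counts` (pattern
#'   count table as from [count_patterns()]) and `truth` (per-locus planted
#'   group vectors as `pA.*`/`pB.*` columns, expected epipolymorphism per
#'   group `epi_tumour`/`epi_normal`, `delta_true`, `differential` flag).
#' @export
simulate_epiallele_data <- function(config) {
  stopifnot(inherits(config, "epipoly_config"))
  set.seed(config$seed)
  L <- config$n_eloci
  # synthetic catalog: loci 1 kb apart, CpGs 12 bp apart within a locus
  start <- 1000L * seq_len(L)
  eloci <- data.frame(
    elocus_id = sprintf("chrS:%d-%d", start, start + 36L),
    chrom = "chrS",
    pos1 = start, pos2 = start + 12L, pos3 = start + 24L, pos4 = start + 36L,
    span = 36L
  )
  n_tum <- config$n_patients * config$regions_per_patient
  samples <- data.frame(
    sample_id = c(sprintf("T%02d_R%d", rep(seq_len(config$n_patients),
                                           each = config$regions_per_patient),
                          rep(seq_len(config$regions_per_patient), config$n_patients)),
                  sprintf("N%02d", seq_len(config$n_normal))),
    patient_id = c(sprintf("P%02d", rep(seq_len(config$n_patients),
                                        each = config$regions_per_patient)),
                   sprintf("NP%02d", seq_len(config$n_normal))),
    group = rep(c("tumour", "normal"), c(n_tum, config$n_normal))
  )
  n_diff <- round(config$frac_differential * L)
  diff_idx <- if (n_diff > 0) sort(sample.int(L, n_diff)) else integer()
  pT <- pN <- matrix(0, L, 16)
  pole <- sample(c(0L, 15L), L, replace = TRUE)    # 50/50 unmeth/meth pole
  for (i in seq_len(L)) {
    ordered <- .rdirichlet(1, config$disorder_low * .base_pole(pole[i]))[, 1]
    if (i %in% diff_idx) {
      disordered <- .rdirichlet(1, config$disorder_high * .base_uniform)[, 1]
      if (stats::runif(1) < 0.5) {
        pT[i, ] <- disordered; pN[i, ] <- ordered
      } else {
        pT[i, ] <- ordered; pN[i, ] <- disordered
      }
    } else {
      # shared across groups: a concordant majority (75%) with a disordered
      # minority, mirroring the spread of epipolymorphism seen in real tissue
      shared <- if (stats::runif(1) < 0.75) ordered else
        .rdirichlet(1, config$disorder_high * .base_uniform)[, 1]
      pT[i, ] <- shared; pN[i, ] <- shared
    }
  }
  epi_t <- 1 - rowSums(pT^2)
  epi_n <- 1 - rowSums(pN^2)
  truth <- data.frame(
    elocus_id = eloci$elocus_id,
    differential = seq_len(L) %in% diff_idx,
    epi_tumour = epi_t, epi_normal = epi_n,
    delta_true = epi_t - epi_n
  )
  truth <- cbind(truth,
                 stats::setNames(as.data.frame(pT), paste0("pA.", 0:15)),
                 stats::setNames(as.data.frame(pN), paste0("pB.", 0:15)))
  n_samp <- nrow(samples)
  depth <- matrix(stats::rnbinom(L * n_samp, mu = config$coverage_mean,
                                 size = config$coverage_dispersion), L, n_samp)
  blocks <- vector("list", n_samp)
  for (s in seq_len(n_samp)) {
    p <- if (samples$group[s] == "tumour") pT else pN
    keep <- which(depth[, s] > 0L)
    if (!length(keep)) next
    cnts <- t(vapply(keep, function(i) stats::rmultinom(1, depth[i, s], p[i, ])[, 1],
                     integer(16)))
    colnames(cnts) <- paste0("n", 0:15)
    blocks[[s]] <- cbind(
      data.frame(elocus_id = eloci$elocus_id[keep],
                 sample_id = samples$sample_id[s]),
      as.data.frame(cnts),
      data.frame(depth = depth[keep, s])
    )
  }
  counts <- do.call(rbind, blocks)
  rownames(counts) <- NULL
  list(eloci = eloci, samples = samples, counts = counts, truth = truth)
}

#' Expand a pattern-count table to read-level calls
#'
#' Inverse of [count_patterns()] for testing and for writing read-level TSVs:
#' each counted read becomes four rows of binary calls at the e-locus CpGs.
#'
#' @param counts pattern-count table (`elocus_id`, `sample_id`, `n0`..`n15`).
#' @param eloci matching e-locus catalog.
#' @return read-level call data.frame (`read_id`, `sample_id`, `chrom`, `pos`,
#'   `call`).
#' @export
pattern_counts_to_reads <- function(counts, eloci) {
  m <- .as_count_matrix(counts)
  idx <- match(counts$elocus_id, eloci$elocus_id)
  stopifnot(!anyNA(idx))
  rows <- lapply(seq_len(nrow(counts)), function(r) {
    pats <- rep(0:15, m[r, ])
    if (!length(pats)) return(NULL)
    nread <- length(pats)
    bits <- t(vapply(pats, function(p) as.integer(bitwAnd(p, c(8L, 4L, 2L, 1L)) > 0L),
                     integer(4)))
    e <- idx[r]
    data.frame(
      read_id = rep(sprintf("%s|%s|read%04d", counts$sample_id[r],
                            counts$elocus_id[r], seq_len(nread)), each = 4L),
      sample_id = counts$sample_id[r],
      chrom = eloci$chrom[e],
      pos = rep(c(eloci$pos1[e], eloci$pos2[e], eloci$pos3[e], eloci$pos4[e]), nread),
      call = as.integer(t(bits))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate expression linked to methylation and epipolymorphism
#'
#' One gene per promoter e-locus: log2 expression is an affine function of the
#' locus's average methylation and epipolymorphism plus Gaussian noise,
#' `y = b0 + beta_meth * meth + beta_epi * epi + N(0, noise_sd)`.
#'
#' @param profiles profile table ([elocus_profiles()]) restricted to the
#'   promoter e-loci to model; one gene is created per distinct `elocus_id`.
#' @param config a [simulation_config()] supplying `beta_meth`, `beta_epi`,
#'   `noise_sd` and the seed.
#' @return list with `expression` (genes x samples matrix of log2 values),
#'   `pairs` (gene_id, elocus_id) and `truth` (per-gene b0, beta_meth,
#'   beta_epi).
#' @export
simulate_expression <- function(profiles, config) {
  stopifnot(inherits(config, "epipoly_config"))
  set.seed(config$seed + 1L)
  loci <- unique(profiles$elocus_id)
  samples <- sort(unique(profiles$sample_id))
  gene_id <- sprintf("gene_%04d", seq_along(loci))
  b0 <- stats::rnorm(length(loci), mean = 8, sd = 2)
  meth <- epi <- matrix(NA_real_, length(loci), length(samples),
                        dimnames = list(gene_id, samples))
  ri <- match(profiles$elocus_id, loci)
  ci <- match(profiles$sample_id, samples)
  meth[cbind(ri, ci)] <- profiles$avg_methylation
  epi[cbind(ri, ci)] <- profiles$epipolymorphism
  y <- b0 + config$beta_meth * meth + config$beta_epi * epi +
    matrix(stats::rnorm(length(meth), 0, config$noise_sd), nrow(meth))
  list(
    expression = y,
    pairs = data.frame(gene_id = gene_id, elocus_id = loci),
    truth = data.frame(gene_id = gene_id, b0 = b0,
                       beta_meth = config$beta_meth, beta_epi = config$beta_epi)
  )
}

#' Simulate a bulk methylome mixture
#'
#' Component methylomes `T0` have entries near the 0/1 poles (Beta(1, 25) at
#' a randomly chosen pole per entry), per-sample proportions `A0` are
#' Dirichlet columns on the simplex, and the observed matrix is
#' `D = clip(T0 %*% A0 + noise, 0, 1)`.
#'
#' @param config a [simulation_config()] (uses `k_true`,
#'   `mixing_concentration`, `mixture_noise_sd`, seed).
#' @param m number of features (CpGs/DMCs).
#' @param n number of bulk samples.
#' @return list with `D` (m x n), `T0` (m x k), `A0` (k x n).
#' @export
simulate_mixture <- function(config, m = 500L, n = 30L) {
  stopifnot(inherits(config, "epipoly_config"), config$k_true >= 1L)
  set.seed(config$seed + 2L)
  k <- config$k_true
  pole <- matrix(stats::rbinom(m * k, 1, 0.5), m, k)
  spread <- matrix(stats::rbeta(m * k, 1, 25), m, k)
  T0 <- abs(pole - spread)                 # near 0 or near 1
  A0 <- .rdirichlet(n, rep(config$mixing_concentration, k))
  D <- T0 %*% A0
  if (config$mixture_noise_sd > 0) {
    D <- D + matrix(stats::rnorm(m * n, 0, config$mixture_noise_sd), m, n)
  }
  D <- pmin(pmax(D, 0), 1)
  dimnames(D) <- list(sprintf("cpg_%05d", seq_len(m)), sprintf("S%03d", seq_len(n)))
  dimnames(T0) <- list(rownames(D), sprintf("comp%d", seq_len(k)))
  dimnames(A0) <- list(colnames(T0), colnames(D))
  list(D = D, T0 = T0, A0 = A0)
}

#' Simulate a random tree, its additive distances and Brownian features
#'
#' Draws a random binary tree with positive branch lengths, derives the
#' additive (path-length) leaf distance matrix, and evolves continuous
#' features along the branches by Brownian motion.
#'
#' @param n_leaves number of leaves (>= 3).
#' @param seed integer seed.
#' @param n_features number of Brownian-evolved features.
#' @param sigma Brownian rate (SD per unit branch length).
#' @return list with `tree` (unrooted `phylo`), `dist` (leaf path-length
#'   matrix) and `features` (leaves x features matrix).
#' @export
simulate_tree_data <- function(n_leaves, seed = 1L, n_features = 100L, sigma = 1) {
  if (n_leaves < 3L) stop("n_leaves must be >= 3")
  set.seed(seed)
  tree <- ape::rtree(n_leaves, br = function(n) stats::runif(n, 0.1, 1))
  feats <- replicate(n_features, ape::rTraitCont(tree, model = "BM", sigma = sigma))
  rownames(feats) <- tree$tip.label
  utree <- ape::unroot(tree)
  d <- stats::cophenetic(utree)
  list(tree = utree, dist = d, features = feats)
}
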