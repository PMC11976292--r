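# Epiallele pattern counting and methylation-disorder statistics at e-loci.
#
# An e-locus is a run of 4 adjacent CpGs phased on single reads. Each read
# covering all 4 CpGs exhibits one of 16 binary epiallele patterns; pattern
# codes are 0..15 with bit i = state of the i-th CpG and the 5'-most CpG as
# the most significant bit (so all-methylated = 15, 1000 = 8).

# number of methylated CpGs in each pattern code 0..15
.POPCOUNT4 <- vapply(0:15, function(p) sum(bitwAnd(p, c(8L, 4L, 2L, 1L)) > 0L), integer(1))

#' Enumerate 4-CpG e-loci from CpG positions
#'
#' Slides a 4-CpG window (step one CpG) along each chromosome and emits every
#' window whose span (last minus first coordinate) is at most `max_span`.
#' Overlapping e-loci are intentional: they are the superset from which any
#' tiling can be thinned downstream.
#'
#' @param cpg_positions data.frame with columns `chrom` and `pos` (0-based CpG
#'   coordinates, plus-strand C). Positions must be sorted and unique within
#'   each chromosome.
#' @param max_span maximum span in bp between the first and the last CpG of an
#'   e-locus. Defaults to 100 bp, the single-read scale on which epialleles
#'   can be phased.
#' @return data.frame with columns `elocus_id` (`chrom:pos1-pos4`), `chrom`,
#'   `pos1`..`pos4` and `span`.
#' @examples
#' enumerate_eloci(data.frame(chrom = "chr1", pos = c(10, 20, 30, 40, 200)))
#' @export
enumerate_eloci <- function(cpg_positions, max_span = 100) {
  stopifnot(is.data.frame(cpg_positions), all(c("chrom", "pos") %in% names(cpg_positions)))
  out <- lapply(split(cpg_positions$pos, cpg_positions$chrom), function(pos) {
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("CpG positions must be sorted and unique within each chromosome")
    }
    n <- length(pos)
    if (n < 4L) return(NULL)
    i <- seq_len(n - 3L)
    span <- pos[i + 3L] - pos[i]
    keep <- which(span <= max_span)
    if (!length(keep)) return(NULL)
    data.frame(
      pos1 = pos[keep], pos2 = pos[keep + 1L],
      pos3 = pos[keep + 2L], pos4 = pos[keep + 3L],
      span = span[keep]
    )
  })
  chroms <- rep(names(out), vapply(out, function(x) if (is.null(x)) 0L else nrow(x), integer(1)))
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(
      elocus_id = character(), chrom = character(),
      pos1 = numeric(), pos2 = numeric(), pos3 = numeric(), pos4 = numeric(),
      span = numeric()
    ))
  }
  res <- data.frame(
    elocus_id = sprintf("%s:%d-%d", chroms, out$pos1, out$pos4),
    chrom = chroms, out, row.names = NULL
  )
  res[order(res$chrom, res$pos1), , drop = FALSE]
}

#' Remove CpGs falling at SNP sites
#'
#' CpGs located at C/T and G/A SNP sites give spurious methylation calls and
#' are removed before e-locus enumeration.
#'
#' @param cpg_positions data.frame with `chrom`, `pos` (0-based).
#' @param snp_sites either a data.frame of 0-based half-open intervals
#'   (`chrom`, `start`, `end`) or of single positions (`chrom`, `pos`).
#' @return `cpg_positions` with overlapping rows removed.
#' @export
remove_snp_cpgs <- function(cpg_positions, snp_sites) {
  stopifnot(is.data.frame(cpg_positions))
  if (is.null(snp_sites) || nrow(snp_sites) == 0L) return(cpg_positions)
  if (!"start" %in% names(snp_sites)) {
    snp_sites <- data.frame(chrom = snp_sites$chrom,
                            start = snp_sites$pos, end = snp_sites$pos + 1)
  }
  q <- GenomicRanges::GRanges(cpg_positions$chrom,
                              IRanges::IRanges(cpg_positions$pos + 1L, width = 1L))
  s <- GenomicRanges::GRanges(snp_sites$chrom,
                              IRanges::IRanges(snp_sites$start + 1L, snp_sites$end))
  hit <- GenomicRanges::countOverlaps(q, s) > 0L
  cpg_positions[!hit, , drop = FALSE]
}

#' Count epiallele patterns per e-locus and sample
#'
#' A read contributes to an e-locus only if it carries a definite binary call
#' at all four CpGs; reads partially covering an e-locus are excluded. Reads
#' may contribute to several overlapping e-loci.
#'
#' @param read_calls data.frame of read-level calls with columns `read_id`,
#'   `sample_id`, `chrom`, `pos` (0-based CpG coordinate) and `call` (1 =
#'   methylated, 0 = unmethylated). Calls outside \{0,1\} are dropped with a
#'   message.
#' @param eloci e-locus catalog from [enumerate_eloci()].
#' @return data.frame with `elocus_id`, `sample_id`, 16 pattern-count columns
#'   `n0`..`n15` and `depth`. Only (e-locus, sample) pairs with at least one
#'   complete read are emitted.
#' @export
count_patterns <- function(read_calls, eloci) {
  stopifnot(all(c("read_id", "sample_id", "chrom", "pos", "call") %in% names(read_calls)))
  bad <- !(read_calls$call %in% c(0, 1))
  if (any(bad)) {
    message(sum(bad), " ambiguous calls excluded")
    read_calls <- read_calls[!bad, , drop = FALSE]
  }
  if (nrow(eloci) == 0L || nrow(read_calls) == 0L) return(.empty_counts())
  el_long <- data.table::data.table(
    elocus_id = rep(eloci$elocus_id, 4L),
    chrom = rep(eloci$chrom, 4L),
    pos = c(eloci$pos1, eloci$pos2, eloci$pos3, eloci$pos4),
    slot = rep(1:4, each = nrow(eloci))
  )
  dt <- data.table::as.data.table(read_calls[c("read_id", "sample_id", "chrom", "pos", "call")])
  m <- merge(dt, el_long, by = c("chrom", "pos"), allow.cartesian = TRUE)
  if (nrow(m) == 0L) return(.empty_counts())
  # keep reads with a call in every slot of the e-locus
  cnt <- slot <- call <- pattern <- NULL # NSE bindings
  m <- m[, if (.N == 4L) list(pattern = sum(call * 2L^(4L - slot))),
         by = c("sample_id", "read_id", "elocus_id")]
  if (nrow(m) == 0L) return(.empty_counts())
  tab <- m[, list(cnt = .N), by = c("elocus_id", "sample_id", "pattern")]
  wide <- data.table::dcast(tab, elocus_id + sample_id ~ pattern, value.var = "cnt", fill = 0L)
  res <- data.frame(elocus_id = wide$elocus_id, sample_id = wide$sample_id)
  counts <- matrix(0L, nrow(res), 16L, dimnames = list(NULL, paste0("n", 0:15)))
  have <- setdiff(names(wide), c("elocus_id", "sample_id"))
  counts[, paste0("n", have)] <- as.matrix(wide[, have, with = FALSE])
  res <- cbind(res, as.data.frame(counts))
  res$depth <- rowSums(counts)
  res
}

.empty_counts <- function() {
  out <- data.frame(elocus_id = character(), sample_id = character())
  for (i in 0:15) out[[paste0("n", i)]] <- integer()
  out$depth <- integer()
  out
}

.as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts[paste0("n", 0:15)])
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  stopifnot(ncol(counts) == 16L, all(counts >= 0))
  counts
}

#' Epipolymorphism of an epiallele count vector
#'
#' The probability that two epialleles sampled at random (with replacement)
#' from the locus differ: `1 - sum(p_i^2)` with `p_i` the observed pattern
#' frequencies. Ranges from 0 (a single pattern) to 15/16 = 0.9375 (all 16
#' patterns equiprobable). Depth 0 yields `NA`, never 0.
#'
#' @param counts numeric vector of 16 pattern counts (codes 0..15), a matrix
#'   with 16 columns, or a data.frame with columns `n0`..`n15`.
#' @return numeric vector of epipolymorphism values in \[0, 0.9375\].
#' @examples
#' epipolymorphism(c(8, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 2, 0, 2, 0))
#' @export
epipolymorphism <- function(counts) {
  counts <- .as_count_matrix(counts)
  depth <- rowSums(counts)
  p2 <- rowSums((counts / depth)^2)
  out <- 1 - p2
  out[depth == 0] <- NA_real_
  out
}

#' Average methylation of an epiallele count vector
#'
#' Mean methylated fraction across the four CpGs of the e-locus, weighted by
#' read counts: `sum(p_i * popcount(i) / 4)`. Equals the mean of the four
#' per-CpG methylated fractions. Depth 0 yields `NA`.
#'
#' @inheritParams epipolymorphism
#' @return numeric vector of values in \[0, 1\].
#' @export
avg_methylation <- function(counts) {
  counts <- .as_count_matrix(counts)
  depth <- rowSums(counts)
  out <- as.vector(counts %*% .POPCOUNT4) / (4 * depth)
  out[depth == 0] <- NA_real_
  out
}

#' Per-(e-locus, sample) profile table
#'
#' Adds epipolymorphism and average methylation to a pattern-count table.
#'
#' @param counts pattern-count table from [count_patterns()] or
#'   [simulate_epiallele_data()].
#' @return data.frame with `elocus_id`, `sample_id`, `epipolymorphism`,
#'   `avg_methylation`, `depth`.
#' @export
elocus_profiles <- function(counts) {
  data.frame(
    elocus_id = counts$elocus_id,
    sample_id = counts$sample_id,
    epipolymorphism = epipolymorphism(counts),
    avg_methylation = avg_methylation(counts),
    depth = counts$depth
  )
}

#' Coverage filter for e-loci
#'
#' Retains an e-locus iff methylation data are present at sufficient depth in
#' at least `min_sample_fraction` of samples (boundary inclusive: exactly 75%
#' passes the default). Samples with no profile row at a locus count as
#' failing, so depth-0 loci never leak through.
#'
#' @param profiles profile table from [elocus_profiles()] (needs `elocus_id`,
#'   `sample_id`, `depth`).
#' @param min_depth minimum read depth for a sample to count (default 10).
#' @param min_sample_fraction minimum fraction of samples at `min_depth`
#'   (default 0.75).
#' @param samples character vector of all sample ids forming the denominator;
#'   defaults to the samples present in `profiles`.
#' @return character vector of retained `elocus_id`s.
#' @export
filter_eloci <- function(profiles, min_depth = 10, min_sample_fraction = 0.75,
                         samples = NULL) {
  if (is.null(samples)) samples <- unique(profiles$sample_id)
  n <- length(samples)
  if (n == 0L) stop("empty sample set")
  ok <- profiles$depth >= min_depth & profiles$sample_id %in% samples
  n_ok <- tapply(ok, profiles$elocus_id, sum)
  names(n_ok)[n_ok / n >= min_sample_fraction]
}
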