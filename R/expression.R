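# Linking promoter e-loci to genes and quantifying the contribution of
# epipolymorphism to expression beyond average methylation.

#' Assign e-loci to gene promoters
#'
#' Emits an (e-locus, gene) pair whenever any of the locus's four CpGs falls
#' in the gene's promoter window. The window is strand-aware: for a + gene it
#' spans `[tss - upstream, tss + downstream)` and for a - gene
#' `[tss - downstream, tss + upstream)` (0-based half-open). Many-to-many
#' pairs are allowed; genes lacking a TSS are skipped with a warning.
#'
#' @param eloci e-locus catalog ([enumerate_eloci()]).
#' @param genes data.frame with `gene_id`, `chrom`, `tss` (0-based), `strand`
#'   in `+`/`-`.
#' @param upstream,downstream promoter window in bp (defaults 1000 and 500).
#' @return data.frame of pairs: `elocus_id`, `gene_id`.
#' @export
assign_promoter_eloci <- function(eloci, genes, upstream = 1000, downstream = 500) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)))
  bad <- is.na(genes$tss)
  if (any(bad)) {
    warning(sum(bad), " genes without TSS skipped")
    genes <- genes[!bad, , drop = FALSE]
  }
  stopifnot(all(genes$strand %in% c("+", "-")))
  start <- ifelse(genes$strand == "+", genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(genes$strand == "+", genes$tss + downstream, genes$tss + upstream)
  if (nrow(eloci) == 0L || nrow(genes) == 0L)
    return(data.frame(elocus_id = character(), gene_id = character()))
  q <- GenomicRanges::GRanges(
    rep(eloci$chrom, 4L),
    IRanges::IRanges(c(eloci$pos1, eloci$pos2, eloci$pos3, eloci$pos4) + 1L,
                     width = 1L)
  )
  s <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(start + 1L, end))
  ov <- GenomicRanges::findOverlaps(q, s)
  if (!length(ov)) return(data.frame(elocus_id = character(), gene_id = character()))
  pairs <- unique(data.frame(
    elocus_id = eloci$elocus_id[(S4Vectors::queryHits(ov) - 1L) %% nrow(eloci) + 1L],
    gene_id = genes$gene_id[S4Vectors::subjectHits(ov)]
  ))
  rownames(pairs) <- NULL
  pairs[order(pairs$elocus_id, pairs$gene_id), , drop = FALSE]
}

#' Remove genes with low expression counts
#'
#' Drops genes whose raw count is below `min_count` (strictly less: a count of
#' exactly 5 is retained under the default). By default the rule applies to
#' the gene's total count across samples; `per_sample = TRUE` instead drops
#' genes falling below the threshold in any sample.
#'
#' @param counts genes x samples matrix of raw (non-negative) counts.
#' @param min_count removal threshold (default 5).
#' @param per_sample apply the rule per sample rather than to totals.
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_count = 5, per_sample = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  keep <- if (per_sample) {
    apply(counts, 1, function(x) all(x >= min_count))
  } else {
    rowSums(counts) >= min_count
  }
  counts[keep, , drop = FALSE]
}

#' Univariate expression ~ epipolymorphism model
#'
#' Ordinary least squares of log2 expression on epipolymorphism for one
#' (e-locus, gene) pair; the two-sided p-value refers to the slope.
#'
#' @param expr numeric vector of log2 expression values.
#' @param epipoly matched epipolymorphism values.
#' @return one-row data.frame: `n_samples`, `slope`, `p`, `sign` in
#'   \{`neg`, `pos`\}. Requires >= 4 paired non-missing samples and a
#'   non-constant regressor; a constant regressor yields `NA` p (excluded
#'   from any downstream BH).
#' @export
fit_univariate <- function(expr, epipoly) {
  ok <- !is.na(expr) & !is.na(epipoly)
  expr <- expr[ok]; epipoly <- epipoly[ok]
  n <- length(expr)
  if (n < 4L) stop("need >= 4 paired non-missing samples")
  if (stats::sd(epipoly) == 0) {
    return(data.frame(n_samples = n, slope = NA_real_, p = NA_real_,
                      sign = NA_character_))
  }
  fit <- stats::lm(expr ~ epipoly)
  cf <- summary(fit)$coefficients
  slope <- cf["epipoly", "Estimate"]
  data.frame(n_samples = n, slope = slope, p = cf["epipoly", "Pr(>|t|)"],
             sign = if (slope < 0) "neg" else "pos")
}

#' Nested models: methylation alone vs methylation + epipolymorphism
#'
#' Fits `expr ~ meth` (reduced) and `expr ~ meth + epipoly` (full) on the same
#' samples and tests the epipolymorphism term by a likelihood ratio test. The
#' statistic is `n * ln(RSS_reduced / RSS_full)`; its p-value is computed
#' exactly from the statistic's Gaussian finite-sample null distribution via
#' the monotone F(1, n-3) pivot (default), or from the asymptotic chi-squared
#' (1 df) reference with `p_method = "chisq"`.
#'
#' @param expr,meth,epipoly matched numeric vectors (log2 expression, average
#'   methylation, epipolymorphism); >= 5 paired non-missing samples and
#'   non-constant methylation required.
#' @param p_method `"exact"` (F-pivot, default) or `"chisq"`.
#' @return one-row data.frame: `n_samples`, `slope_epi_univariate`, `p_uni`,
#'   `adjR2_meth`, `adjR2_full`, `lrt_stat`, `p_lrt`, `sign_epi`, `collinear`.
#'   An epipolymorphism vector collinear with methylation (|r| = 1, including
#'   constant epipoly) yields `lrt_stat` 0, `p_lrt` 1 and `collinear = TRUE`.
#' @export
compare_nested_models <- function(expr, meth, epipoly,
                                  p_method = c("exact", "chisq")) {
  p_method <- match.arg(p_method)
  ok <- !is.na(expr) & !is.na(meth) & !is.na(epipoly)
  expr <- expr[ok]; meth <- meth[ok]; epipoly <- epipoly[ok]
  n <- length(expr)
  if (n < 5L) stop("need >= 5 paired non-missing samples")
  if (stats::sd(meth) == 0) stop("methylation regressor is constant")
  uni <- if (stats::sd(epipoly) > 0) fit_univariate(expr, epipoly) else
    data.frame(n_samples = n, slope = NA_real_, p = NA_real_, sign = NA_character_)
  collinear <- stats::sd(epipoly) == 0 ||
    abs(stats::cor(meth, epipoly)) > 1 - 1e-12
  red <- stats::lm(expr ~ meth)
  adjR2_meth <- summary(red)$adj.r.squared
  if (collinear) {
    return(data.frame(
      n_samples = n, slope_epi_univariate = uni$slope, p_uni = uni$p,
      adjR2_meth = adjR2_meth, adjR2_full = adjR2_meth,
      lrt_stat = 0, p_lrt = 1, sign_epi = uni$sign, collinear = TRUE
    ))
  }
  full <- stats::lm(expr ~ meth + epipoly)
  rss_r <- sum(stats::residuals(red)^2)
  rss_f <- sum(stats::residuals(full)^2)
  eps <- .Machine$double.eps * n * max(1, stats::var(expr))
  if (rss_f <= eps) {
    lrt <- Inf
    p <- 0
  } else {
    lrt <- n * log(rss_r / rss_f)
    p <- if (p_method == "chisq") {
      stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    } else {
      stats::pf((n - 3) * (rss_r - rss_f) / rss_f, 1, n - 3, lower.tail = FALSE)
    }
  }
  slope_epi <- stats::coef(full)[["epipoly"]]
  data.frame(
    n_samples = n, slope_epi_univariate = uni$slope, p_uni = uni$p,
    adjR2_meth = adjR2_meth, adjR2_full = summary(full)$adj.r.squared,
    lrt_stat = lrt, p_lrt = p,
    sign_epi = if (slope_epi < 0) "neg" else "pos", collinear = FALSE
  )
}

#' Run the nested-model comparison over all (e-locus, gene) pairs
#'
#' Applies [compare_nested_models()] to every pair, then adjusts the
#' univariate and LRT p-values by Benjamini-Hochberg across pairs (pairs with
#' missing p are excluded from the corresponding BH denominator).
#'
#' @param pairs data.frame of `elocus_id`, `gene_id` (e.g. from
#'   [assign_promoter_eloci()]).
#' @param expression genes x samples matrix of log2 expression.
#' @param profiles profile table supplying `avg_methylation` and
#'   `epipolymorphism` per (elocus_id, sample_id).
#' @param q_threshold significance threshold on `q_lrt` (default 0.05).
#' @inheritParams compare_nested_models
#' @return data.frame, one row per pair, with [compare_nested_models()]
#'   columns plus `q_uni`, `q_lrt` and `significant` (`q_lrt < q_threshold`).
#' @export
run_expression_models <- function(pairs, expression, profiles,
                                  q_threshold = 0.05,
                                  p_method = c("exact", "chisq")) {
  p_method <- match.arg(p_method)
  samples <- colnames(expression)
  key <- paste(profiles$elocus_id, profiles$sample_id)
  meth_map <- stats::setNames(profiles$avg_methylation, key)
  epi_map <- stats::setNames(profiles$epipolymorphism, key)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    k <- paste(pairs$elocus_id[i], samples)
    rows[[i]] <- tryCatch(
      compare_nested_models(expression[pairs$gene_id[i], ],
                            unname(meth_map[k]), unname(epi_map[k]),
                            p_method = p_method),
      error = function(e) NULL
    )
  }
  keep <- !vapply(rows, is.null, logical(1))
  res <- cbind(pairs[keep, , drop = FALSE], do.call(rbind, rows[keep]))
  rownames(res) <- NULL
  res$q_uni <- res$q_lrt <- NA_real_
  ok <- !is.na(res$p_uni)
  res$q_uni[ok] <- stats::p.adjust(res$p_uni[ok], method = "BH")
  ok <- !is.na(res$p_lrt)
  res$q_lrt[ok] <- stats::p.adjust(res$p_lrt[ok], method = "BH")
  res$significant <- !is.na(res$q_lrt) & res$q_lrt < q_threshold
  res
}
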