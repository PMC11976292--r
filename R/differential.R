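# Differential epipolymorphism between groups and annotation enrichment.

#' Differential epipolymorphism between two groups
#'
#' Per e-locus two-sample test on epipolymorphism values with
#' Benjamini-Hochberg adjustment across tested loci. A locus is called
#' significant only when BOTH the effect-size and the adjusted-p criteria
#' hold: `|delta| > delta_min` AND `p_adj < alpha` (defaults 0.1 and 0.01).
#' When the group labels are `tumour`/`normal`, delta is tumour minus normal;
#' otherwise group A is the first level of `groups`.
#'
#' @param profiles profile table ([elocus_profiles()]); typically restricted
#'   to loci retained by [filter_eloci()].
#' @param groups named character vector mapping `sample_id` to group label
#'   (exactly two labels), or a data.frame with `sample_id`, `group`.
#' @param delta_min minimum absolute epipolymorphism difference (default 0.1).
#' @param alpha adjusted-p threshold (default 0.01).
#' @param test `"welch_t"` (default) or `"wilcoxon"`.
#' @param collapse_patients optional named vector mapping `sample_id` to
#'   patient; when given, multi-region samples are collapsed to per-patient
#'   means before testing (off by default: every region is a sample).
#' @return data.frame (one row per locus): `elocus_id`, `mean_epi_A`,
#'   `mean_epi_B`, `delta`, `p_raw`, `p_adj`, `direction` in
#'   \{`higher_in_A`, `higher_in_B`, `ns`\}, `significant`. Loci with fewer
#'   than 2 non-missing values in a group get `NA` p-values and are excluded
#'   from the BH denominator. The test used and thresholds are recorded in
#'   `attr(, "params")`.
#' @export
diff_epipolymorphism <- function(profiles, groups, delta_min = 0.1, alpha = 0.01,
                                 test = c("welch_t", "wilcoxon"),
                                 collapse_patients = NULL) {
  test <- match.arg(test)
  if (is.data.frame(groups)) groups <- stats::setNames(groups$group, groups$sample_id)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups required")
  if (all(c("tumour", "normal") %in% lv)) lv <- c("tumour", "normal")
  pr <- profiles[profiles$sample_id %in% names(groups) &
                   !is.na(profiles$epipolymorphism), , drop = FALSE]
  if (!is.null(collapse_patients)) {
    key <- paste(pr$elocus_id,
                 collapse_patients[pr$sample_id],
                 groups[pr$sample_id], sep = "\r")
    agg <- tapply(pr$epipolymorphism, key, mean)
    parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    pr <- data.frame(elocus_id = parts[, 1], sample_id = parts[, 2],
                     epipolymorphism = as.numeric(agg))
    groups <- stats::setNames(parts[, 3], parts[, 2])
  }
  grp <- groups[pr$sample_id]
  split_A <- split(pr$epipolymorphism[grp == lv[1]], pr$elocus_id[grp == lv[1]])
  split_B <- split(pr$epipolymorphism[grp == lv[2]], pr$elocus_id[grp == lv[2]])
  loci <- sort(unique(pr$elocus_id))
  res <- data.frame(elocus_id = loci, mean_epi_A = NA_real_, mean_epi_B = NA_real_,
                    delta = NA_real_, p_raw = NA_real_)
  for (i in seq_along(loci)) {
    a <- split_A[[loci[i]]]
    b <- split_B[[loci[i]]]
    if (length(a)) res$mean_epi_A[i] <- mean(a)
    if (length(b)) res$mean_epi_B[i] <- mean(b)
    res$delta[i] <- res$mean_epi_A[i] - res$mean_epi_B[i]
    if (length(a) >= 2L && length(b) >= 2L) {
      res$p_raw[i] <- if (test == "welch_t") {
        if (stats::sd(a) == 0 && stats::sd(b) == 0) {
          if (mean(a) == mean(b)) 1 else 0
        } else {
          stats::t.test(a, b)$p.value
        }
      } else {
        stats::wilcox.test(a, b, exact = FALSE)$p.value
      }
    }
  }
  res$p_adj <- NA_real_
  tested <- !is.na(res$p_raw)
  res$p_adj[tested] <- stats::p.adjust(res$p_raw[tested], method = "BH")
  res$significant <- !is.na(res$p_adj) & abs(res$delta) > delta_min & res$p_adj < alpha
  res$direction <- ifelse(!res$significant, "ns",
                          ifelse(res$delta > 0, "higher_in_A", "higher_in_B"))
  attr(res, "params") <- list(group_A = lv[1], group_B = lv[2], test = test,
                              delta_min = delta_min, alpha = alpha)
  res
}

#' Flag e-loci overlapping annotation intervals
#'
#' An e-locus carries an annotation flag if any of its four CpG coordinates
#' falls inside any interval of the annotation set (BED convention: 0-based
#' half-open).
#'
#' @param results a [diff_epipolymorphism()] table (or any data.frame with
#'   `elocus_id`).
#' @param eloci e-locus catalog with the CpG coordinates.
#' @param annotations named list of BED interval data.frames
#'   (`chrom`, `start`, `end`), e.g. `list(in_promoter = ..., in_cpg_island = ...)`;
#'   each becomes a logical column of that name.
#' @return `results` with one logical column appended per annotation set.
#' @export
annotate_direction_sets <- function(results, eloci, annotations) {
  idx <- match(results$elocus_id, eloci$elocus_id)
  if (anyNA(idx)) stop("e-loci missing from catalog")
  q <- GenomicRanges::GRanges(
    rep(eloci$chrom[idx], 4L),
    IRanges::IRanges(c(eloci$pos1[idx], eloci$pos2[idx],
                       eloci$pos3[idx], eloci$pos4[idx]) + 1L, width = 1L)
  )
  for (nm in names(annotations)) {
    bed <- annotations[[nm]]
    if (nrow(bed) == 0L) {
      results[[nm]] <- rep(FALSE, nrow(results))
      next
    }
    s <- GenomicRanges::GRanges(bed$chrom, IRanges::IRanges(bed$start + 1L, bed$end))
    hit <- GenomicRanges::countOverlaps(q, s) > 0L
    results[[nm]] <- rowSums(matrix(hit, ncol = 4L)) > 0L
  }
  results
}

#' Two-proportion enrichment test
#'
#' Two-sided chi-squared test comparing the annotated fraction between two
#' direction sets (e.g. promoter fraction among loci more disordered in
#' tumour vs more disordered in normal). Continuity correction is off by
#' default. If any expected cell count falls below 1 the function warns and
#' falls back to Fisher's exact test.
#'
#' @param k_A,n_A annotated count and total in direction set A.
#' @param k_B,n_B annotated count and total in direction set B.
#' @param continuity apply Yates continuity correction (default FALSE).
#' @return one-row data.frame: `k_A`, `n_A`, `k_B`, `n_B`, `prop_A`, `prop_B`,
#'   `statistic` (chi-squared; `NA` for the exact fallback), `p`, `method`.
#' @export
proportion_enrichment <- function(k_A, n_A, k_B, n_B, continuity = FALSE) {
  stopifnot(n_A >= 1, n_B >= 1, k_A >= 0, k_B >= 0, k_A <= n_A, k_B <= n_B)
  O <- matrix(c(k_A, n_A - k_A, k_B, n_B - k_B), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  if (any(E < 1)) {
    warning("expected cell count < 1; using Fisher's exact test")
    p <- stats::fisher.test(O)$p.value
    stat <- NA_real_
    method <- "fisher"
  } else if (k_A / n_A == k_B / n_B) {
    stat <- 0
    p <- 1
    method <- if (continuity) "chisq_continuity" else "chisq"
  } else {
    ht <- stats::prop.test(c(k_A, k_B), c(n_A, n_B), correct = continuity)
    stat <- unname(ht$statistic)
    p <- ht$p.value
    method <- if (continuity) "chisq_continuity" else "chisq"
  }
  data.frame(k_A = k_A, n_A = n_A, k_B = k_B, n_B = n_B,
             prop_A = k_A / n_A, prop_B = k_B / n_B,
             statistic = stat, p = p, method = method)
}
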