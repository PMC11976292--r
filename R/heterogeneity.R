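# Intra-tumour heterogeneity indices and phylo-epigenetic tree comparison.

#' Select features by variance across tumour samples
#'
#' Ranks features by their sample variance (computed across the given tumour
#' columns only) and keeps the top `ceiling(fraction * m)` with the highest
#' (default) or lowest variance. Ties are broken deterministically by genomic
#' coordinate, then feature id. Rows with fewer than two non-missing values
#' are excluded before ranking.
#'
#' @param mat features x samples numeric matrix with feature rownames.
#' @param fraction fraction of features to keep (default 0.10).
#' @param direction `"highest"` (default) or `"lowest"` variance.
#' @param tumour_samples column names to compute variance over; defaults to
#'   all columns.
#' @param coords optional numeric vector (parallel to rows) used as the
#'   first tie-break key; defaults to row order.
#' @return the row-subset matrix (all original columns), in rank order.
#' @export
select_top_variance <- function(mat, fraction = 0.10,
                                direction = c("highest", "lowest"),
                                tumour_samples = NULL, coords = NULL) {
  direction <- match.arg(direction)
  stopifnot(fraction > 0, fraction <= 1)
  sub <- if (is.null(tumour_samples)) mat else mat[, tumour_samples, drop = FALSE]
  if (ncol(sub) < 2L) stop("need >= 2 tumour samples to compute variance")
  v <- apply(sub, 1, stats::var, na.rm = TRUE)
  usable <- which(rowSums(!is.na(sub)) >= 2L)
  if (is.null(coords)) coords <- seq_len(nrow(mat))
  ids <- if (is.null(rownames(mat))) as.character(seq_len(nrow(mat))) else rownames(mat)
  n_keep <- ceiling(fraction * length(usable))
  key <- if (direction == "highest") -v[usable] else v[usable]
  ord <- usable[order(key, coords[usable], ids[usable])]
  mat[ord[seq_len(n_keep)], , drop = FALSE]
}

#' Average pairwise intra-tumour heterogeneity (APITH)
#'
#' Mean distance over all C(n, 2) pairs of multi-region tumour samples from
#' one patient, `APITH = 2 / (n (n - 1)) * sum_{i<j} d(i, j)`. The averaging
#' over pairs makes the index comparable across patients with different
#' numbers of sampled regions. The default distance is the mean absolute beta
#' difference over features non-missing in both samples.
#'
#' @param mat features x samples matrix for one patient's tumour samples
#'   (n >= 2 columns).
#' @param metric `"mean_abs_beta"` (default) or `"euclidean"`.
#' @return one-row data.frame: `n_samples`, `metric`, `apith`. With n < 2 the
#'   value is `NA`.
#' @export
apith <- function(mat, metric = c("mean_abs_beta", "euclidean")) {
  metric <- match.arg(metric)
  mat <- as.matrix(mat)
  n <- ncol(mat)
  if (n < 2L) {
    return(data.frame(n_samples = n, metric = metric, apith = NA_real_))
  }
  dists <- utils::combn(n, 2, function(ij) {
    x <- mat[, ij[1]]; y <- mat[, ij[2]]
    ok <- !is.na(x) & !is.na(y)
    if (!any(ok)) return(NA_real_)
    if (metric == "mean_abs_beta") mean(abs(x[ok] - y[ok]))
    else sqrt(sum((x[ok] - y[ok])^2))
  })
  data.frame(n_samples = n, metric = metric, apith = mean(dists))
}

#' PCAR (predicted-to-chronological age ratio) homogeneity summary
#'
#' Computes PCAR = DNAm age / chronological age per sample and, per patient,
#' the maximum relative PCAR difference among tumour samples,
#' `(max - min) / min`. A patient is flagged methylation-homogeneous iff that
#' difference is strictly below `bound` (default 0.30). Patients with a single
#' tumour sample are homogeneous by convention (`n_samples = 1`). Samples with
#' missing DNAm age are excluded with a message.
#'
#' @param ages data.frame with `sample_id`, `patient_id`, `dnam_age`,
#'   `chrono_age` (> 0); optional logical `is_tumour` (default all TRUE).
#' @param bound relative-difference threshold (default 0.30).
#' @return list with `samples` (per-sample PCAR) and `patients` (per-patient
#'   `n_samples`, `max_pcar_diff`, `homogeneous`).
#' @export
pcar_summary <- function(ages, bound = 0.30) {
  stopifnot(all(c("sample_id", "patient_id", "dnam_age", "chrono_age") %in% names(ages)))
  if (any(ages$chrono_age <= 0, na.rm = TRUE)) stop("chronological age must be > 0")
  miss <- is.na(ages$dnam_age)
  if (any(miss)) {
    message(sum(miss), " samples without DNAm age excluded")
    ages <- ages[!miss, , drop = FALSE]
  }
  if (is.null(ages$is_tumour)) ages$is_tumour <- TRUE
  samples <- data.frame(
    sample_id = ages$sample_id, patient_id = ages$patient_id,
    dnam_age = ages$dnam_age, chrono_age = ages$chrono_age,
    pcar = ages$dnam_age / ages$chrono_age,
    is_tumour = ages$is_tumour
  )
  tum <- samples[samples$is_tumour, , drop = FALSE]
  pat <- lapply(split(tum$pcar, tum$patient_id), function(p) {
    d <- if (length(p) < 2L) 0 else (max(p) - min(p)) / min(p)
    data.frame(n_samples = length(p), max_pcar_diff = d, homogeneous = d < bound)
  })
  patients <- cbind(data.frame(patient_id = names(pat)), do.call(rbind, pat))
  rownames(patients) <- NULL
  list(samples = samples, patients = patients)
}

#' Sample-by-sample methylation distance matrix
#'
#' Pairwise distances between sample columns on pairwise-complete features.
#'
#' @param beta features x samples matrix (typically pre-selected with
#'   [select_top_variance()]).
#' @param metric `"euclidean"`, `"manhattan"` or `"pearson"` (1 - Pearson
#'   correlation).
#' @param min_shared minimum number of features shared by every sample pair
#'   (default 10); fewer is an error.
#' @return symmetric distance matrix with zero diagonal.
#' @export
methylation_distance_matrix <- function(beta,
                                        metric = c("euclidean", "manhattan", "pearson"),
                                        min_shared = 10L) {
  metric <- match.arg(metric)
  beta <- as.matrix(beta)
  obs <- !is.na(beta)
  shared <- crossprod(obs)
  diag(shared) <- NA
  if (min(shared, na.rm = TRUE) < min_shared) {
    stop("some sample pair shares fewer than ", min_shared, " features")
  }
  n <- ncol(beta)
  d <- matrix(0, n, n, dimnames = list(colnames(beta), colnames(beta)))
  if (metric == "pearson") {
    d <- 1 - stats::cor(beta, use = "pairwise.complete.obs")
    diag(d) <- 0
  } else {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        x <- beta[, i]; y <- beta[, j]
        ok <- !is.na(x) & !is.na(y)
        d[i, j] <- d[j, i] <- if (metric == "euclidean") {
          sqrt(sum((x[ok] - y[ok])^2))
        } else {
          sum(abs(x[ok] - y[ok]))
        }
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Q-matrix criterion, via the phylogenetics
#' machinery of `ape`); on an additive matrix NJ reproduces the generating
#' topology and branch lengths. Negative branch lengths (possible on
#' non-additive input) are clamped to zero with the deficit transferred to the
#' adjacent branch so leaf-to-leaf path lengths are preserved where possible.
#'
#' @param d symmetric distance matrix (n >= 3) with labelled rows/columns.
#' @return unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need >= 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) stop("matrix must be symmetric")
  tree <- ape::nj(stats::as.dist(d))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    len <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    node <- tree$edge[e, 2]
    adj <- which(tree$edge[, 1] == node)
    if (length(adj)) {
      tree$edge.length[adj] <- pmax(tree$edge.length[adj] + len, 0)
    }
  }
  tree
}

#' Average-linkage tree from a distance matrix
#'
#' Hierarchical clustering alternative to [neighbor_joining()] (UPGMA-style
#' average linkage), returned as a `phylo` tree.
#'
#' @inheritParams neighbor_joining
#' @return rooted ultrametric `phylo` tree.
#' @export
average_linkage_tree <- function(d) {
  ape::as.phylo(stats::hclust(stats::as.dist(as.matrix(d)), method = "average"))
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the non-trivial bipartitions present in exactly one of the two
#' unrooted trees; for fully resolved trees on n leaves the maximum is
#' 2 (n - 3), which normalizes the distance to \[0, 1\].
#'
#' @param tree1,tree2 `phylo` trees on identical leaf sets.
#' @return one-row data.frame: `rf` (even integer), `rf_normalized`.
#' @export
robinson_foulds <- function(tree1, tree2) {
  if (!setequal(tree1$tip.label, tree2$tip.label)) {
    stop("trees must share an identical leaf set")
  }
  t1 <- ape::unroot(tree1)
  t2 <- ape::unroot(tree2)
  rf <- phangorn::RF.dist(t1, t2, normalize = FALSE)
  n <- length(t1$tip.label)
  data.frame(rf = rf, rf_normalized = if (n > 3) rf / (2 * (n - 3)) else 0)
}
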