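# Reference-free decomposition of bulk methylomes into latent methylation
# components (LMCs) by regularized non-negative matrix factorization:
#
#   minimize  || W o (D - T A) ||_F^2 + lambda * sum_{j,c} T_jc (1 - T_jc)
#   subject to 0 <= T <= 1,  A >= 0,  columns of A on the probability simplex.
#
# The T(1-T) penalty pushes component methylomes towards the biologically
# plausible 0/1 poles. Optimization alternates an exact per-entry T update
# with simplex-projected gradient descent on the (convex, quadratic) A
# subproblem; the objective is asserted non-increasing at every iteration.

# Euclidean projection onto the probability simplex (sorting algorithm).
.proj_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u > (css - 1) / seq_along(u)))
  pmax(v - (css[rho] - 1) / rho, 0)
}

.deconv_objective <- function(D, T, A, lambda, W) {
  r <- D - T %*% A
  if (!is.null(W)) r <- r * W
  sum(r^2, na.rm = TRUE) + lambda * sum(T * (1 - T))
}

# One pass of exact coordinate minimization over T, one component at a time.
# For fixed component c every row decouples: the entry minimizes a scalar
# quadratic q t^2 + b t over [0, 1] (interior stationary point when q > 0,
# otherwise the better endpoint).
.update_T <- function(D, T, A, lambda, W) {
  k <- ncol(T)
  R <- D - T %*% A
  if (!is.null(W)) R[W == 0] <- 0
  for (c in seq_len(k)) {
    if (is.null(W)) {
      Rc <- R + outer(T[, c], A[c, ])
      q <- rep(sum(A[c, ]^2) - lambda, nrow(T))
      b <- -2 * as.vector(Rc %*% A[c, ]) + lambda
    } else {
      Rc <- R + outer(T[, c], A[c, ]) * W
      q <- as.vector(W %*% A[c, ]^2) - lambda
      b <- -2 * as.vector(Rc %*% A[c, ]) + lambda
    }
    t_new <- ifelse(q > 0, pmin(pmax(-b / (2 * pmax(q, 1e-300)), 0), 1),
                    as.numeric(q + b < 0))
    R <- Rc - outer(t_new, A[c, ] * 1) * (if (is.null(W)) 1 else W)
    T[, c] <- t_new
  }
  T
}

# Column-wise simplex projection of a k x n matrix (single radix sort over
# the flattened matrix; k is small so the cumsum runs row-wise).
.proj_simplex_cols <- function(V) {
  k <- nrow(V)
  n <- ncol(V)
  if (k == 1L) return(matrix(1, 1L, n))
  o <- order(rep(seq_len(n), each = k), V, method = "radix",
             decreasing = c(FALSE, TRUE))
  U <- matrix(V[o], k, n)
  CSS <- U
  for (i in 2:k) CSS[i, ] <- CSS[i - 1L, ] + U[i, ]
  # the Duchi condition holds on a prefix of each sorted column
  rho <- colSums(U > (CSS - 1) / seq_len(k))
  theta <- (CSS[cbind(rho, seq_len(n))] - 1) / rho
  pmax(sweep(V, 2, theta), 0)
}

# Projected gradient descent on the simplex-constrained columns of A, run on
# all columns at once. A single Lipschitz bound 2 ||T'T||_2 dominates every
# column's (possibly masked) quadratic, so each step descends per column.
.update_A <- function(D, T, A, W, inner_iter = 40L, inner_tol = 1e-9) {
  TtT <- crossprod(T)
  L <- 2 * max(eigen(TtT, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  G <- if (is.null(W)) crossprod(T, D) else crossprod(T, W * D)
  for (it in seq_len(inner_iter)) {
    grad <- if (is.null(W)) {
      2 * (TtT %*% A - G)
    } else {
      2 * (crossprod(T, W * (T %*% A)) - G)
    }
    A_new <- .proj_simplex_cols(A - grad / L)
    if (max(abs(A_new - A)) < inner_tol) { A <- A_new; break }
    A <- A_new
  }
  A
}

#' Regularized NMF deconvolution of a bulk methylation matrix
#'
#' Factorizes `D ~ T %*% A` where `T` holds k latent methylation components
#' (entries in \[0, 1\]) and `A` per-sample proportions (non-negative, columns
#' summing to 1), minimizing the Frobenius reconstruction error plus a
#' `lambda * sum(T * (1 - T))` penalty that draws components towards fully
#' methylated/unmethylated states. Alternating minimization with multiple
#' random restarts; the best restart by final objective is returned. The
#' objective is checked to be non-increasing at every iteration and any
#' violation above 1e-9 aborts the run.
#'
#' @param D features x samples matrix, entries in \[0, 1\], no non-finite
#'   values (rows with missing entries are dropped with a message unless a
#'   `mask` is supplied).
#' @param k number of components (1 <= k <= min(dim(D))).
#' @param lambda regularization weight (>= 0, default 0).
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed; restart r uses `seed + r`.
#' @param max_iter maximum alternating iterations per restart (default 200).
#' @param tol relative objective-change stopping tolerance (default 1e-7).
#' @param mask optional logical/0-1 matrix like `D`; `FALSE`/0 entries are
#'   excluded from the fit (masked objective), e.g. for cross-validation.
#' @return list of class `epipoly_deconv`: `T`, `A`, `k`, `lambda`,
#'   `objective`, `trace` (per-iteration objective of the winning restart),
#'   `restarts`, `seed`.
#' @export
deconvolute <- function(D, k, lambda = 0, n_restarts = 10L, seed = 1L,
                        max_iter = 200L, tol = 1e-7, mask = NULL) {
  D <- as.matrix(D)
  if (is.null(mask)) {
    if (anyNA(D)) {
      keep <- stats::complete.cases(D)
      message(sum(!keep), " rows with missing entries dropped")
      D <- D[keep, , drop = FALSE]
    }
    if (any(!is.finite(D))) stop("non-finite entries in D")
    if (any(D < 0 | D > 1)) stop("entries of D must lie in [0, 1]")
  } else {
    mask <- (mask != 0) * 1
    stopifnot(all(dim(mask) == dim(D)))
    D[mask == 0] <- 0
    if (any(!is.finite(D))) stop("non-finite observed entries in D")
  }
  if (k < 1L || k > min(dim(D))) stop("k must satisfy 1 <= k <= min(dim(D))")
  if (lambda < 0) stop("lambda must be >= 0")
  m <- nrow(D); n <- ncol(D)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    T <- matrix(stats::runif(m * k), m, k)
    A <- .rdirichlet(n, rep(1, k))
    obj <- .deconv_objective(D, T, A, lambda, mask)
    trace <- obj
    for (it in seq_len(max_iter)) {
      A <- .update_A(D, T, A, mask)
      T <- .update_T(D, T, A, lambda, mask)
      new_obj <- .deconv_objective(D, T, A, lambda, mask)
      if (new_obj > obj + 1e-9 * max(1, abs(obj))) {
        stop("objective increased during alternating minimization")
      }
      trace <- c(trace, new_obj)
      if (obj - new_obj < tol * max(1, abs(obj))) { obj <- new_obj; break }
      obj <- new_obj
    }
    if (is.null(best) || obj < best$objective) {
      best <- list(T = T, A = A, objective = obj, trace = trace)
    }
  }
  rownames(best$T) <- rownames(D)
  colnames(best$T) <- rownames(best$A) <- sprintf("LMC%d", seq_len(k))
  colnames(best$A) <- colnames(D)
  out <- list(T = best$T, A = best$A, k = k, lambda = lambda,
              objective = best$objective, trace = best$trace,
              restarts = n_restarts, seed = seed)
  class(out) <- "epipoly_deconv"
  out
}

#' Select the number of components and regularization by masked CV
#'
#' For each fold, a random `holdout` fraction of matrix entries is hidden, the
#' factorization is fitted on the remaining entries (masked objective), and
#' reconstruction RMSE is scored on the hidden entries. The (k, lambda) pair
#' with the lowest mean RMSE wins; pairs whose RMSE is within `rel_tol`
#' (relative) of the minimum are treated as ties, resolved towards smaller k,
#' then larger lambda (parsimony).
#'
#' @param D features x samples matrix in \[0, 1\].
#' @param ks integer grid of component numbers.
#' @param lambdas numeric grid of regularization weights (default 0).
#' @param n_folds number of random masks (default 3).
#' @param holdout fraction of entries hidden per fold (default 0.10).
#' @param seed integer seed (drives masks and fits).
#' @param rel_tol relative RMSE tie tolerance (default 0.01).
#' @param n_restarts,max_iter,tol passed to [deconvolute()] (fewer restarts by
#'   default than a final fit).
#' @return list: `k`, `lambda`, `cv` (per k/lambda/fold RMSE table).
#' @export
select_model <- function(D, ks, lambdas = 0, n_folds = 3L, holdout = 0.10,
                         seed = 1L, rel_tol = 0.01,
                         n_restarts = 3L, max_iter = 150L, tol = 1e-6) {
  D <- as.matrix(D)
  stopifnot(length(ks) >= 1L, length(lambdas) >= 1L)
  n_entries <- length(D)
  n_hide <- round(holdout * n_entries)
  if (n_hide < 1L) stop("holdout fraction hides no entries")
  cv <- expand.grid(k = sort(ks), lambda = sort(lambdas, decreasing = TRUE),
                    fold = seq_len(n_folds), rmse = NA_real_)
  for (f in seq_len(n_folds)) {
    set.seed(seed + 1000L * f)
    hidden <- sample.int(n_entries, n_hide)
    W <- matrix(1, nrow(D), ncol(D))
    W[hidden] <- 0
    for (i in which(cv$fold == f)) {
      fit <- deconvolute(D, k = cv$k[i], lambda = cv$lambda[i],
                         n_restarts = n_restarts, seed = seed + i,
                         max_iter = max_iter, tol = tol, mask = W)
      rec <- fit$T %*% fit$A
      cv$rmse[i] <- sqrt(mean((D[hidden] - rec[hidden])^2))
    }
  }
  agg <- stats::aggregate(rmse ~ k + lambda, data = cv, FUN = mean)
  best_rmse <- min(agg$rmse)
  tied <- agg[agg$rmse <= best_rmse * (1 + rel_tol), , drop = FALSE]
  tied <- tied[order(tied$k, -tied$lambda), , drop = FALSE]
  list(k = tied$k[1], lambda = tied$lambda[1], cv = cv)
}

#' Match latent components to reference methylomes
#'
#' Pearson correlation between each LMC and each reference methylome over
#' their shared features, with BH-adjusted correlation-test p-values; a match
#' is called `positive`/`negative` by the sign of significant correlations
#' (adjusted p <= 0.05) and `none` otherwise. A joint average-linkage
#' dendrogram over LMC and reference columns (distance 1 - correlation) is
#' returned alongside.
#'
#' @param T features x k LMC matrix (rownames = feature ids).
#' @param references features x r matrix of reference methylomes (rownames
#'   matched against `T`'s when both are named).
#' @param min_shared minimum shared feature count (default 100).
#' @return list: `matches` (lmc, reference, correlation, p, p_adj, call) and
#'   `dendrogram` (an `hclust` over LMCs and references).
#' @export
match_components <- function(T, references, min_shared = 100L) {
  T <- as.matrix(T); references <- as.matrix(references)
  if (!is.null(rownames(T)) && !is.null(rownames(references))) {
    shared <- intersect(rownames(T), rownames(references))
    T <- T[shared, , drop = FALSE]
    references <- references[shared, , drop = FALSE]
  } else if (nrow(T) != nrow(references)) {
    stop("unnamed feature sets of different size")
  }
  if (nrow(T) < min_shared) stop("fewer than ", min_shared, " shared features")
  if (is.null(colnames(T))) colnames(T) <- sprintf("LMC%d", seq_len(ncol(T)))
  if (is.null(colnames(references)))
    colnames(references) <- sprintf("ref%d", seq_len(ncol(references)))
  grid <- expand.grid(lmc = colnames(T), reference = colnames(references),
                      stringsAsFactors = FALSE)
  ct <- Map(function(l, r) stats::cor.test(T[, l], references[, r]),
            grid$lmc, grid$reference)
  grid$correlation <- vapply(ct, function(x) unname(x$estimate), numeric(1))
  grid$p <- vapply(ct, function(x) x$p.value, numeric(1))
  grid$p_adj <- stats::p.adjust(grid$p, method = "BH")
  grid$call <- ifelse(grid$p_adj > 0.05, "none",
                      ifelse(grid$correlation > 0, "positive", "negative"))
  joint <- cbind(T, references)
  dend <- stats::hclust(stats::as.dist(1 - stats::cor(joint)), method = "average")
  list(matches = grid, dendrogram = dend)
}

#' Compare a component's proportions across sample labels
#'
#' Two-sided Wilcoxon rank-sum test of one LMC's per-sample proportion for
#' each binary label (e.g. tumour/normal, stage, grade), with BH adjustment
#' across labels. Labels with fewer than 2 samples per level are skipped with
#' a warning.
#'
#' @param proportions named numeric vector: one row of `A` (names = samples).
#' @param labels data.frame of per-sample labels, rownames (or a `sample_id`
#'   column) matching the names of `proportions`; every other column is a
#'   binary label.
#' @return data.frame per tested label: `label`, `level_A`, `level_B`,
#'   `median_A`, `median_B`, `p`, `p_adj`.
#' @export
compare_proportions_by_group <- function(proportions, labels) {
  if ("sample_id" %in% names(labels)) {
    rownames(labels) <- labels$sample_id
    labels$sample_id <- NULL
  }
  labels <- labels[names(proportions), , drop = FALSE]
  rows <- list()
  for (nm in names(labels)) {
    lab <- labels[[nm]]
    ok <- !is.na(lab) & !is.na(proportions)
    lv <- unique(lab[ok])
    if (length(lv) != 2L || min(table(lab[ok])) < 2L) {
      warning("label '", nm, "' degenerate; skipped")
      next
    }
    x <- proportions[ok][lab[ok] == lv[1]]
    y <- proportions[ok][lab[ok] == lv[2]]
    rows[[nm]] <- data.frame(
      label = nm, level_A = as.character(lv[1]), level_B = as.character(lv[2]),
      median_A = stats::median(x), median_B = stats::median(y),
      p = stats::wilcox.test(x, y, exact = FALSE)$p.value
    )
  }
  if (!length(rows)) {
    return(data.frame(label = character(), level_A = character(),
                      level_B = character(), median_A = numeric(),
                      median_B = numeric(), p = numeric(), p_adj = numeric()))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res
}
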