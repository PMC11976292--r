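# Readers/writers for the plain-text formats the pipeline consumes and an
# effective-configuration snapshot. Internal coordinates are 0-based
# half-open throughout.

#' Read per-CpG methylation counts (bedGraph or Bismark-style CpG report)
#'
#' Auto-detects the dialect by column count unless `format` is given:
#' a 6-column bedGraph (`chrom start end meth_pct count_M count_U`, 0-based
#' half-open) or a 7-column CpG report
#' (`chrom pos strand count_M count_U context trinucleotide`, 1-based).
#' Both are returned on unified 0-based coordinates.
#'
#' @param path file path.
#' @param format `"auto"` (default), `"bedgraph"` or `"cpg_report"`.
#' @return data.frame: `chrom`, `pos` (0-based), `count_M`, `count_U`.
#' @export
read_cpg_counts <- function(path, format = c("auto", "bedgraph", "cpg_report")) {
  format <- match.arg(format)
  empty <- data.frame(chrom = character(), pos = integer(),
                      count_M = integer(), count_U = integer())
  if (!any(nzchar(readLines(path, n = 10L)))) {
    warning("empty file: ", path)
    return(empty)
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    warning("empty file: ", path)
    return(empty)
  }
  if (format == "auto") {
    format <- if (ncol(tab) >= 7L) "cpg_report" else "bedgraph"
  }
  out <- if (format == "bedgraph") {
    if (ncol(tab) < 6L) stop("bedGraph needs 6 columns (4 + count_M, count_U)")
    data.frame(chrom = tab[[1]], pos = as.integer(tab[[2]]),
               count_M = as.integer(tab[[5]]), count_U = as.integer(tab[[6]]))
  } else {
    if (ncol(tab) < 5L) stop("CpG report needs >= 5 columns")
    data.frame(chrom = tab[[1]], pos = as.integer(tab[[2]]) - 1L,
               count_M = as.integer(tab[[4]]), count_U = as.integer(tab[[5]]))
  }
  if (any(out$count_M < 0 | out$count_U < 0)) stop("negative counts in ", path)
  out
}

#' Read a BED file of intervals
#'
#' @param path BED path (>= 3 columns, 0-based half-open). Malformed lines are
#'   reported with their line number.
#' @return data.frame: `chrom`, `start`, `end` (plus `name` when present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) return(data.frame(chrom = character(), start = integer(),
                                        end = integer()))
  parts <- strsplit(lines, "\t")
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | end < start)
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L), start = start, end = end)
  if (any(vapply(parts, length, integer(1)) >= 4L)) {
    out$name <- vapply(parts, function(x) if (length(x) >= 4L) x[4] else NA_character_, "")
  }
  out
}

#' Read read-level methylation calls from TSV
#'
#' Expected columns: `read_id`, `sample_id`, `chrom`, `pos` (0-based),
#' `call` (0/1). A header line is required.
#'
#' @param path TSV path.
#' @return data.frame of calls.
#' @export
read_read_calls <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("read_id", "sample_id", "chrom", "pos", "call")
  if (!all(need %in% names(tab))) {
    stop("read-call TSV must have columns: ", paste(need, collapse = ", "))
  }
  tab
}

#' Read and write Newick trees
#'
#' Thin wrappers around the `ape` Newick parser/serializer (branch lengths and
#' quoted labels supported); a write-read-write cycle is stable modulo float
#' formatting.
#'
#' @param path file path.
#' @return `read_newick`: a `phylo` tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree a `phylo` tree.
#' @export
write_newick <- function(tree, path) ape::write.tree(tree, file = path)

#' Read and write numeric matrices as TSV
#'
#' Matrices are written with row and column names and `NA` tokens for missing
#' values; text round-trips preserve missingness and (up to float formatting)
#' values. Lines starting with `#` are treated as header comments.
#'
#' @param path file path.
#' @return `read_matrix_tsv`: a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                              comment.char = "#", check.names = FALSE))
}

#' @rdname read_matrix_tsv
#' @param x numeric matrix.
#' @param comment optional character vector written as `#` header lines
#'   (e.g. the effective-config snapshot).
#' @export
write_matrix_tsv <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("feature", colnames(x)), collapse = "\t"), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, col.names = FALSE,
                     row.names = TRUE, na = "NA")
}

#' Effective pipeline configuration
#'
#' Collects every analysis threshold with its default so a run can snapshot
#' the exact settings used. Defaults are the canonical thresholds of the
#' analysis: |delta| > 0.1 with adjusted p < 0.01 for differential
#' epipolymorphism, depth >= 10 in >= 75% of samples, top 10% by variance,
#' promoter window -1000/+500 bp, LRT q < 0.05, PCAR homogeneity bound 0.30.
#'
#' @param ... overrides for any field.
#' @return named list of class `epipoly_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    delta_min = 0.1, alpha = 0.01,
    min_depth = 10, min_sample_fraction = 0.75,
    variance_fraction = 0.10,
    promoter_upstream = 1000, promoter_downstream = 500,
    q_threshold = 0.05, pcar_bound = 0.30,
    max_span = 100, min_count = 5,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "epipoly_pipeline_config"
  cfg
}

#' Write an effective-config snapshot
#'
#' @param config a [pipeline_config()].
#' @param path output path (simple `key: value` YAML-compatible text).
#' @export
write_config <- function(config, path) {
  writeLines(c(
    sprintf("# epipoly %s effective configuration", as.character(utils::packageVersion("epipoly"))),
    vapply(names(unclass(config)),
           function(n) sprintf("%s: %s", n, format(config[[n]])), "")
  ), path)
}
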