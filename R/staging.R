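#' Pseudo-bulk aggregation of single-cell counts
#'
#' Sums raw counts over the cells of each sample, producing a bulk-like
#' genes-by-samples matrix.
#'
#' @param sce a SingleCellExperiment with a raw `counts` assay, or a plain
#'   genes-by-cells count matrix.
#' @param sample_labels sample id per cell; no NAs.
#' @return genes-by-samples matrix of summed counts.
#' @export
pseudobulk <- function(sce, sample_labels) {
  counts <- if (methods::is(sce, "SummarizedExperiment")) get_counts(sce)
            else sce
  if (length(sample_labels) != ncol(counts))
    stop("'sample_labels' must have one entry per cell", call. = FALSE)
  if (anyNA(sample_labels)) stop("unlabeled cell(s)", call. = FALSE)
  f <- factor(sample_labels)
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), nlevels(f)))
  out <- as.matrix(counts %*% ind)
  dimnames(out) <- list(rownames(counts), levels(f))
  out
}

#' Stage query profiles against an age-graded reference by correlation
#'
#' Selects the `n_hvg` most variable genes on the REFERENCE (raw counts,
#' variance-stabilized ranking), normalizes both sides to log1p
#' counts-per-million, computes the Pearson correlation of each query
#' column with every reference sample over the shared variable genes, and
#' reports the mean correlation per reference age group. The best-matching
#' age is the argmax of those means.
#'
#' @param query genes-by-queries matrix of raw counts (e.g. a
#'   [pseudobulk()] result).
#' @param ref a [simulate_reference_series()] `reference_series`, or a list
#'   with `counts` (genes x samples) and `ages`.
#' @param n_hvg number of reference variable genes (default 2000, capped at
#'   the shared gene count).
#' @return list with `by_age` (queries x ages matrix of mean Pearson r),
#'   `best_age` (named vector, per query) and `n_genes_used`.
#' @export
stage_by_correlation <- function(query, ref, n_hvg = 2000L) {
  stopifnot(is.list(ref), !is.null(ref$counts), !is.null(ref$ages))
  shared <- intersect(rownames(query), rownames(ref$counts))
  if (length(shared) < 2)
    stop("fewer than 2 genes shared between query and reference",
         call. = FALSE)
  ref_counts <- ref$counts[shared, , drop = FALSE]
  hvg <- select_hvg(ref_counts, min(n_hvg, length(shared)))
  if (length(hvg) < 2) stop("fewer than 2 shared variable genes", call. = FALSE)

  q <- cpm_log1p(query[hvg, , drop = FALSE])
  r <- cpm_log1p(ref_counts[hvg, , drop = FALSE])
  cors <- cor(q, r)                        # queries x ref samples
  ages <- factor(ref$ages)
  by_age <- t(apply(cors, 1L, function(row) tapply(row, ages, mean)))
  if (ncol(query) == 1) {
    by_age <- matrix(by_age, nrow = 1,
                     dimnames = list(colnames(query), levels(ages)))
  }
  best <- as.numeric(levels(ages))[max.col(by_age, ties.method = "first")]
  list(by_age = by_age, best_age = setNames(best, colnames(query)),
       n_genes_used = length(hvg))
}

#' Cluster specificity scores for marker genes
#'
#' For each marker gene g and cluster c, the specificity score is the mean
#' library-size-normalized expression (counts per 10,000) of g over the
#' cells of c divided by its mean over all cells. A uniformly expressed
#' gene scores 1 in every cluster; the cell-count-weighted mean of a
#' gene's scores across clusters is 1. Genes with zero global mean are
#' dropped with a warning.
#'
#' @param sce SingleCellExperiment with raw `counts`, or a genes-by-cells
#'   count matrix.
#' @param cluster_labels cluster per cell.
#' @param marker_genes genes to score (non-empty, intersected with the
#'   matrix).
#' @param source_tag dataset tag stored on the result.
#' @return object of class `specificity_table`: genes-by-clusters matrix
#'   with attribute `source`.
#' @export
specificity_scores <- function(sce, cluster_labels, marker_genes,
                               source_tag = "dataset") {
  counts <- if (methods::is(sce, "SummarizedExperiment")) get_counts(sce)
            else sce
  if (length(cluster_labels) != ncol(counts))
    stop("'cluster_labels' must have one entry per cell", call. = FALSE)
  use <- intersect(unique(marker_genes), rownames(counts))
  if (!length(use)) stop("no marker gene present in the matrix", call. = FALSE)
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) stop("cell(s) with zero total counts", call. = FALSE)
  norm <- Matrix::t(Matrix::t(counts[use, , drop = FALSE]) * (1e4 / tot))
  global_mean <- Matrix::rowMeans(norm)
  drop <- global_mean == 0
  if (any(drop)) {
    warning("dropping gene(s) with zero global mean: ",
            paste(use[drop], collapse = ", "))
    use <- use[!drop]
    norm <- norm[!drop, , drop = FALSE]
    global_mean <- global_mean[!drop]
  }
  f <- factor(cluster_labels)
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), nlevels(f)))
  cl_mean <- sweep(as.matrix(norm %*% ind), 2L, table(f), "/")
  out <- cl_mean / global_mean
  dimnames(out) <- list(use, levels(f))
  structure(out, class = c("specificity_table", "matrix"),
            source = source_tag)
}

#' Cross-dataset correlation of cluster specificity scores
#'
#' Correlates cluster identities between two datasets: for each pair of
#' clusters, the Pearson correlation of their specificity scores over the
#' intersection of the two marker gene lists. Clusters with constant
#' scores yield NA (undefined correlation), not 0.
#'
#' @param a,b [specificity_scores()] tables.
#' @return clusters(a) x clusters(b) matrix of Pearson r.
#' @export
cross_dataset_correlation <- function(a, b) {
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) < 3)
    stop("marker gene intersection has fewer than 3 genes", call. = FALSE)
  suppressWarnings(cor(a[shared, , drop = FALSE], b[shared, , drop = FALSE]))
}
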