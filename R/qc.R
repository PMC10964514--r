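#' Quality-control filtering of cells
#'
#' Retains cells with at least `min_genes` detected genes AND a
#' mitochondrial count fraction of at most `max_mito_fraction`. The
#' boundaries are inclusive: a cell detecting exactly `min_genes` genes, or
#' with a mitochondrial fraction exactly at the cap, is kept. Cell order is
#' preserved.
#'
#' @param sce a SingleCellExperiment with a raw `counts` assay. If rowData
#'   lacks a logical `mito` column, mitochondrial genes are identified by
#'   the `MT-` symbol prefix.
#' @param min_genes minimum detected (count > 0) genes per cell.
#' @param max_mito_fraction maximum mitochondrial count fraction.
#' @return the filtered SingleCellExperiment.
#' @export
filter_cells <- function(sce, min_genes = 750L, max_mito_fraction = 0.10) {
  counts <- get_counts(sce)
  mito <- gene_flag(sce, "mito", "^MT-")
  detected <- Matrix::colSums(counts > 0)
  tot <- Matrix::colSums(counts)
  mito_frac <- ifelse(tot > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / tot, 0)
  keep <- detected >= min_genes & mito_frac <= max_mito_fraction
  if (!any(keep))
    stop("all cells filtered: no cell passes min_genes = ", min_genes,
         " and max_mito_fraction = ", max_mito_fraction, call. = FALSE)
  sce[, keep]
}

#' Quality-control filtering of genes
#'
#' Removes ribosomal-flagged genes (optionally) and genes detected in fewer
#' than `min_cells` cells. A gene detected in exactly `min_cells` cells is
#' retained.
#'
#' @param sce a SingleCellExperiment with a raw `counts` assay. If rowData
#'   lacks a logical `ribo` column, ribosomal genes are identified by the
#'   `RPL`/`RPS` symbol prefixes.
#' @param min_cells minimum number of cells a gene must be detected in.
#' @param drop_ribosomal drop ribosomal genes?
#' @return the filtered SingleCellExperiment.
#' @export
filter_genes <- function(sce, min_cells = 5L, drop_ribosomal = TRUE) {
  counts <- get_counts(sce)
  ribo <- gene_flag(sce, "ribo", "^RP[LS]")
  detected_in <- Matrix::rowSums(counts > 0)
  keep <- detected_in >= min_cells
  if (drop_ribosomal) keep <- keep & !ribo
  if (!any(keep))
    stop("all genes filtered", call. = FALSE)
  sce[keep, ]
}

#' Library-size normalization with log1p transform
#'
#' Scales each cell to `target_sum` total counts and applies log1p:
#' normalized value = log(1 + count / cell_total * target_sum). The result
#' is stored in the `logcounts` assay.
#'
#' @param sce a SingleCellExperiment with a raw `counts` assay; every cell
#'   must have a positive total count.
#' @param target_sum per-cell total after scaling (default 10,000).
#' @return the SingleCellExperiment with a `logcounts` assay added.
#' @export
normalize_counts <- function(sce, target_sum = 1e4) {
  counts <- get_counts(sce)
  tot <- Matrix::colSums(counts)
  if (any(tot == 0))
    stop("cannot normalize cell(s) with zero total counts: ",
         paste(colnames(sce)[tot == 0], collapse = ", "), call. = FALSE)
  scaled <- counts %*% Matrix::Diagonal(x = target_sum / tot)
  norm <- scaled
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "logcounts") <- norm
  sce
}

#' Select highly variable genes by standardized variance
#'
#' Ranks genes by their variance after standardization against a fitted
#' mean-variance trend (variance-stabilizing flavor): a quadratic trend of
#' log10 variance on log10 mean is fit across genes, counts are
#' standardized by the trend-predicted standard deviation with values
#' clipped at sqrt(n_cells), and genes are ranked by the variance of the
#' clipped values.
#'
#' @param sce a SingleCellExperiment with a raw `counts` assay, or a plain
#'   genes-by-cells count matrix.
#' @param n_top number of genes to return.
#' @return character vector of the `n_top` gene names, ranked most variable
#'   first.
#' @export
select_hvg <- function(sce, n_top = 2000L) {
  counts <- if (methods::is(sce, "SummarizedExperiment")) get_counts(sce) else sce
  if (n_top > nrow(counts))
    stop("'n_top' exceeds the number of genes (", nrow(counts), ")",
         call. = FALSE)
  sv <- standardized_variance(counts)
  rownames(counts)[order(-sv, seq_along(sv))][seq_len(n_top)]
}

standardized_variance <- function(counts) {
  x <- as.matrix(counts)
  n <- ncol(x)
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / max(1, n - 1)
  fit_on <- mu > 0 & v > 0
  sd_pred <- sqrt(v)                       # fallback: no regularization
  if (sum(fit_on) >= 3 && length(unique(mu[fit_on])) >= 3) {
    lx <- log10(mu[fit_on]); ly <- log10(v[fit_on])
    fit <- lm(ly ~ poly(lx, 2))
    # second pass without high-variance outliers, so genuinely variable
    # genes do not drag the trend toward themselves
    res <- ly - predict(fit)
    keep <- res <= 2 * sd(res)
    if (sum(keep) >= 3 && length(unique(lx[keep])) >= 3)
      fit <- lm(ly ~ poly(lx, 2), subset = keep)
    sd_pred[fit_on] <- sqrt(10^predict(fit, newdata = data.frame(lx = lx)))
  }
  clip <- sqrt(n)
  z <- (x - mu) / sd_pred
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  out <- rowSums((z - rowMeans(z))^2) / max(1, n - 1)
  out[!fit_on & v == 0] <- 0
  out
}

#' One-vs-rest cluster marker detection by Wilcoxon rank-sum test
#'
#' For every gene and cluster, tests the cluster's cells against all other
#' cells with a two-sided Wilcoxon rank-sum test on the normalized layer.
#' Small samples (<= 50 cells in total) use the exact null distribution
#' (full enumeration when tied values are present and the total is <= 20);
#' larger samples use the tie-corrected normal approximation. P-values are
#' Benjamini-Hochberg adjusted within each cluster.
#'
#' @param sce a SingleCellExperiment with a `logcounts` assay.
#' @param labels cluster label per cell; at least 2 clusters, each with at
#'   least 2 cells.
#' @return data.frame with columns gene, cluster, lfc (difference of mean
#'   logcounts, cluster minus rest), stat (rank-sum W), p, p_adj.
#' @export
rank_markers <- function(sce, labels) {
  expr <- get_logcounts(sce)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(expr))
  tab <- table(labels)
  if (length(tab) < 2) stop("need >= 2 clusters", call. = FALSE)
  if (any(tab < 2))
    stop("cluster(s) with < 2 cells: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)

  x <- as.matrix(expr)
  n <- ncol(x)
  res <- list()
  for (cl in names(tab)) {
    in_cl <- labels == cl
    n1 <- sum(in_cl)
    if (n <= 50) {
      p <- apply(x, 1L, function(g) exact_rank_test(g[in_cl], g[!in_cl]))
      w <- apply(x, 1L, function(g) {
        r <- rank(g)
        sum(r[in_cl]) - n1 * (n1 + 1) / 2
      })
    } else {
      # vectorized tie-corrected normal approximation
      rk <- t(apply(x, 1L, rank))
      rsum <- rowSums(rk[, in_cl, drop = FALSE])
      w <- rsum - n1 * (n1 + 1) / 2
      mu_w <- n1 * (n - n1) / 2
      tie_term <- apply(x, 1L, function(g) {
        t_ <- table(g)
        sum(t_^3 - t_)
      })
      sig <- sqrt(n1 * (n - n1) / 12 * ((n + 1) - tie_term / (n * (n - 1))))
      z <- (w - mu_w - sign(w - mu_w) * 0.5) / pmax(sig, .Machine$double.eps)
      p <- 2 * pnorm(-abs(z))
      p[sig == 0] <- 1
      p <- pmin(p, 1)
    }
    lfc <- rowMeans(x[, in_cl, drop = FALSE]) -
      rowMeans(x[, !in_cl, drop = FALSE])
    res[[cl]] <- data.frame(gene = rownames(x), cluster = cl, lfc = lfc,
                            stat = w, p = p, p_adj = p.adjust(p, "BH"),
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# ---- internal accessors -----------------------------------------------------

get_counts <- function(sce) {
  if (!"counts" %in% SummarizedExperiment::assayNames(sce))
    stop("no raw 'counts' assay present", call. = FALSE)
  SummarizedExperiment::assay(sce, "counts")
}

get_logcounts <- function(sce) {
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce))
    stop("no 'logcounts' assay present; run normalize_counts() first",
         call. = FALSE)
  SummarizedExperiment::assay(sce, "logcounts")
}

gene_flag <- function(sce, column, prefix_regex) {
  rd <- SummarizedExperiment::rowData(sce)
  if (column %in% colnames(rd)) return(as.logical(rd[[column]]))
  grepl(prefix_regex, rownames(sce))
}
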