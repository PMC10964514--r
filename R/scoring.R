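#' Gene-signature score with expression-bin-matched controls
#'
#' Scores each cell for a gene set as the mean normalized expression of the
#' set genes minus the mean expression of a random control gene pool. Genes
#' are first binned by average expression across cells
#' (`n_bins` equal-frequency bins); for every set gene, `n_ctrl_per_gene`
#' control genes are sampled with replacement from the same bin, so the
#' control pool matches the set's expression profile and the expected score
#' of a random set is zero.
#'
#' @param sce a normalized SingleCellExperiment (`logcounts`) or a plain
#'   normalized genes-by-cells matrix.
#' @param genes character vector of gene symbols (the signature); must
#'   intersect the matrix's genes.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl_per_gene control genes sampled per set gene (default 100).
#' @param seed integer seed for control sampling.
#' @param name signature name used in error messages.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(sce, genes, n_bins = 24L, n_ctrl_per_gene = 100L,
                         seed = 1L, name = "gene set") {
  expr <- if (methods::is(sce, "SummarizedExperiment")) get_logcounts(sce)
          else sce
  genes <- unique(genes)
  use <- intersect(genes, rownames(expr))
  if (!length(use))
    stop("no genes of '", name, "' are present in the matrix", call. = FALSE)

  avg <- Matrix::rowMeans(expr)
  n_bins_eff <- min(n_bins, length(avg))
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins_eff,
             labels = FALSE)
  names(bin) <- rownames(expr)

  set.seed(derive_seed(seed, 601L))
  ctrl <- unlist(lapply(use, function(g) {
    pool <- names(bin)[bin == bin[g]]
    sample(pool, n_ctrl_per_gene, replace = TRUE)
  }), use.names = FALSE)

  # control genes enter with multiplicity; accumulate as a weighted mean
  w <- table(ctrl)
  ctrl_mean <- as.numeric(
    Matrix::t(expr[names(w), , drop = FALSE]) %*% as.numeric(w)) / sum(w)
  set_mean <- Matrix::colMeans(expr[use, , drop = FALSE])
  setNames(as.numeric(set_mean - ctrl_mean), colnames(expr))
}

#' Gene-signature scores for bulk samples
#'
#' Applies counts-per-million + log1p normalization to raw bulk counts and
#' then the same bin-matched control scheme as [module_score()].
#'
#' @param counts raw genes-by-samples count matrix.
#' @param genes signature gene symbols.
#' @inheritParams module_score
#' @return named numeric vector of per-sample scores.
#' @export
module_score_bulk <- function(counts, genes, n_bins = 24L,
                              n_ctrl_per_gene = 100L, seed = 1L,
                              name = "gene set") {
  module_score(cpm_log1p(counts), genes, n_bins = n_bins,
               n_ctrl_per_gene = n_ctrl_per_gene, seed = seed, name = name)
}

#' Group means of signature scores, z-scaled across groups
#'
#' Averages per-unit scores within groups, then standardizes each gene
#' set's group means to zero mean and unit variance across groups (the
#' heatmap readout for stress signatures grouped by cell type and age).
#' With a single group the scaled value is defined as 0, with a warning.
#'
#' @param scores data.frame with one row per unit: grouping column(s) plus
#'   one numeric column per gene set.
#' @param group_keys names of the grouping column(s).
#' @return data.frame: one row per group, scaled mean per gene set.
#' @export
scaled_group_summary <- function(scores, group_keys) {
  if (!all(group_keys %in% names(scores)))
    stop("missing group key(s): ",
         paste(setdiff(group_keys, names(scores)), collapse = ", "),
         call. = FALSE)
  set_cols <- setdiff(names(scores), group_keys)
  grp <- interaction(scores[group_keys], drop = TRUE, sep = ":")
  means <- aggregate(scores[set_cols], by = list(group = grp), FUN = mean)
  if (nrow(means) == 1) {
    warning("single group: scaled scores defined as 0")
    means[set_cols] <- 0
    return(means)
  }
  for (s in set_cols) {
    v <- means[[s]]
    sdv <- sd(v)
    means[[s]] <- if (sdv > 0) (v - mean(v)) / sdv else rep(0, length(v))
  }
  means
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description description field per set (recycled).
#' @export
write_gmt <- function(sets, path, description = "") {
  desc <- rep_len(description, length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}
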