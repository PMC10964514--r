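#' Read a ligand-receptor pair table
#'
#' TSV with columns `pair_id`, `ligand_genes`, `receptor_genes`; multi-gene
#' complexes are semicolon-joined. A small curated table with glioma
#' microenvironment pairs (SPP1, FGF1, FGF2, PDGFA, PTN and their
#' receptors) ships with the package, see
#' `system.file("extdata", "lr_pairs.tsv", package = "glicomix")`.
#'
#' @param path TSV path.
#' @return data.frame of class `lr_pairs` with list-columns `ligand` and
#'   `receptor`.
#' @export
read_lr_pairs <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  lr_pairs(tab$pair_id, tab$ligand_genes, tab$receptor_genes)
}

#' @rdname read_lr_pairs
#' @param pair_id unique pair identifiers.
#' @param ligand_genes,receptor_genes semicolon-joined gene symbols (or
#'   character lists).
#' @export
lr_pairs <- function(pair_id, ligand_genes, receptor_genes) {
  split_genes <- function(x) {
    if (is.list(x)) x else strsplit(x, ";", fixed = TRUE)
  }
  lig <- split_genes(ligand_genes)
  rec <- split_genes(receptor_genes)
  if (anyDuplicated(pair_id)) stop("pair ids must be unique", call. = FALSE)
  if (any(!lengths(lig)) || any(!lengths(rec)))
    stop("ligand and receptor gene sets must be non-empty", call. = FALSE)
  structure(data.frame(pair_id = pair_id, stringsAsFactors = FALSE),
            ligand = lig, receptor = rec, class = c("lr_pairs", "data.frame"))
}

lr_genes <- function(pairs) {
  unique(unlist(c(attr(pairs, "ligand"), attr(pairs, "receptor"))))
}

#' Restrict a dataset for receptor-ligand analysis
#'
#' Drops cells of excluded (non-neuroglial) types and restricts genes to
#' the union of the top `n_hvg` most variable genes and every gene
#' referenced by the pair table, so that no ligand or receptor is lost to
#' the variable-gene cut.
#'
#' @param sce SingleCellExperiment (raw `counts`; `logcounts` kept if
#'   present).
#' @param cell_type_labels cell type per cell.
#' @param excluded_types types to remove (e.g. choroid plexus, retina,
#'   meninges).
#' @param pairs an `lr_pairs` table.
#' @param n_hvg number of variable genes (default 5000, capped).
#' @return list with `sce` (restricted) and `labels`.
#' @export
prepare_crosstalk_input <- function(sce, cell_type_labels,
                                    excluded_types = character(0),
                                    pairs, n_hvg = 5000L) {
  stopifnot(length(cell_type_labels) == ncol(sce))
  keep_cells <- !(cell_type_labels %in% excluded_types)
  if (!any(keep_cells))
    stop("excluded types remove all cells", call. = FALSE)
  sub <- sce[, keep_cells]
  hvg <- select_hvg(sub, min(n_hvg, nrow(sub)))
  keep_genes <- rownames(sub) %in% union(hvg, lr_genes(pairs))
  list(sce = sub[keep_genes, ], labels = cell_type_labels[keep_cells])
}

#' Permutation test for receptor-ligand interactions between clusters
#'
#' For every ordered cluster pair (A, B) and ligand-receptor pair, the
#' observed score is the mean of the ligand's expression in cluster A and
#' the receptor's expression in cluster B, where a complex's cluster
#' expression is the minimum over member genes of the cluster mean
#' (normalized layer). An expression gate requires every ligand member to
#' be expressed in at least `min_expressed_fraction` of A's cells and every
#' receptor member likewise in B. The null distribution is built by
#' shuffling cluster labels across cells `n_permutations` times; the
#' one-sided p-value is (1 + #(null >= observed)) / (n_permutations + 1).
#' A zero score or a failed gate yields p = 1.
#'
#' @param sce normalized SingleCellExperiment (`logcounts`) or plain
#'   normalized matrix.
#' @param labels cluster label per cell; >= 2 clusters.
#' @param pairs an `lr_pairs` table; pairs referencing absent genes are
#'   skipped (recorded in the result).
#' @param n_permutations number of label shuffles (>= 100, default 1000).
#' @param min_expressed_fraction expression gate (default 0.10).
#' @param alpha significance level for the `significant` flag.
#' @param seed integer seed for the permutations.
#' @return object of class `interaction_result`: data.frame with columns
#'   cluster_a, cluster_b, pair_id, score, expressed_gate, p, significant;
#'   attributes `alpha`, `n_permutations`, `min_expressed_fraction`,
#'   `skipped_pairs`.
#' @export
lr_permutation_test <- function(sce, labels, pairs, n_permutations = 1000L,
                                min_expressed_fraction = 0.10, alpha = 0.05,
                                seed = 1L) {
  expr <- if (methods::is(sce, "SummarizedExperiment")) get_logcounts(sce)
          else sce
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(expr))
  if (length(unique(labels)) < 2) stop("need >= 2 clusters", call. = FALSE)
  if (n_permutations < 100) stop("n_permutations must be >= 100", call. = FALSE)

  present <- vapply(seq_len(nrow(pairs)), function(i)
    all(attr(pairs, "ligand")[[i]] %in% rownames(expr)) &&
    all(attr(pairs, "receptor")[[i]] %in% rownames(expr)), logical(1))
  skipped <- pairs$pair_id[!present]
  if (!all(present)) {
    lig <- attr(pairs, "ligand")[present]
    rec <- attr(pairs, "receptor")[present]
    pairs <- pairs[present, , drop = FALSE]
    attr(pairs, "ligand") <- lig
    attr(pairs, "receptor") <- rec
  }
  if (!nrow(pairs)) stop("no testable pairs", call. = FALSE)

  genes <- intersect(rownames(expr), lr_genes(pairs))
  E <- as.matrix(expr[genes, , drop = FALSE])
  f <- factor(labels)
  K <- nlevels(f)
  sizes <- as.numeric(table(f))

  cluster_means <- function(lab_int) {
    ind <- Matrix::sparseMatrix(i = lab_int, j = seq_along(lab_int), x = 1,
                                dims = c(K, length(lab_int)))
    as.matrix(Matrix::tcrossprod(E, ind)) / rep(sizes, each = nrow(E))
  }

  # complex expression: min over member genes of the cluster mean
  complex_expr <- function(means, members) {
    vapply(members, function(g)
      apply(means[g, , drop = FALSE], 2L, min), numeric(K))
  }

  lab_int <- as.integer(f)
  means_obs <- cluster_means(lab_int)
  rownames(means_obs) <- genes
  lig_m <- attr(pairs, "ligand")
  rec_m <- attr(pairs, "receptor")
  lig_obs <- complex_expr(means_obs, lig_m)   # K x n_pairs
  rec_obs <- complex_expr(means_obs, rec_m)

  # expression gate per cluster and complex
  frac_expr <- function(members) {
    det <- (E > 0) * 1
    ind <- Matrix::sparseMatrix(i = lab_int, j = seq_along(lab_int), x = 1,
                                dims = c(K, length(lab_int)))
    fr <- as.matrix(Matrix::tcrossprod(det, ind)) /
      rep(sizes, each = nrow(E))
    rownames(fr) <- genes
    vapply(members, function(g)
      apply(fr[g, , drop = FALSE], 2L, min), numeric(K))
  }
  lig_gate <- frac_expr(lig_m) >= min_expressed_fraction
  rec_gate <- frac_expr(rec_m) >= min_expressed_fraction

  n_pairs <- nrow(pairs)
  grid <- expand.grid(a = seq_len(K), b = seq_len(K), p = seq_len(n_pairs))
  score_obs <- (lig_obs[cbind(grid$a, grid$p)] +
                rec_obs[cbind(grid$b, grid$p)]) / 2
  gate <- lig_gate[cbind(grid$a, grid$p)] & rec_gate[cbind(grid$b, grid$p)]

  set.seed(derive_seed(seed, 701L))
  exceed <- integer(length(score_obs))
  for (b in seq_len(n_permutations)) {
    means_p <- cluster_means(sample(lab_int))
    rownames(means_p) <- genes
    lig_p <- complex_expr(means_p, lig_m)
    rec_p <- complex_expr(means_p, rec_m)
    null_s <- (lig_p[cbind(grid$a, grid$p)] +
               rec_p[cbind(grid$b, grid$p)]) / 2
    exceed <- exceed + (null_s >= score_obs)
  }
  p <- (1 + exceed) / (n_permutations + 1)
  p[score_obs == 0 | !gate] <- 1

  out <- data.frame(cluster_a = levels(f)[grid$a],
                    cluster_b = levels(f)[grid$b],
                    pair_id = pairs$pair_id[grid$p],
                    score = score_obs, expressed_gate = gate, p = p,
                    significant = p <= alpha & gate,
                    stringsAsFactors = FALSE)
  structure(out, class = c("interaction_result", "data.frame"),
            alpha = alpha, n_permutations = n_permutations,
            min_expressed_fraction = min_expressed_fraction,
            skipped_pairs = skipped)
}

#' Count significant interactions per cluster pair
#'
#' @param res an [lr_permutation_test()] `interaction_result`.
#' @param symmetrize sum both directions into a symmetric matrix?
#' @return clusters x clusters count matrix (attribute `symmetrized`).
#' @export
interaction_counts <- function(res, symmetrize = FALSE) {
  cl <- sort(unique(c(res$cluster_a, res$cluster_b)))
  m <- matrix(0L, length(cl), length(cl), dimnames = list(cl, cl))
  sig <- res[res$significant, , drop = FALSE]
  if (nrow(sig)) {
    tab <- table(factor(sig$cluster_a, cl), factor(sig$cluster_b, cl))
    m <- m + unclass(tab)
  }
  if (symmetrize) m <- m + t(m)
  structure(m, symmetrized = symmetrize)
}

#' Keep microenvironment-ligand to tumor-receptor interactions
#'
#' Filters significant interactions to those whose ligand side is a
#' non-tumor cluster and whose receptor side is the tumor cluster — the
#' directional edge list behind the circos readout of pro-tumorigenic
#' crosstalk.
#'
#' @param res an `interaction_result`.
#' @param tumor_cluster name of the tumor cluster (must be present).
#' @return filtered data.frame.
#' @export
directional_filter <- function(res, tumor_cluster) {
  if (!tumor_cluster %in% c(res$cluster_a, res$cluster_b))
    stop("unknown tumor cluster: ", tumor_cluster, call. = FALSE)
  out <- res[res$significant & res$cluster_a != tumor_cluster &
               res$cluster_b == tumor_cluster, , drop = FALSE]
  rownames(out) <- NULL
  out
}
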