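#' Infer relative copy number from smoothed expression
#'
#' Centers each gene's normalized expression on the mean over an
#' assumed-diploid reference cell set, then smooths per cell with a moving
#' average over `window_genes` consecutive genes in genomic order within
#' each chromosome. Aneuploid regions show up as sustained positive or
#' negative window scores; the per-cell aneuploidy score is the mean of
#' squared window scores.
#'
#' @param sce a normalized SingleCellExperiment (`logcounts` assay) whose
#'   rowData carries `chrom` and `pos`.
#' @param reference_cells logical or index vector selecting the reference
#'   (assumed-diploid) cells; must be non-empty.
#' @param window_genes moving-average window (default 101 genes); windows
#'   are truncated (with a warning) on chromosomes with fewer genes.
#' @return object of class `cnv_profile`: list with `scores` (genes x
#'   cells window scores, genes in genomic order), `aneuploidy` (per-cell
#'   mean squared window score), `gene_order`, `window_genes`,
#'   `reference_cells`.
#' @export
infer_cnv <- function(sce, reference_cells, window_genes = 101L) {
  expr <- get_logcounts(sce)
  rd <- SummarizedExperiment::rowData(sce)
  if (!all(c("chrom", "pos") %in% colnames(rd)))
    stop("rowData must provide 'chrom' and 'pos'", call. = FALSE)
  ref_idx <- seq_len(ncol(expr))[reference_cells]
  if (!length(ref_idx)) stop("reference cell set is empty", call. = FALSE)

  chrom_levels <- unique(as.character(rd$chrom))
  ord <- order(match(as.character(rd$chrom), chrom_levels), rd$pos)
  x <- as.matrix(expr)[ord, , drop = FALSE]
  chrom <- as.character(rd$chrom)[ord]
  x <- x - rowMeans(x[, ref_idx, drop = FALSE])

  scores <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  truncated <- character(0)
  for (ch in unique(chrom)) {
    rows <- which(chrom == ch)
    w <- window_genes
    if (length(rows) < w) {
      truncated <- c(truncated, ch)
      w <- length(rows)
    }
    scores[rows, ] <- running_mean(x[rows, , drop = FALSE], w)
  }
  if (length(truncated))
    warning("window truncated on chromosome(s) with fewer than ",
            window_genes, " genes: ", paste(truncated, collapse = ", "))

  structure(list(scores = scores,
                 aneuploidy = colMeans(scores^2),
                 gene_order = rownames(x),
                 window_genes = window_genes,
                 reference_cells = colnames(expr)[ref_idx]),
            class = "cnv_profile")
}

# centered moving average over rows with window truncation at the edges
running_mean <- function(x, w) {
  n <- nrow(x)
  half <- (w - 1L) %/% 2L
  cs <- rbind(0, apply(x, 2L, cumsum))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat("cnv_profile:", nrow(x$scores), "genes x", ncol(x$scores),
      "cells; window", x$window_genes, "genes;",
      length(x$reference_cells), "reference cells\n")
  invisible(x)
}

#' Name mixture components by inferred aneuploidy
#'
#' The component whose mixture-assigned cells have the higher median
#' aneuploidy score is named `tumor`; the other `organoid`. An exact tie of
#' medians raises an error so the labeling can be set manually rather than
#' silently guessed.
#'
#' @param fit a `genotype_mixture` (or its assignment data.frame).
#' @param cnv a [infer_cnv()] `cnv_profile` over the same cells, in the
#'   same order.
#' @return the assignments with the `genotype` column filled in for every
#'   A/B-labeled cell; when `fit` is a `genotype_mixture` the full object
#'   is returned with updated assignments and a `component_genotype` map.
#' @export
label_components_by_cnv <- function(fit, cnv) {
  asg <- as_assignments(fit)
  stopifnot(inherits(cnv, "cnv_profile"))
  if (length(cnv$aneuploidy) != nrow(asg))
    stop("cnv profile and assignments cover different cells", call. = FALSE)
  in_a <- asg$label == "A"; in_b <- asg$label == "B"
  if (!any(in_a) || !any(in_b))
    stop("both components need >= 1 mixture-assigned cell", call. = FALSE)
  med_a <- median(cnv$aneuploidy[in_a])
  med_b <- median(cnv$aneuploidy[in_b])
  if (med_a == med_b)
    stop("aneuploidy medians tie exactly; component genotypes cannot be ",
         "determined from CNV - label manually", call. = FALSE)
  map <- if (med_a > med_b) c(A = "tumor", B = "organoid")
         else c(A = "organoid", B = "tumor")
  asg$genotype <- ifelse(asg$label %in% c("A", "B"),
                         unname(map[asg$label]), NA_character_)
  if (inherits(fit, "genotype_mixture")) {
    fit$assignments <- asg
    fit$component_genotype <- map
    fit
  } else asg
}

#' Rescue unassigned cells by expression nearest neighbors
#'
#' Assigns every unassigned cell the majority genotype among its
#' `n_neighbors` nearest mixture-assigned cells in principal-component
#' space of the normalized expression matrix (top `n_pcs` components on
#' the `n_hvg` most variable genes). Rescued cells are marked with method
#' `neighbor-rescue`.
#'
#' @param fit labeled `genotype_mixture` or assignment data.frame (the
#'   `genotype` column must be filled for assigned cells).
#' @param sce normalized SingleCellExperiment over the same cells.
#' @param n_neighbors neighbors to vote (default 30); when fewer assigned
#'   cells exist, all are used with a warning.
#' @param n_pcs number of principal components (default 30).
#' @param n_hvg number of variable genes for the PCA (default 2000, capped
#'   at the gene count).
#' @return assignments (same shape as input) with every cell labeled.
#' @export
rescue_unassigned <- function(fit, sce, n_neighbors = 30L, n_pcs = 30L,
                              n_hvg = 2000L) {
  asg <- as_assignments(fit)
  stopifnot(ncol(sce) == nrow(asg))
  unas <- which(asg$label == "unassigned")
  assigned <- which(asg$label %in% c("A", "B"))
  if (!length(assigned)) stop("no assigned cells to rescue from", call. = FALSE)
  if (!length(unas)) {
    return(if (inherits(fit, "genotype_mixture")) fit else asg)
  }
  if (length(assigned) < n_neighbors) {
    warning("fewer assigned cells (", length(assigned), ") than n_neighbors (",
            n_neighbors, "); using all assigned cells")
    n_neighbors <- length(assigned)
  }

  expr <- get_logcounts(sce)
  hvg <- select_hvg(sce, min(n_hvg, nrow(sce)))
  x <- t(as.matrix(expr[hvg, , drop = FALSE]))
  keep <- apply(x, 2L, sd) > 0
  x <- scale(x[, keep, drop = FALSE])
  pc <- prcomp(x, center = FALSE, scale. = FALSE,
               rank. = min(n_pcs, ncol(x), nrow(x)))$x

  ref <- pc[assigned, , drop = FALSE]
  ref_geno <- asg$genotype[assigned]
  # fall back to component labels when CNV naming has not been run yet
  use_labels <- all(is.na(ref_geno))
  if (use_labels) ref_geno <- asg$label[assigned]
  ref_norm2 <- rowSums(ref^2)
  for (i in unas) {
    d2 <- ref_norm2 - 2 * as.numeric(ref %*% pc[i, ])
    nn <- order(d2)[seq_len(n_neighbors)]
    votes <- table(ref_geno[nn])
    win <- names(votes)[which.max(votes)]
    if (use_labels) asg$label[i] <- win else asg$genotype[i] <- win
    asg$method[i] <- "neighbor-rescue"
  }
  # keep the component label column consistent with the genotype map
  comp_map <- if (inherits(fit, "genotype_mixture")) fit$component_genotype
  if (!use_labels) {
    if (!is.null(comp_map)) {
      inv <- setNames(names(comp_map), comp_map)
      asg$label[unas] <- unname(inv[asg$genotype[unas]])
    } else {
      asg$label[unas] <- asg$genotype[unas]
    }
  }
  if (inherits(fit, "genotype_mixture")) {
    fit$assignments <- asg
    return(fit)
  }
  asg
}
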