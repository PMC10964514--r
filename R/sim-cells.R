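#' Simulation configuration for a two-genotype organoid co-culture
#'
#' Bundles and validates all parameters of the droplet-data simulator. The
#' defaults describe the study conditions the package targets: 2000 cells of
#' which 10% belong to the minor tumor genotype, 2000 genes with four
#' organoid cell types plus a transcriptionally distinct tumor state,
#' expression-level chromosome-arm CNVs in tumor cells (chr7 gain, chr10
#' loss, the classic glioblastoma pattern), 200 germline SNP sites with a
#' mean of 20 SNP-covering reads per cell, and a 1e-3 per-base miscall rate.
#'
#' @param n_cells number of cells.
#' @param tumor_fraction expected fraction of cells carrying the tumor
#'   genotype (genotype B), in [0, 1].
#' @param n_genes number of genes (includes mitochondrial and ribosomal
#'   genes).
#' @param cell_types data.frame with columns `name`, `proportion`,
#'   `n_markers`, `fold_change`; proportions (over organoid cells) must sum
#'   to 1. Marker genes are disjoint blocks chosen by the simulator and
#'   recorded in the returned truth.
#' @param tumor_markers list with `n_markers` and `fold_change` for the
#'   tumor-genotype expression module.
#' @param cnv_segments data.frame with columns `chrom`, `start_gene`,
#'   `end_gene`, `ratio`; copy-ratio multipliers applied to tumor-cell
#'   expression. `start_gene`/`end_gene` index genes within the chromosome
#'   (genomic order); NA means the whole chromosome. Ratios must be > 0.
#' @param mean_reads_per_cell_at_snps mean TOTAL number of SNP-covering
#'   reads per cell (Poisson); reads are spread over sites multinomially
#'   with uniform weights.
#' @param error_rate per-base miscall probability in [0, 0.5).
#' @param library_size_lognormal c(meanlog, sdlog) of the per-cell library
#'   size distribution.
#' @param dispersion negative-binomial gene-level dispersion (1/size).
#' @param n_mito,n_ribo number of mitochondrial (chrM, `MT-` prefix) and
#'   ribosomal (`RPL`/`RPS` prefix) genes.
#' @param mito_share expected share of counts from mitochondrial genes.
#' @param sample_id sample label stored in the cell metadata.
#' @param seed integer top-level seed; all sub-streams derive from it.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 2000L,
                       tumor_fraction = 0.1,
                       n_genes = 2000L,
                       cell_types = default_cell_types(),
                       tumor_markers = list(n_markers = 50L, fold_change = 4),
                       cnv_segments = default_cnv_segments(),
                       mean_reads_per_cell_at_snps = 20,
                       error_rate = 1e-3,
                       library_size_lognormal = c(log(8000), 0.3),
                       dispersion = 0.1,
                       n_mito = 13L, n_ribo = 40L, mito_share = 0.05,
                       sample_id = "sim1",
                       seed = 1L) {
  if (!is.numeric(n_cells) || n_cells < 1)
    stop("'n_cells' must be >= 1", call. = FALSE)
  if (!is.numeric(n_genes) || n_genes < 1)
    stop("'n_genes' must be >= 1", call. = FALSE)
  stopifnot_scalar_prob(tumor_fraction, "tumor_fraction")
  stopifnot_scalar_prob(error_rate, "error_rate", allow_one = FALSE)
  if (error_rate >= 0.5)
    stop("'error_rate' must be < 0.5", call. = FALSE)
  if (abs(sum(cell_types$proportion) - 1) > 1e-8)
    stop("cell-type proportions must sum to 1", call. = FALSE)
  if (!is.null(cnv_segments) && nrow(cnv_segments) &&
      any(cnv_segments$ratio <= 0))
    stop("CNV copy ratios must be > 0", call. = FALSE)
  if (mean_reads_per_cell_at_snps <= 0)
    stop("'mean_reads_per_cell_at_snps' must be positive", call. = FALSE)
  structure(list(
    n_cells = as.integer(n_cells), tumor_fraction = tumor_fraction,
    n_genes = as.integer(n_genes), cell_types = cell_types,
    tumor_markers = tumor_markers, cnv_segments = cnv_segments,
    mean_reads_per_cell_at_snps = mean_reads_per_cell_at_snps,
    error_rate = error_rate,
    library_size_lognormal = library_size_lognormal,
    dispersion = dispersion, n_mito = as.integer(n_mito),
    n_ribo = as.integer(n_ribo), mito_share = mito_share,
    sample_id = sample_id, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_cell_types <- function() {
  data.frame(
    name = c("radial_glia", "excitatory_neurons", "astrocytes", "inn_npc"),
    proportion = c(0.35, 0.30, 0.20, 0.15),
    n_markers = c(40L, 40L, 40L, 40L),
    fold_change = c(6, 6, 6, 6),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
default_cnv_segments <- function() {
  data.frame(chrom = c("chr7", "chr10"),
             start_gene = NA_integer_, end_gene = NA_integer_,
             ratio = c(1.5, 0.5), stringsAsFactors = FALSE)
}

#' Simulate droplet single-cell data for a two-genotype co-culture
#'
#' Draws a gene-by-cell count matrix and a per-cell SNP allele-count matrix
#' with known ground truth. Expression is negative-binomial around a
#' cell-type-specific mean (marker-gene fold changes; tumor cells carry an
#' additional marker module and have genes inside CNV segments scaled by the
#' copy ratio). SNP coverage per cell is Poisson in total and multinomial
#' (uniform) over sites; alt read counts are binomial with success
#' probability equal to the genotype's allele fraction blended with the
#' sequencing error rate.
#'
#' @param genotypes a [make_genotypes()] `genotype_pair`; genotype B plays
#'   the tumor genotype.
#' @param config a [sim_config()].
#'
#' @param gene_model optional precomputed [make_gene_model()] result; pass
#'   the same model to several calls to simulate samples of a cohort that
#'   share their gene structure (required before combining samples).
#' @return list with `sce` (a
#'   [SingleCellExperiment::SingleCellExperiment] with assay `counts`,
#'   rowData `symbol`/`chrom`/`pos`/`mito`/`ribo`, colData
#'   `barcode`/`sample`), `allele_counts` (class `allele_counts`), and
#'   `truth` (class `sim_truth`: per-cell genotype and cell-type labels,
#'   marker-gene assignments, resolved CNV gene indices, the genotype pair
#'   and the config).
#' @export
simulate_cells <- function(genotypes, config = sim_config(),
                           gene_model = NULL) {
  stopifnot(inherits(genotypes, "genotype_pair"),
            inherits(config, "sim_config"))
  n_cells <- config$n_cells
  n_genes <- config$n_genes
  if (n_cells < 1 || n_genes < 1)
    stop("need at least one cell and one gene", call. = FALSE)

  if (is.null(gene_model)) gene_model <- make_gene_model(config)
  genes <- gene_model$genes
  marker_genes <- gene_model$marker_genes
  tumor_marker_genes <- gene_model$tumor_marker_genes
  cnv_gene_idx <- gene_model$cnv_gene_idx
  abund <- gene_model$abund

  set.seed(derive_seed(config$seed, 212L))
  # per-cell labels
  is_tumor <- runif(n_cells) < config$tumor_fraction
  cell_type <- character(n_cells)
  n_org <- sum(!is_tumor)
  if (n_org > 0)
    cell_type[!is_tumor] <- sample(config$cell_types$name, n_org,
                                   replace = TRUE,
                                   prob = config$cell_types$proportion)
  cell_type[is_tumor] <- "tumor"
  barcodes <- sprintf("cell_%04d", seq_len(n_cells))

  # one expression profile per (cell type x genotype) combination
  profile_for <- function(type, tumor) {
    fc <- rep(1, n_genes)
    if (type != "tumor")
      fc[marker_genes[[type]]] <- config$cell_types$fold_change[
        match(type, config$cell_types$name)]
    if (tumor) {
      fc[tumor_marker_genes] <- config$tumor_markers$fold_change
      for (j in seq_along(cnv_gene_idx))
        fc[cnv_gene_idx[[j]]] <- fc[cnv_gene_idx[[j]]] *
          config$cnv_segments$ratio[j]
    }
    p <- abund * fc
    p / sum(p)
  }

  lib <- rlnorm(n_cells, config$library_size_lognormal[1],
                config$library_size_lognormal[2])
  counts <- matrix(0L, n_genes, n_cells)
  size <- 1 / config$dispersion
  groups <- unique(data.frame(type = cell_type, tumor = is_tumor))
  for (r in seq_len(nrow(groups))) {
    sel <- which(cell_type == groups$type[r] & is_tumor == groups$tumor[r])
    prof <- profile_for(groups$type[r], groups$tumor[r])
    mu <- outer(prof, lib[sel])
    counts[, sel] <- rnbinom(length(mu), mu = mu, size = size)
  }
  dimnames(counts) <- list(genes$symbol, barcodes)

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                       "CsparseMatrix")),
    rowData = S4Vectors::DataFrame(symbol = genes$symbol, chrom = genes$chrom,
                                   pos = genes$pos, mito = genes$mito,
                                   ribo = genes$ribo, row.names = genes$symbol),
    colData = S4Vectors::DataFrame(barcode = barcodes,
                                   sample = config$sample_id,
                                   row.names = barcodes))

  ac <- simulate_allele_counts(genotypes, is_tumor, barcodes,
                               config$mean_reads_per_cell_at_snps,
                               config$error_rate,
                               derive_seed(config$seed, 223L))

  truth <- structure(list(
    barcode = barcodes,
    genotype = ifelse(is_tumor, "B", "A"),
    is_tumor = is_tumor,
    cell_type = cell_type,
    marker_genes = lapply(marker_genes, function(i) genes$symbol[i]),
    tumor_marker_genes = genes$symbol[tumor_marker_genes],
    cnv_gene_idx = cnv_gene_idx,
    tumor_fraction = mean(is_tumor),
    genotypes = genotypes,
    config = config
  ), class = "sim_truth")

  list(sce = sce, allele_counts = ac, truth = truth)
}

#' Build the shared gene model of a simulated cohort
#'
#' Draws the gene table (symbols, genomic coordinates, mitochondrial and
#' ribosomal flags), the relative gene abundances, the disjoint marker
#' modules for each cell type plus the tumor module, and the resolved CNV
#' gene indices. Samples of one cohort must share a gene model so their
#' matrices can be combined.
#'
#' @param config a [sim_config()]; the model derives its randomness from
#'   `config$seed` unless `seed` is given.
#' @param seed optional override seed.
#' @return list with `genes`, `abund`, `marker_genes` (index list per cell
#'   type), `tumor_marker_genes`, `cnv_gene_idx`.
#' @export
make_gene_model <- function(config, seed = config$seed) {
  set.seed(derive_seed(seed, 211L))
  genes <- make_gene_table(config)
  n_genes <- config$n_genes

  # marker modules: disjoint blocks among plain (non-mito, non-ribo) genes
  plain <- which(!genes$mito & !genes$ribo)
  need <- sum(config$cell_types$n_markers) + config$tumor_markers$n_markers
  if (need > length(plain))
    stop("not enough non-flagged genes for the requested marker modules",
         call. = FALSE)
  pool <- sample(plain, need)
  marker_genes <- vector("list", nrow(config$cell_types))
  off <- 0L
  for (k in seq_len(nrow(config$cell_types))) {
    nk <- config$cell_types$n_markers[k]
    marker_genes[[k]] <- sort(pool[off + seq_len(nk)])
    off <- off + nk
  }
  tumor_marker_genes <- sort(pool[off + seq_len(config$tumor_markers$n_markers)])
  names(marker_genes) <- config$cell_types$name

  # relative gene abundances; mitochondrial genes pinned to their share
  abund <- rlnorm(n_genes, 0, 1)
  if (config$n_mito > 0 && config$mito_share > 0) {
    m <- genes$mito
    abund[m] <- abund[m] * (config$mito_share / (1 - config$mito_share)) *
      sum(abund[!m]) / sum(abund[m])
  }

  list(genes = genes, abund = abund, marker_genes = marker_genes,
       tumor_marker_genes = tumor_marker_genes,
       cnv_gene_idx = resolve_cnv_segments(config$cnv_segments, genes))
}

make_gene_table <- function(config) {
  n <- config$n_genes
  n_mito <- min(config$n_mito, n)
  n_auto <- n - n_mito
  chroms <- paste0("chr", 1:22)
  chrom <- sort(factor(rep_len(chroms, n_auto), levels = chroms))
  pos <- unlist(lapply(split(seq_len(n_auto), chrom),
                       function(ix) sort(sample.int(2e8L, length(ix)))),
                use.names = FALSE)
  ribo <- rep(FALSE, n_auto)
  if (config$n_ribo > 0 && n_auto > 0)
    ribo[sample.int(n_auto, min(config$n_ribo, n_auto))] <- TRUE
  sym <- character(n_auto)
  sym[!ribo] <- sprintf("G%04d", seq_len(sum(!ribo)))
  half <- sum(ribo) %/% 2
  sym[ribo] <- c(sprintf("RPL%d", seq_len(half)),
                 sprintf("RPS%d", seq_len(sum(ribo) - half)))
  out <- data.frame(symbol = sym, chrom = as.character(chrom), pos = pos,
                    mito = FALSE, ribo = ribo, stringsAsFactors = FALSE)
  if (n_mito > 0) {
    out <- rbind(out, data.frame(
      symbol = sprintf("MT-G%d", seq_len(n_mito)), chrom = "chrM",
      pos = seq_len(n_mito) * 1000L, mito = TRUE, ribo = FALSE,
      stringsAsFactors = FALSE))
  }
  out
}

resolve_cnv_segments <- function(cnv_segments, genes) {
  if (is.null(cnv_segments) || !nrow(cnv_segments)) return(list())
  lapply(seq_len(nrow(cnv_segments)), function(j) {
    on_chr <- which(genes$chrom == cnv_segments$chrom[j])
    a <- cnv_segments$start_gene[j]
    b <- cnv_segments$end_gene[j]
    if (is.na(a)) a <- 1L
    if (is.na(b)) b <- length(on_chr)
    on_chr[seq.int(a, min(b, length(on_chr)))]
  })
}

simulate_allele_counts <- function(genotypes, is_tumor, barcodes,
                                   mean_reads, error_rate, seed) {
  set.seed(seed)
  n_snps <- nrow(genotypes$sites)
  n_cells <- length(is_tumor)
  vaf_a <- geno_vaf(genotypes$geno_a)
  vaf_b <- geno_vaf(genotypes$geno_b)
  ii <- jj <- integer(0); rr <- aa <- integer(0)
  for (c_ in seq_len(n_cells)) {
    n_reads <- rpois(1L, mean_reads)
    if (n_reads == 0L) next
    cov <- tabulate(sample.int(n_snps, n_reads, replace = TRUE), n_snps)
    covered <- which(cov > 0L)
    vaf <- if (is_tumor[c_]) vaf_b[covered] else vaf_a[covered]
    p <- vaf * (1 - error_rate) + (1 - vaf) * error_rate
    alt <- rbinom(length(covered), cov[covered], p)
    ii <- c(ii, covered); jj <- c(jj, rep.int(c_, length(covered)))
    aa <- c(aa, alt); rr <- c(rr, cov[covered] - alt)
  }
  allele_counts(sites = genotypes$sites, barcodes = barcodes,
                ref = Matrix::sparseMatrix(i = ii, j = jj, x = rr,
                                           dims = c(n_snps, n_cells)),
                alt = Matrix::sparseMatrix(i = ii, j = jj, x = aa,
                                           dims = c(n_snps, n_cells)))
}

#' Per-cell SNP allele-count container
#'
#' @param sites data.frame with columns chrom, pos, ref, alt (unique keys).
#' @param barcodes cell barcodes (columns).
#' @param ref,alt sparse sites-by-cells matrices of reference / alternate
#'   read counts.
#' @return object of class `allele_counts`.
#' @export
allele_counts <- function(sites, barcodes, ref, alt) {
  stopifnot(nrow(sites) == nrow(ref), nrow(ref) == nrow(alt),
            ncol(ref) == length(barcodes), ncol(alt) == length(barcodes))
  if (any(ref@x < 0) || any(alt@x < 0))
    stop("allele counts must be non-negative", call. = FALSE)
  key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  if (anyDuplicated(key))
    stop("duplicate SNP site keys", call. = FALSE)
  dimnames(ref) <- dimnames(alt) <- list(key, barcodes)
  structure(list(sites = sites, barcodes = barcodes, ref = ref, alt = alt),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("allele_counts:", nrow(x$sites), "sites x", length(x$barcodes),
      "cells;", sum(x$ref@x + x$alt@x), "reads total\n")
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$barcode), "cells;",
      sum(x$is_tumor), "tumor (realized fraction",
      signif(x$tumor_fraction, 3), ")\n")
  invisible(x)
}
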