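# Shared fixtures. Heavy objects (the full default simulation and its
# demultiplexing run) are built lazily once per session and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .cache)) assign(key, build(), envir = .cache)
  get(key, envir = .cache)
}

# the study-default simulation: 2000 cells, 10% tumor, 200 SNPs with 10%
# exclusive per genotype, 20 SNP reads/cell, error 1e-3
default_sim <- function() {
  cached("default_sim", function() {
    gp <- make_genotypes(200, 0.1, seed = 1)
    sim <- simulate_cells(gp, sim_config(seed = 1))
    list(gp = gp, sim = sim)
  })
}

# the full in-silico genotyping run on the default simulation:
# mixture fit, CNV component naming, neighbor rescue
default_demux <- function() {
  cached("default_demux", function() {
    d <- default_sim()
    fit <- fit_two_genotype_mixture(d$sim$allele_counts, seed = 1)
    sce <- normalize_counts(d$sim$sce)
    cnv <- suppressWarnings(infer_cnv(sce, seq_len(ncol(sce))))
    labeled <- label_components_by_cnv(fit, cnv)
    full <- rescue_unassigned(labeled, sce)
    list(fit = fit, cnv = cnv, labeled = labeled, full = full, sce = sce)
  })
}

# small SCE built from an explicit dense count matrix
toy_sce <- function(counts, chrom = NULL, pos = NULL, mito = NULL,
                    ribo = NULL) {
  n_genes <- nrow(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%03d", seq_len(n_genes))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                       "CsparseMatrix")),
    rowData = S4Vectors::DataFrame(
      symbol = rownames(counts),
      chrom = chrom %||% rep("chr1", n_genes),
      pos = pos %||% seq_len(n_genes) * 1000L,
      mito = mito %||% rep(FALSE, n_genes),
      ribo = ribo %||% rep(FALSE, n_genes),
      row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(barcode = colnames(counts),
                                   sample = "toy",
                                   row.names = colnames(counts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny allele_counts built from explicit dense ref/alt matrices (sites x cells)
toy_allele_counts <- function(ref, alt) {
  n <- nrow(ref)
  sites <- data.frame(chrom = "chr1", pos = seq_len(n) * 100L,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  allele_counts(sites = sites,
                barcodes = sprintf("c%02d", seq_len(ncol(ref))),
                ref = methods::as(Matrix::Matrix(ref, sparse = TRUE),
                                  "CsparseMatrix"),
                alt = methods::as(Matrix::Matrix(alt, sparse = TRUE),
                                  "CsparseMatrix"))
}

# brute-force oracle for the two-component mixture on tiny instances:
# maximum complete-data log-likelihood over every diploid-state
# configuration of both components and every hard cell partition, with
# mixing proportions at their partition MLE
bf_mixture_loglik <- function(ac, error_rate = 1e-3) {
  A <- as.matrix(ac$alt); R <- as.matrix(ac$ref)
  S <- nrow(A); C <- ncol(A)
  states <- c(error_rate, 0.5, 1 - error_rate)
  state_grid <- as.matrix(expand.grid(rep(list(1:3), S)))
  # per cell, log-lik under each single-component state configuration
  cell_ll <- function(theta) colSums(A * log(theta) + R * log1p(-theta))
  config_ll <- apply(state_grid, 1L, function(ix) cell_ll(states[ix]))
  if (C == 1) config_ll <- matrix(config_ll, nrow = 1)  # cells x configs
  best <- -Inf
  for (mask in 0:(2^C - 1)) {
    g <- as.integer(intToBits(mask))[seq_len(C)]  # 0 = comp2, 1 = comp1
    n1 <- sum(g)
    lp <- c(if (n1 > 0) log(n1 / C) else 0,
            if (C - n1 > 0) log((C - n1) / C) else 0)
    ll1 <- if (n1 > 0)
      max(colSums(config_ll[g == 1, , drop = FALSE])) + n1 * lp[1]
    else 0
    ll2 <- if (C - n1 > 0)
      max(colSums(config_ll[g == 0, , drop = FALSE])) + (C - n1) * lp[2]
    else 0
    best <- max(best, ll1 + ll2)
  }
  best
}

# accuracy of component labels against simulated truth, up to the
# inherent component permutation
accuracy_up_to_permutation <- function(labels, is_tumor) {
  use <- labels %in% c("A", "B")
  acc <- mean((labels[use] == "B") == is_tumor[use])
  max(acc, 1 - acc)
}
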