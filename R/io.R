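#' Write / read a count matrix as MatrixMarket + TSV sidecars
#'
#' Writes `matrix.mtx` (genes x cells), `genes.tsv` (gene, chrom, pos and
#' any flags) and `barcodes.tsv` into `dir`; `read_counts_mtx()` restores a
#' SingleCellExperiment from such a directory.
#'
#' @param sce SingleCellExperiment with a raw `counts` assay.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; `read_counts_mtx()` returns a
#'   SingleCellExperiment.
#' @export
write_counts_mtx <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- get_counts(sce)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  rd <- as.data.frame(SummarizedExperiment::rowData(sce))
  if (!"symbol" %in% names(rd)) rd$symbol <- rownames(sce)
  write.table(rd, file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(genes$symbol, barcodes)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(genes, row.names = genes$symbol),
    colData = S4Vectors::DataFrame(barcode = barcodes,
                                   row.names = barcodes))
}

#' Write / read per-cell allele counts as long-format TSV
#'
#' Columns: barcode, chrom, pos, ref, alt, ref_count, alt_count; one row
#' per (cell, covered site).
#'
#' @param ac an [allele_counts()] object.
#' @param path TSV path.
#' @return `path` invisibly; the reader returns an `allele_counts`.
#' @export
write_allele_counts <- function(ac, path) {
  idx <- Matrix::which(ac$ref + ac$alt > 0, arr.ind = TRUE)
  out <- data.frame(barcode = ac$barcodes[idx[, 2]],
                    ac$sites[idx[, 1], c("chrom", "pos", "ref", "alt")],
                    ref_count = ac$ref[idx], alt_count = ac$alt[idx],
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_allele_counts
#' @param sites optional full site table (data.frame chrom/pos/ref/alt) so
#'   uncovered sites are preserved; defaults to the sites seen in the file.
#' @param barcodes optional full barcode vector.
#' @export
read_allele_counts <- function(path, sites = NULL, barcodes = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(sites))
    sites <- unique(tab[, c("chrom", "pos", "ref", "alt")])
  if (is.null(barcodes)) barcodes <- unique(tab$barcode)
  site_key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  i <- match(paste(tab$chrom, tab$pos, tab$ref, tab$alt), site_key)
  j <- match(tab$barcode, barcodes)
  if (anyNA(i) || anyNA(j))
    stop("allele-count rows outside the provided sites/barcodes",
         call. = FALSE)
  dims <- c(nrow(sites), length(barcodes))
  allele_counts(sites = sites, barcodes = barcodes,
                ref = Matrix::sparseMatrix(i = i, j = j, x = tab$ref_count,
                                           dims = dims),
                alt = Matrix::sparseMatrix(i = i, j = j, x = tab$alt_count,
                                           dims = dims))
}

#' Write a genotype pair as two VCF v4.2 files
#'
#' Emits one single-sample VCF per genotype with GT and DP fields (a
#' constant nominal depth, since the simulator models genotypes, not
#' reads), suitable as input to [build_fingerprints()].
#'
#' @param genotypes a `genotype_pair`.
#' @param dir output directory.
#' @param names file base names for the two genotypes.
#' @param depth nominal DP written to every record.
#' @param qual nominal QUAL.
#' @return character vector of the two file paths, invisibly.
#' @export
write_genotype_vcfs <- function(genotypes, dir, names = c("genoA", "genoB"),
                                depth = 50L, qual = 100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(names, ".vcf"))
  gts <- c("0/0", "0/1", "1/1")
  for (k in 1:2) {
    geno <- if (k == 1) genotypes$geno_a else genotypes$geno_b
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=glicomix",
      paste0("##contig=<ID=", unique(genotypes$sites$chrom), ">"),
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names[k], sep = "\t"))
    body <- with(genotypes$sites, paste(
      chrom, pos, ".", ref, alt, qual, "PASS", ".", "GT:DP",
      paste0(gts[geno + 1L], ":", depth), sep = "\t"))
    writeLines(c(header, body), paths[k])
  }
  invisible(paths)
}

#' Write / read bulk allele counts as TSV
#'
#' @param bulk data.frame chrom, pos, ref, alt, ref_count, alt_count.
#' @param path TSV path.
#' @export
write_bulk_counts <- function(bulk, path) {
  write.table(bulk, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bulk_counts
#' @export
read_bulk_counts <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a fingerprint panel as BED-like TSV files
#'
#' One file per genotype with 0-based half-open coordinates plus alleles
#' and zygosity.
#'
#' @param panel a `fingerprint_panel`.
#' @param dir output directory.
#' @return the two paths, invisibly.
#' @export
write_fingerprint_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("panel_a.bed.tsv", "panel_b.bed.tsv"))
  for (k in 1:2) {
    s <- if (k == 1) panel$a else panel$b
    out <- data.frame(chrom = s$chrom, start = s$pos - 1L, end = s$pos,
                      ref = s$ref, alt = s$alt, zygosity = s$zygosity,
                      stringsAsFactors = FALSE)
    write.table(out, paths[k], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Write simulation truth as TSV + JSON
#'
#' Per-cell labels go to `<base>_cells.tsv`; scalar truths (realized tumor
#' fraction, marker-module membership, CNV gene indices) to `<base>.json`.
#'
#' @param truth a `sim_truth`.
#' @param base output path prefix.
#' @return the two paths, invisibly.
#' @export
write_truth <- function(truth, base) {
  cells <- data.frame(barcode = truth$barcode, genotype = truth$genotype,
                      is_tumor = truth$is_tumor, cell_type = truth$cell_type,
                      stringsAsFactors = FALSE)
  tsv <- paste0(base, "_cells.tsv")
  json <- paste0(base, ".json")
  write.table(cells, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    tumor_fraction = truth$tumor_fraction,
    marker_genes = truth$marker_genes,
    tumor_marker_genes = truth$tumor_marker_genes,
    cnv_gene_idx = truth$cnv_gene_idx
  ), json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
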