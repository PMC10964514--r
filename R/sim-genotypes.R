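#' Simulate a pair of germline genotypes with mutually exclusive SNPs
#'
#' Generates two diploid genotypes over a shared panel of biallelic SNP sites.
#' Most sites carry identical genotypes in both; a configurable fraction is
#' exclusive to each genotype (alt-carrying in exactly one, hom-ref in the
#' other). These exclusive sites are the germline SNP "fingerprints" that let
#' a minor genotype be detected and quantified in mixed bulk DNA.
#'
#' @param n_snps number of biallelic SNP sites (>= 1).
#' @param exclusive_fraction fraction of sites exclusive to EACH genotype,
#'   in (0, 0.5]. Each genotype receives `round(exclusive_fraction * n_snps)`
#'   exclusive sites; the two sets are disjoint.
#' @param seed integer seed; the same seed reproduces the same pair exactly.
#' @param zygosity_probs probabilities that an exclusive site is het vs
#'   hom-alt in its owning genotype (default 0.7 / 0.3, a realistic germline
#'   composition).
#' @param shared_probs genotype frequencies (hom-ref, het, hom-alt) at shared
#'   sites, copied into both genotypes.
#'
#' @return an object of class `genotype_pair`: a list with `sites`
#'   (data.frame chrom/pos/ref/alt), integer vectors `geno_a`, `geno_b`
#'   (alt-allele dosage 0/1/2), and index vectors `exclusive_a`,
#'   `exclusive_b`.
#' @export
make_genotypes <- function(n_snps, exclusive_fraction = 0.1, seed = 1L,
                           zygosity_probs = c(het = 0.7, hom_alt = 0.3),
                           shared_probs = c(hom_ref = 0.5, het = 0.35,
                                            hom_alt = 0.15)) {
  if (!is.numeric(n_snps) || length(n_snps) != 1L || n_snps < 1)
    stop("'n_snps' must be a positive integer", call. = FALSE)
  n_snps <- as.integer(n_snps)
  if (!is.numeric(exclusive_fraction) || length(exclusive_fraction) != 1L ||
      exclusive_fraction <= 0 || exclusive_fraction > 0.5)
    stop("'exclusive_fraction' must lie in (0, 0.5]", call. = FALSE)
  n_ex <- round(exclusive_fraction * n_snps)
  if (n_ex < 1)
    stop("'exclusive_fraction' too small: no exclusive sites at n_snps = ",
         n_snps, call. = FALSE)
  if (2L * n_ex > n_snps)
    stop("exclusive sets would overlap: 2 * round(exclusive_fraction * n_snps)",
         " exceeds n_snps", call. = FALSE)

  set.seed(derive_seed(seed, 101L))
  chroms <- paste0("chr", 1:22)
  chrom <- sort(rep_len(chroms, n_snps))
  # order by chromosome number, positions increasing within chromosome
  chrom <- chrom[order(match(chrom, chroms))]
  pos <- unlist(lapply(split(seq_len(n_snps), factor(chrom, levels = chroms)),
                       function(ix) sort(sample.int(2e8L, length(ix)))),
                use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  ex_pool <- sample.int(n_snps, 2L * n_ex)
  exclusive_a <- sort(ex_pool[seq_len(n_ex)])
  exclusive_b <- sort(ex_pool[n_ex + seq_len(n_ex)])

  geno_a <- geno_b <- integer(n_snps)
  shared <- setdiff(seq_len(n_snps), ex_pool)
  g_shared <- sample(0:2, length(shared), replace = TRUE, prob = shared_probs)
  geno_a[shared] <- g_shared
  geno_b[shared] <- g_shared
  draw_zyg <- function(n) sample(1:2, n, replace = TRUE, prob = zygosity_probs)
  geno_a[exclusive_a] <- draw_zyg(n_ex)
  geno_b[exclusive_b] <- draw_zyg(n_ex)

  structure(list(
    sites = data.frame(chrom = chrom, pos = pos, ref = unname(ref),
                       alt = unname(alt), stringsAsFactors = FALSE),
    geno_a = geno_a, geno_b = geno_b,
    exclusive_a = exclusive_a, exclusive_b = exclusive_b,
    seed = seed
  ), class = "genotype_pair")
}

#' @export
print.genotype_pair <- function(x, ...) {
  cat("genotype_pair:", nrow(x$sites), "biallelic SNP sites\n")
  cat("  exclusive to A:", length(x$exclusive_a),
      "| exclusive to B:", length(x$exclusive_b),
      "| shared:", nrow(x$sites) - length(x$exclusive_a) -
        length(x$exclusive_b), "\n")
  invisible(x)
}

# alt-allele fraction implied by a diploid dosage vector
geno_vaf <- function(geno) geno / 2
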