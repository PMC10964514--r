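#' Simulate bulk allele counts for a genotype mixture
#'
#' Emulates whole-exome allele counts at the germline SNP panel for a DNA
#' sample that is a mixture of the two genotypes. Per site, sequencing depth
#' is Poisson and the alternate read count is binomial with success
#' probability equal to the mixture-weighted allele fraction blended with
#' the error rate.
#'
#' @param genotypes a [make_genotypes()] `genotype_pair`.
#' @param fraction_b mixture fraction of genotype B (the tumor genotype),
#'   in [0, 1].
#' @param mean_depth mean per-site sequencing depth (> 0).
#' @param error_rate per-base miscall probability.
#' @param seed integer seed.
#'
#' @return list with `bulk` (data.frame chrom, pos, ref, alt, ref_count,
#'   alt_count) and `truth` (list with `fraction_b`).
#' @export
simulate_bulk_mixture <- function(genotypes, fraction_b, mean_depth = 100,
                                  error_rate = 1e-3, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_pair"))
  stopifnot_scalar_prob(fraction_b, "fraction_b")
  if (!is.numeric(mean_depth) || mean_depth <= 0)
    stop("'mean_depth' must be positive", call. = FALSE)
  stopifnot_scalar_prob(error_rate, "error_rate", allow_one = FALSE)

  set.seed(derive_seed(seed, 307L))
  n <- nrow(genotypes$sites)
  vaf <- (1 - fraction_b) * geno_vaf(genotypes$geno_a) +
    fraction_b * geno_vaf(genotypes$geno_b)
  p <- vaf * (1 - error_rate) + (1 - vaf) * error_rate
  depth <- rpois(n, mean_depth)
  alt <- rbinom(n, depth, p)
  bulk <- data.frame(genotypes$sites,
                     ref_count = depth - alt, alt_count = alt,
                     stringsAsFactors = FALSE)
  list(bulk = bulk, truth = list(fraction_b = fraction_b))
}

#' Simulate an age-graded bulk reference expression series
#'
#' Generates bulk profiles across developmental ages in which each age owns
#' a module of genes whose mean expression follows a unimodal (Gaussian)
#' trajectory peaking at that age, plus lognormal noise and Poisson counts.
#' Used as a stand-in for an age-annotated developmental reference atlas
#' when testing pseudo-bulk staging.
#'
#' @param ages numeric vector of at least 2 distinct ages (e.g. weeks post
#'   conception) defining the age groups.
#' @param n_genes number of genes.
#' @param n_age_modules number of age-peaked gene modules; defaults to one
#'   per distinct age. 0 yields exchangeable (structureless) profiles.
#' @param seed integer seed.
#' @param n_replicates reference samples per age.
#' @param query_ages optional ages at which to draw additional query
#'   profiles from the same generative model (same gene modules).
#' @param module_size genes per age module.
#' @param amplitude peak fold increase of module genes at their age.
#' @param width Gaussian width of the trajectory, in age units; defaults to
#'   half the median age spacing.
#' @param noise_sd sdlog of the lognormal sample-level noise.
#' @param depth expected total counts per sample.
#'
#' @return object of class `reference_series`: list with `counts` (genes x
#'   samples), `ages` (per sample), `query_counts`/`query_ages` (NULL when
#'   no queries requested) and `modules` (gene index list per module age).
#' @export
simulate_reference_series <- function(ages, n_genes = 2000L,
                                      n_age_modules = NULL, seed = 1L,
                                      n_replicates = 3L, query_ages = NULL,
                                      module_size = 50L, amplitude = 3,
                                      width = NULL, noise_sd = 0.15,
                                      depth = 1e6) {
  uages <- sort(unique(ages))
  if (length(uages) < 2)
    stop("need at least 2 distinct ages", call. = FALSE)
  if (is.null(n_age_modules)) n_age_modules <- length(uages)
  if (is.null(width)) width <- median(diff(uages)) / 2

  set.seed(derive_seed(seed, 401L))
  base <- rlnorm(n_genes, 2, 1)
  peak_ages <- if (n_age_modules > 0)
    uages[round(seq(1, length(uages), length.out = n_age_modules))]
  else numeric(0)
  modules <- list()
  free <- seq_len(n_genes)
  for (a in peak_ages) {
    take <- sample(free, min(module_size, length(free)))
    modules[[as.character(a)]] <- take
    free <- setdiff(free, take)
  }

  mean_at_age <- function(age) {
    m <- base
    for (a in names(modules))
      m[modules[[a]]] <- m[modules[[a]]] *
        (1 + amplitude * exp(-(age - as.numeric(a))^2 / (2 * width^2)))
    m / sum(m)
  }

  draw <- function(age_vec) {
    mat <- vapply(age_vec, function(a) {
      mu <- mean_at_age(a) * rlnorm(n_genes, 0, noise_sd)
      rpois(n_genes, depth * mu / sum(mu))
    }, numeric(n_genes))
    rownames(mat) <- sprintf("G%04d", seq_len(n_genes))
    mat
  }

  sample_ages <- rep(ages, each = n_replicates)
  counts <- draw(sample_ages)
  colnames(counts) <- sprintf("ref_%02d", seq_along(sample_ages))
  qc <- qa <- NULL
  if (!is.null(query_ages) && length(query_ages)) {
    qc <- draw(query_ages)
    colnames(qc) <- sprintf("query_%02d", seq_along(query_ages))
    qa <- query_ages
  }
  structure(list(counts = counts, ages = sample_ages,
                 query_counts = qc, query_ages = qa,
                 modules = modules, seed = seed),
            class = "reference_series")
}

#' @export
print.reference_series <- function(x, ...) {
  cat("reference_series:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples over ages", paste(sort(unique(x$ages)), collapse = ", "), "\n")
  invisible(x)
}
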