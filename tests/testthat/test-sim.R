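test_that("exclusive SNP sets have the configured size and are disjoint", {
  gp <- make_genotypes(10, 0.2, seed = 3)
  expect_length(gp$exclusive_a, 2)
  expect_length(gp$exclusive_b, 2)
  expect_length(intersect(gp$exclusive_a, gp$exclusive_b), 0)
  # exclusive sites are alt-carrying in the owner, hom-ref in the other
  expect_true(all(gp$geno_a[gp$exclusive_a] > 0))
  expect_true(all(gp$geno_b[gp$exclusive_a] == 0))
  expect_true(all(gp$geno_b[gp$exclusive_b] > 0))
  expect_true(all(gp$geno_a[gp$exclusive_b] == 0))
  # shared sites carry identical genotypes
  shared <- setdiff(seq_len(10), c(gp$exclusive_a, gp$exclusive_b))
  expect_equal(gp$geno_a[shared], gp$geno_b[shared])
})

test_that("exclusive fraction 0.5 partitions all sites into the two panels", {
  gp <- make_genotypes(10, 0.5, seed = 1)
  expect_setequal(c(gp$exclusive_a, gp$exclusive_b), 1:10)
})

test_that("genotype generation is deterministic given the seed", {
  expect_identical(make_genotypes(50, 0.1, seed = 7),
                   make_genotypes(50, 0.1, seed = 7))
  expect_false(identical(make_genotypes(50, 0.1, seed = 7),
                         make_genotypes(50, 0.1, seed = 8)))
})

test_that("invalid genotype parameters are rejected", {
  expect_error(make_genotypes(10, 0), "exclusive_fraction")
  expect_error(make_genotypes(10, 0.6), "exclusive_fraction")
  expect_error(make_genotypes(0, 0.1), "n_snps")
})

test_that("tumor fraction zero yields an all-organoid cohort", {
  gp <- make_genotypes(20, 0.1, seed = 1)
  sim <- simulate_cells(gp, sim_config(n_cells = 50, n_genes = 300,
                                       tumor_fraction = 0, seed = 2))
  expect_true(all(sim$truth$genotype == "A"))
  expect_false(any(sim$truth$cell_type == "tumor"))
})

test_that("error-free hom-ref sites never yield alt reads", {
  gp <- make_genotypes(30, 0.1, seed = 4)
  sim <- simulate_cells(gp, sim_config(n_cells = 100, n_genes = 300,
                                       tumor_fraction = 0, error_rate = 0,
                                       mean_reads_per_cell_at_snps = 50,
                                       seed = 3))
  hom_ref_a <- which(gp$geno_a == 0)
  expect_true(all(sim$allele_counts$alt[hom_ref_a, ] == 0))
})

test_that("cross-genotype error reads match the closed-form expectation", {
  # a genotype-A cell sees alt reads at B-exclusive hom-ref sites only
  # through miscalls: expected per-cell count is
  # coverage x exclusive-site fraction x error_rate
  err <- 0.01  # raised so the expectation is resolvable at 1000 cells
  gp <- make_genotypes(200, 0.1, seed = 5)
  small_types <- data.frame(name = c("x", "y"), proportion = c(0.6, 0.4),
                          n_markers = c(3L, 3L), fold_change = c(4, 4))
  sim <- simulate_cells(gp, sim_config(n_cells = 1000, n_genes = 50,
                                       tumor_fraction = 0, error_rate = err,
                                       mean_reads_per_cell_at_snps = 20,
                                       cell_types = small_types,
                                       tumor_markers = list(n_markers = 2L,
                                                            fold_change = 2),
                                       cnv_segments = NULL,
                                       n_mito = 3L, n_ribo = 5L,
                                       seed = 6))
  b_excl_homref <- gp$exclusive_b  # hom-ref in genotype A
  per_cell <- Matrix::colSums(sim$allele_counts$alt[b_excl_homref, ])
  expected <- 20 * (length(b_excl_homref) / 200) * err
  se <- sd(per_cell) / sqrt(length(per_cell))
  expect_lt(abs(mean(per_cell) - expected), 3 * se + 1e-12)
})

test_that("realized tumor fraction matches the configured fraction", {
  gp <- make_genotypes(20, 0.1, seed = 1)
  small_types <- data.frame(name = c("x", "y"), proportion = c(0.6, 0.4),
                          n_markers = c(3L, 3L), fold_change = c(4, 4))
  sim <- simulate_cells(gp, sim_config(n_cells = 2000, n_genes = 100,
                                       tumor_fraction = 0.1,
                                       cell_types = small_types,
                                       tumor_markers = list(n_markers = 2L,
                                                            fold_change = 2),
                                       cnv_segments = NULL, seed = 9))
  se <- sqrt(0.1 * 0.9 / 2000)
  expect_lt(abs(mean(sim$truth$is_tumor) - 0.1), 4 * se)
  expect_equal(sim$truth$tumor_fraction, mean(sim$truth$is_tumor))
})

test_that("cell simulation is deterministic given the seed", {
  gp <- make_genotypes(20, 0.1, seed = 1)
  small_types <- data.frame(name = c("x", "y"), proportion = c(0.6, 0.4),
                          n_markers = c(3L, 3L), fold_change = c(4, 4))
  cfg <- sim_config(n_cells = 30, n_genes = 100, cell_types = small_types,
                    tumor_markers = list(n_markers = 2L, fold_change = 2),
                    cnv_segments = NULL, seed = 11)
  s1 <- simulate_cells(gp, cfg)
  s2 <- simulate_cells(gp, cfg)
  expect_equal(as.matrix(SummarizedExperiment::assay(s1$sce)),
               as.matrix(SummarizedExperiment::assay(s2$sce)))
  expect_equal(s1$allele_counts$alt, s2$allele_counts$alt)
  expect_identical(s1$truth$genotype, s2$truth$genotype)
})

test_that("tumor-cell expression reflects the configured copy ratios", {
  gp <- make_genotypes(20, 0.1, seed = 1)
  sim <- simulate_cells(gp, sim_config(n_cells = 400, n_genes = 600,
                                       tumor_fraction = 0.5, seed = 12))
  counts <- as.matrix(SummarizedExperiment::assay(sim$sce))
  gain <- sim$truth$cnv_gene_idx[[1]]  # chr7-like gain, ratio 1.5
  tot <- colSums(counts)
  share <- colSums(counts[gain, ]) / tot
  expect_gt(mean(share[sim$truth$is_tumor]),
            1.2 * mean(share[!sim$truth$is_tumor]))
})

test_that("bulk mixtures obey the stated allele-fraction arithmetic", {
  gp <- make_genotypes(100, 0.2, seed = 2)
  # pure genotype B, no error: A-exclusive sites are silent, B-exclusive
  # het sites fluctuate around alt fraction 0.5
  bm <- simulate_bulk_mixture(gp, 1, mean_depth = 200, error_rate = 0,
                              seed = 3)
  expect_true(all(bm$bulk$alt_count[gp$exclusive_a] == 0))
  het_b <- gp$exclusive_b[gp$geno_b[gp$exclusive_b] == 1]
  frac <- with(bm$bulk[het_b, ], alt_count / (ref_count + alt_count))
  expect_lt(abs(mean(frac) - 0.5), 0.1)
  # 50:50 mixture at a hom-alt B-exclusive site: expected alt fraction 0.5
  bm2 <- simulate_bulk_mixture(gp, 0.5, mean_depth = 500, error_rate = 0,
                               seed = 4)
  homalt_b <- gp$exclusive_b[gp$geno_b[gp$exclusive_b] == 2]
  frac2 <- with(bm2$bulk[homalt_b, ], alt_count / (ref_count + alt_count))
  expect_lt(abs(mean(frac2) - 0.5), 0.1)
})

test_that("bulk het-site alt fractions match the binomial oracle", {
  # fraction_b = 0.25 at a B-exclusive het site -> expected alt 0.125
  gp <- make_genotypes(20000, 0.5, seed = 6)
  bm <- simulate_bulk_mixture(gp, 0.25, mean_depth = 60, error_rate = 0,
                              seed = 7)
  het_b <- gp$exclusive_b[gp$geno_b[gp$exclusive_b] == 1]
  expect_gt(length(het_b), 5000)
  d <- bm$bulk[het_b, ]
  frac <- d$alt_count / (d$ref_count + d$alt_count)
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.125), 3 * se)
})

test_that("reference series are deterministic and structureless without modules", {
  r1 <- simulate_reference_series(c(8, 16, 24), n_genes = 200, seed = 5)
  r2 <- simulate_reference_series(c(8, 16, 24), n_genes = 200, seed = 5)
  expect_equal(r1$counts, r2$counts)
  r0 <- simulate_reference_series(c(8, 16, 24), n_genes = 200,
                                  n_age_modules = 0, seed = 5)
  expect_length(r0$modules, 0)
  expect_error(simulate_reference_series(c(8, 8, 8), n_genes = 100),
               "distinct ages")
})
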