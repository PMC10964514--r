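test_that("two cells with disjoint exclusive alt sites split into components", {
  ref <- cbind(c(0, 5, 2), c(5, 0, 2))
  alt <- cbind(c(5, 0, 0), c(0, 5, 0))
  fit <- fit_two_genotype_mixture(toy_allele_counts(ref, alt),
                                  error_rate = 1e-3, seed = 1)
  asg <- fit$assignments
  expect_setequal(asg$label, c("A", "B"))
  expect_true(all(pmax(asg$posterior_a, asg$posterior_b) > 0.99))
  expect_equal(asg$posterior_a + asg$posterior_b, c(1, 1))
})

test_that("a cell with zero covered sites stays unassigned", {
  ref <- cbind(c(0, 5), c(5, 0), c(0, 0))
  alt <- cbind(c(5, 0), c(0, 5), c(0, 0))
  fit <- fit_two_genotype_mixture(toy_allele_counts(ref, alt), seed = 1)
  expect_identical(fit$assignments$label[3], "unassigned")
})

test_that("uninformative panels warn and leave all cells unassigned", {
  # identical het signal in every cell: both components converge to the
  # same genotype states
  ref <- matrix(3, 2, 4)
  alt <- matrix(3, 2, 4)
  expect_warning(
    fit <- fit_two_genotype_mixture(toy_allele_counts(ref, alt), seed = 1),
    "no informative sites")
  expect_true(all(fit$assignments$label == "unassigned"))
})

test_that("EM reaches the brute-force optimum on tiny instances", {
  # every instance: <= 4 cells, <= 3 sites; EM observed-data likelihood
  # must dominate the best complete-data likelihood over all component
  # genotype configurations and hard partitions
  set.seed(11)
  for (i in 1:12) {
    n_cells <- sample(2:4, 1)
    n_sites <- sample(1:3, 1)
    cov <- matrix(rpois(n_sites * n_cells, 4), n_sites, n_cells)
    alt <- matrix(rbinom(n_sites * n_cells, cov,
                         sample(c(0.02, 0.5, 0.98), n_sites * n_cells,
                                replace = TRUE)),
                  n_sites, n_cells)
    ac <- toy_allele_counts(cov - alt, alt)
    fit <- suppressWarnings(
      fit_two_genotype_mixture(ac, error_rate = 1e-3, seed = i))
    oracle <- bf_mixture_loglik(ac, error_rate = 1e-3)
    expect_gte(fit$loglik, oracle - 1e-6)
  }
})

test_that("identical cells produce all-zero CNV window scores", {
  counts <- matrix(rep(rpois(120, 10), 8), 120, 8)
  sce <- normalize_counts(toy_sce(counts))
  cnv <- suppressWarnings(infer_cnv(sce, reference_cells = 1:8,
                                    window_genes = 11))
  expect_true(all(abs(cnv$scores) < 1e-12))
  expect_true(all(cnv$aneuploidy < 1e-20))
})

test_that("window scores inside a simulated gain separate tumor from reference", {
  d <- default_sim()
  sim <- d$sim
  sce <- normalize_counts(sim$sce)
  cnv <- suppressWarnings(
    infer_cnv(sce, reference_cells = !sim$truth$is_tumor))
  gain_genes <- rownames(sim$sce)[sim$truth$cnv_gene_idx[[1]]]
  in_gain <- rownames(cnv$scores) %in% gain_genes
  tum <- sim$truth$is_tumor
  gain_score <- colMeans(cnv$scores[in_gain, , drop = FALSE])
  p <- stats::wilcox.test(gain_score[tum], gain_score[!tum],
                          alternative = "greater")$p.value
  expect_lt(p, 0.01)
  # aneuploidy summary separates the genotypes too
  expect_gt(median(cnv$aneuploidy[tum]), median(cnv$aneuploidy[!tum]))
})

test_that("component naming by CNV finds the tumor and rejects exact ties", {
  dd <- default_demux()
  d <- default_sim()
  map <- dd$labeled$component_genotype
  # the component enriched for true tumor cells must be named tumor
  asg <- dd$labeled$assignments
  tumor_lab <- names(which.max(vapply(c(A = "A", B = "B"), function(l)
    mean(d$sim$truth$is_tumor[asg$label == l]), numeric(1))))
  expect_identical(unname(map[tumor_lab]), "tumor")

  # exact tie of medians is an error, not a silent choice
  fake_cnv <- dd$cnv
  fake_cnv$aneuploidy[] <- 1
  expect_error(label_components_by_cnv(dd$fit, fake_cnv), "tie")
})

test_that("component naming is invariant to swapping component indices", {
  dd <- default_demux()
  fit <- dd$fit
  swapped <- fit
  swapped$assignments$label <- chartr("AB", "BA", fit$assignments$label)
  swapped$assignments$posterior_a <- fit$assignments$posterior_b
  swapped$assignments$posterior_b <- fit$assignments$posterior_a
  l1 <- label_components_by_cnv(fit, dd$cnv)
  l2 <- label_components_by_cnv(swapped, dd$cnv)
  expect_identical(l1$assignments$genotype, l2$assignments$genotype)
})

test_that("rescue is a no-op without unassigned cells and copies exact twins", {
  dd <- default_demux()
  asg <- dd$labeled$assignments
  done <- asg[asg$label != "unassigned", ]
  rownames(done) <- NULL
  sce_done <- dd$sce[, asg$label != "unassigned"]
  out <- rescue_unassigned(done, sce_done, n_neighbors = 5)
  expect_identical(out, done)
})

test_that("rescued cells recover ground truth on the default simulation", {
  dd <- default_demux()
  d <- default_sim()
  asg <- dd$full$assignments
  expect_true(all(!is.na(asg$genotype)))
  resc <- asg$method == "neighbor-rescue"
  expect_gt(sum(resc), 0)
  pred <- ifelse(asg$genotype[resc] == "tumor", "B", "A")
  expect_gte(mean(pred == d$sim$truth$genotype[resc]), 0.9)
})

test_that("per-sample fractions follow the counting identities", {
  asg <- data.frame(
    barcode = sprintf("c%d", 1:10),
    posterior_a = 1, posterior_b = 0,
    label = "A", method = "mixture",
    genotype = c(rep("tumor", 3), rep("organoid", 6), NA),
    stringsAsFactors = FALSE)
  samples <- c(rep("s1", 5), rep("s2", 5))
  fr <- genotype_fractions(asg, samples)
  expect_equal(fr$tumor_fraction[fr$sample == "s1"], 3 / 5)
  expect_equal(fr$n_unassigned[fr$sample == "s2"], 1)
  # sample-size-weighted fractions reproduce the global fraction
  labeled <- fr$n_tumor + fr$n_organoid
  expect_equal(sum(fr$tumor_fraction * labeled) / sum(labeled), 3 / 9)
  expect_error(genotype_fractions(asg, c(samples[-1], NA)), "unknown")
  # all-tumor sample
  asg2 <- asg; asg2$genotype <- "tumor"
  expect_equal(genotype_fractions(asg2, rep("s", 10))$tumor_fraction, 1)
})

test_that("assignment accuracy degrades as SNP coverage thins", {
  # non-strict monotone mean accuracy over a coverage ladder
  gp <- make_genotypes(200, 0.1, seed = 21)
  acc <- vapply(c(20, 10, 5, 2), function(reads) {
    mean(vapply(1:10, function(s) {
      sim <- simulate_cells(gp, sim_config(
        n_cells = 300, n_genes = 20, tumor_fraction = 0.1,
        mean_reads_per_cell_at_snps = reads,
        cell_types = data.frame(name = "org", proportion = 1,
                                n_markers = 2L, fold_change = 2),
        tumor_markers = list(n_markers = 2L, fold_change = 2),
        cnv_segments = NULL, n_mito = 0L, n_ribo = 0L, seed = 100 + s))
      fit <- suppressWarnings(
        fit_two_genotype_mixture(sim$allele_counts, seed = s))
      # fraction of ALL cells that are both assigned and correct, so that
      # thinning coverage cannot hide behind a shrinking assigned set
      lab <- fit$assignments$label
      is_b <- lab == "B"
      acc_dir <- mean(lab != "unassigned" &
                        (is_b == sim$truth$is_tumor))
      acc_swp <- mean(lab != "unassigned" &
                        ((lab == "A") == sim$truth$is_tumor))
      max(acc_dir, acc_swp)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.02))  # allow sampling jitter, trend down
  expect_gt(acc[1], acc[4])
})
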