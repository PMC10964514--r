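# small normalized expression fixture with planted ligand/receptor structure
crosstalk_fixture <- function(seed = 1, n_per_cluster = 40) {
  set.seed(seed)
  clusters <- c("astro", "neuron", "tumor")
  n <- n_per_cluster * length(clusters)
  labels <- rep(clusters, each = n_per_cluster)
  genes <- c("LIG1", "LIG2", "REC1", "REC2", "RECB1", "RECB2",
             sprintf("BG%02d", 1:20))
  counts <- matrix(rpois(length(genes) * n, 2), length(genes), n,
                   dimnames = list(genes, sprintf("c%03d", 1:n)))
  counts["LIG1", labels == "astro"] <- rpois(n_per_cluster, 20)
  counts["LIG2", labels == "astro"] <- rpois(n_per_cluster, 20)
  counts["REC1", labels == "tumor"] <- rpois(n_per_cluster, 20)
  counts["REC2", labels == "tumor"] <- rpois(n_per_cluster, 20)
  counts["RECB1", labels == "tumor"] <- rpois(n_per_cluster, 20)
  counts["RECB2", labels == "tumor"] <- rpois(n_per_cluster, 20)
  sce <- normalize_counts(toy_sce(counts))
  list(sce = sce, labels = labels)
}

planted_pairs <- function() {
  lr_pairs(c("planted", "complexed", "reversed"),
           list("LIG1", "LIG2", "REC1"),
           list("REC1", c("RECB1", "RECB2"), "LIG1"))
}

test_that("the shipped ligand-receptor table parses with complexes intact", {
  tab <- read_lr_pairs(system.file("extdata", "lr_pairs.tsv",
                                   package = "glicomix"))
  expect_true("SPP1_ITGAV_ITGB1" %in% tab$pair_id)
  cx <- attr(tab, "receptor")[[match("SPP1_ITGAV_ITGB1", tab$pair_id)]]
  expect_setequal(cx, c("ITGAV", "ITGB1"))
  expect_true(all(lengths(attr(tab, "ligand")) >= 1))
})

test_that("input preparation keeps ligand/receptor genes past the HVG cut", {
  fx <- crosstalk_fixture()
  pairs <- planted_pairs()
  inp <- prepare_crosstalk_input(fx$sce, fx$labels, character(0), pairs,
                                 n_hvg = 3)
  # only 3 variable genes requested, yet every LR gene survives (union rule)
  expect_true(all(c("LIG1", "LIG2", "REC1", "RECB1", "RECB2") %in%
                    rownames(inp$sce)))
  # excluding a type removes exactly its cells
  inp2 <- prepare_crosstalk_input(fx$sce, fx$labels, "neuron", pairs,
                                  n_hvg = 3)
  expect_equal(ncol(inp2$sce), sum(fx$labels != "neuron"))
  expect_false("neuron" %in% inp2$labels)
  expect_error(prepare_crosstalk_input(fx$sce, fx$labels,
                                       unique(fx$labels), pairs),
               "all cells")
})

test_that("planted directional interactions hit the permutation floor", {
  fx <- crosstalk_fixture()
  res <- lr_permutation_test(fx$sce, fx$labels, planted_pairs(),
                             n_permutations = 200, seed = 3)
  floor_p <- 1 / 201
  hit <- res[res$cluster_a == "astro" & res$cluster_b == "tumor" &
               res$pair_id == "planted", ]
  expect_equal(hit$p, floor_p)
  expect_true(hit$significant)
  # the complex (min rule) pair is also significant toward tumor
  cx <- res[res$cluster_a == "astro" & res$cluster_b == "tumor" &
              res$pair_id == "complexed", ]
  expect_lt(cx$p, 0.05)
  # p-values never fall below the add-one floor
  expect_true(all(res$p >= floor_p))
})

test_that("all-zero expression yields no significant interactions", {
  genes <- c("LIG1", "REC1", "BG1")
  expr <- matrix(0, 3, 30, dimnames = list(genes, sprintf("c%d", 1:30)))
  res <- lr_permutation_test(expr, rep(c("a", "b", "c"), 10),
                             lr_pairs("p", "LIG1", "REC1"),
                             n_permutations = 100, seed = 1)
  expect_false(any(res$significant))
  expect_true(all(res$p == 1))
})

test_that("pairs with absent genes are skipped and recorded", {
  fx <- crosstalk_fixture()
  pairs <- lr_pairs(c("ok", "ghost"), list("LIG1", "NOT_A_GENE"),
                    list("REC1", "REC1"))
  res <- lr_permutation_test(fx$sce, fx$labels, pairs,
                             n_permutations = 100, seed = 2)
  expect_identical(attr(res, "skipped_pairs"), "ghost")
  expect_setequal(unique(res$pair_id), "ok")
})

test_that("interaction counts satisfy the accounting identity", {
  fx <- crosstalk_fixture()
  res <- lr_permutation_test(fx$sce, fx$labels, planted_pairs(),
                             n_permutations = 200, seed = 4)
  m <- interaction_counts(res)
  expect_equal(sum(m), sum(res$significant))
  msym <- interaction_counts(res, symmetrize = TRUE)
  m2 <- matrix(msym, nrow(msym), dimnames = dimnames(msym))
  expect_equal(m2, t(m2))
  # no significant pairs -> zero matrix
  res0 <- res
  res0$significant <- FALSE
  expect_true(all(interaction_counts(res0) == 0))
})

test_that("relabeling clusters permutes rows without changing p-values", {
  fx <- crosstalk_fixture()
  res1 <- lr_permutation_test(fx$sce, fx$labels, planted_pairs(),
                              n_permutations = 150, seed = 5)
  ren <- c(astro = "z_astro", neuron = "m_neuron", tumor = "a_tumor")
  res2 <- lr_permutation_test(fx$sce, unname(ren[fx$labels]),
                              planted_pairs(),
                              n_permutations = 150, seed = 5)
  key1 <- paste(ren[res1$cluster_a], ren[res1$cluster_b], res1$pair_id)
  key2 <- paste(res2$cluster_a, res2$cluster_b, res2$pair_id)
  expect_equal(res1$p, res2$p[match(key1, key2)])
})

test_that("loosening the expression gate never shrinks the significant set", {
  fx <- crosstalk_fixture()
  r_strict <- lr_permutation_test(fx$sce, fx$labels, planted_pairs(),
                                  n_permutations = 150,
                                  min_expressed_fraction = 0.10, seed = 6)
  r_loose <- lr_permutation_test(fx$sce, fx$labels, planted_pairs(),
                                 n_permutations = 150,
                                 min_expressed_fraction = 0, seed = 6)
  key <- function(r) with(r, paste(cluster_a, cluster_b, pair_id))
  sig_strict <- key(r_strict)[r_strict$significant]
  sig_loose <- key(r_loose)[r_loose$significant]
  expect_true(all(sig_strict %in% sig_loose))
})

test_that("the directional filter keeps only microenvironment-to-tumor edges", {
  fx <- crosstalk_fixture()
  res <- lr_permutation_test(fx$sce, fx$labels, planted_pairs(),
                             n_permutations = 200, seed = 7)
  kept <- directional_filter(res, "tumor")
  expect_true(all(kept$cluster_b == "tumor"))
  expect_false(any(kept$cluster_a == "tumor"))
  expect_true(all(kept$significant))
  # the planted orientation survives; its reverse does not
  expect_true("planted" %in% kept$pair_id)
  expect_false(any(kept$pair_id == "reversed" & kept$cluster_a == "tumor"))
  expect_error(directional_filter(res, "no_such_cluster"), "unknown")
})
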