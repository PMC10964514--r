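#' Default run configuration
#'
#' Nested key-value configuration for [run_pipeline()]. Defaults follow the
#' documented stage defaults (QC: at least 750 detected genes, at most 10%
#' mitochondrial counts, genes in at least 5 cells; normalization to
#' 10,000 counts; 2000 variable genes; demultiplexing threshold 0.99; ...).
#' The default simulated cohort is three samples emulating a time course:
#' low tumor fraction, the study default 10%, and near-takeover.
#'
#' @return nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    stages = list(qc = TRUE, demux = TRUE, fingerprint = TRUE,
                  scoring = TRUE, staging = TRUE, crosstalk = TRUE),
    sim = list(
      n_cells = 2000L, n_genes = 2000L, n_snps = 200L,
      exclusive_fraction = 0.1, mean_reads_per_cell_at_snps = 20,
      error_rate = 1e-3,
      samples = list(list(id = "young", tumor_fraction = 0.02),
                     list(id = "mid", tumor_fraction = 0.10),
                     list(id = "old", tumor_fraction = 0.60)),
      bulk_fractions = c(0.01, 0.1, 0.5, 0.9),
      bulk_mean_depth = 100
    ),
    qc = list(min_genes = 750L, max_mito = 0.10, min_cells = 5L),
    norm = list(target_sum = 1e4),
    hvg = list(n_top = 2000L),
    demux = list(error_rate = 1e-3, posterior_threshold = 0.99,
                 max_iter = 200L, window_genes = 101L, n_neighbors = 30L),
    fingerprint = list(min_depth = 10L, min_alt_reads = 3L,
                       min_quality = 30),
    score = list(n_bins = 24L, n_ctrl_per_gene = 100L),
    stage = list(ages = c(8, 12, 16, 21, 24, 37), n_hvg = 1000L),
    crosstalk = list(n_permutations = 1000L, min_expressed_fraction = 0.10,
                     alpha = 0.05)
  )
}

#' Validate and default a run configuration
#'
#' Accepts a YAML file path or a nested list, fills in every default from
#' [default_run_config()], and rejects unknown keys, type mismatches and
#' invalid values (negative seed, empty sample list, proportions outside
#' [0, 1]).
#'
#' @param config YAML path or nested list (possibly partial).
#' @return validated config list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a file path or a list",
                             call. = FALSE)
  merged <- merge_config(default_run_config(), config, path = "")
  if (!is.numeric(merged$seed) || length(merged$seed) != 1 ||
      is.na(merged$seed) || merged$seed < 0 || merged$seed != round(merged$seed))
    stop("config error at 'seed': must be a non-negative integer",
         call. = FALSE)
  merged$seed <- as.integer(merged$seed)
  if (!length(merged$sim$samples))
    stop("config error at 'sim.samples': sample list is empty",
         call. = FALSE)
  for (s in merged$sim$samples) {
    if (is.null(s$id) || is.null(s$tumor_fraction))
      stop("config error at 'sim.samples': each sample needs id and ",
           "tumor_fraction", call. = FALSE)
    stopifnot_scalar_prob(s$tumor_fraction, "sim.samples.tumor_fraction")
  }
  stopifnot_scalar_prob(merged$qc$max_mito, "qc.max_mito")
  stopifnot_scalar_prob(merged$demux$posterior_threshold,
                        "demux.posterior_threshold")
  structure(merged, class = c("run_config", "list"))
}

# recursive default-filling; unknown keys are a config error
merge_config <- function(defaults, user, path) {
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop("config error: unknown key(s) ",
         paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "),
         call. = FALSE)
  out <- defaults
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        k != "samples") {
      if (!is.list(user[[k]]))
        stop("config error at '", sub("^\\.", "", paste0(path, ".", k)),
             "': expected a key-value block", call. = FALSE)
      out[[k]] <- merge_config(defaults[[k]], user[[k]],
                               paste0(path, ".", k))
    } else {
      out[[k]] <- user[[k]]
    }
  }
  out
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the enabled stages in dependency order on a simulated
#' two-genotype cohort: simulation, QC + normalization, genotype
#' demultiplexing with CNV component labeling and neighbor rescue,
#' per-sample genotype fractions, germline fingerprint construction and
#' bulk mixture detection, signature scoring, pseudo-bulk developmental
#' staging, and receptor-ligand crosstalk (with ligand/receptor pairs
#' planted from the simulated marker modules). Any stage failure aborts
#' with a stage-tagged error. The report is written atomically (temp file,
#' renamed on success) as JSON when `outdir` is set.
#'
#' @param config a [validate_config()] `run_config`, a partial list, or a
#'   YAML path.
#' @return the report, an object of class `run_report` (nested list; also
#'   serialized to `<outdir>/report.json` when an output directory is
#'   configured).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("glicomix")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- simulate -------------------------------------------------------------
  sim <- stage("simulate", {
    gp <- make_genotypes(cfg$sim$n_snps, cfg$sim$exclusive_fraction,
                         seed = cfg$seed)
    base_cfg <- sim_config(
      n_cells = ceiling(cfg$sim$n_cells / length(cfg$sim$samples)),
      n_genes = cfg$sim$n_genes,
      mean_reads_per_cell_at_snps = cfg$sim$mean_reads_per_cell_at_snps,
      error_rate = cfg$sim$error_rate, seed = cfg$seed)
    gm <- make_gene_model(base_cfg)
    runs <- lapply(seq_along(cfg$sim$samples), function(i) {
      s <- cfg$sim$samples[[i]]
      scfg <- base_cfg
      scfg$tumor_fraction <- s$tumor_fraction
      scfg$sample_id <- s$id
      scfg$seed <- derive_seed(cfg$seed, 1000L + i)
      simulate_cells(gp, scfg, gene_model = gm)
    })
    combine_sim_runs(runs, gp)
  })
  report$simulate <- list(n_cells = ncol(sim$sce),
                          n_genes = nrow(sim$sce),
                          n_snps = nrow(sim$allele_counts$sites),
                          true_tumor_fraction = mean(sim$truth$is_tumor))

  # ---- qc + normalization ---------------------------------------------------
  sce <- sim$sce
  ac <- sim$allele_counts
  truth_geno <- setNames(sim$truth$genotype, sim$truth$barcode)
  truth_type <- setNames(sim$truth$cell_type, sim$truth$barcode)
  if (isTRUE(cfg$stages$qc)) {
    n0 <- c(ncol(sce), nrow(sce))
    sce <- stage("qc", {
      x <- filter_cells(sce, cfg$qc$min_genes, cfg$qc$max_mito)
      filter_genes(x, cfg$qc$min_cells)
    })
    ac <- subset_allele_cells(ac, match(colnames(sce), ac$barcodes))
    report$qc <- list(cells_before = n0[1], cells_after = ncol(sce),
                      genes_before = n0[2], genes_after = nrow(sce))
  }
  sce <- stage("normalize", normalize_counts(sce, cfg$norm$target_sum))

  # ---- demultiplexing -------------------------------------------------------
  if (isTRUE(cfg$stages$demux)) {
    res <- stage("demux", {
      fit <- fit_two_genotype_mixture(
        ac, error_rate = cfg$demux$error_rate,
        max_iter = cfg$demux$max_iter,
        posterior_threshold = cfg$demux$posterior_threshold,
        seed = cfg$seed)
      cnv <- suppressWarnings(
        infer_cnv(sce, reference_cells = seq_len(ncol(sce)),
                  window_genes = cfg$demux$window_genes))
      fit <- label_components_by_cnv(fit, cnv)
      fit <- rescue_unassigned(fit, sce,
                               n_neighbors = cfg$demux$n_neighbors,
                               n_hvg = cfg$hvg$n_top)
      fit
    })
    asg <- res$assignments
    pred <- ifelse(asg$genotype == "tumor", "B", "A")
    truth_here <- truth_geno[asg$barcode]
    fr <- genotype_fractions(res, sample_labels =
                               SummarizedExperiment::colData(sce)$sample)
    report$demux <- list(
      n_mixture_assigned = sum(asg$method == "mixture", na.rm = TRUE),
      n_rescued = sum(asg$method == "neighbor-rescue", na.rm = TRUE),
      pct_labeled = 100 * mean(!is.na(asg$genotype)),
      accuracy_vs_truth = mean(pred == truth_here, na.rm = TRUE),
      component_genotype = as.list(res$component_genotype),
      fractions = fr)
  }

  # ---- fingerprints ---------------------------------------------------------
  if (isTRUE(cfg$stages$fingerprint)) {
    report$fingerprint <- stage("fingerprint", {
      vcf_dir <- if (!is.null(cfg$outdir)) file.path(cfg$outdir, "vcf")
                 else file.path(tempdir(), "glicomix_vcf")
      paths <- write_genotype_vcfs(sim$truth$genotypes, vcf_dir)
      panel <- build_fingerprints(paths[1], paths[2],
                                  min_depth = cfg$fingerprint$min_depth,
                                  min_quality = cfg$fingerprint$min_quality)
      ests <- lapply(seq_along(cfg$sim$bulk_fractions), function(i) {
        f <- cfg$sim$bulk_fractions[i]
        bm <- simulate_bulk_mixture(sim$truth$genotypes, f,
                                    mean_depth = cfg$sim$bulk_mean_depth,
                                    error_rate = cfg$sim$error_rate,
                                    seed = derive_seed(cfg$seed, 2000L + i))
        detect_fingerprints(panel, bm$bulk,
                            min_depth = cfg$fingerprint$min_depth,
                            min_alt_reads = cfg$fingerprint$min_alt_reads,
                            sample_id = sprintf("mix_%g", f))
      })
      list(panel_sizes = c(a = nrow(panel$a), b = nrow(panel$b)),
           comparison = compare_samples(ests),
           true_fractions = cfg$sim$bulk_fractions)
    })
  }

  # ---- signature scoring ----------------------------------------------------
  if (isTRUE(cfg$stages$scoring)) {
    report$scoring <- stage("scoring", {
      sets <- c(sim$truth$marker_genes,
                list(tumor = sim$truth$tumor_marker_genes))
      scores <- as.data.frame(lapply(seq_along(sets), function(i)
        module_score(sce, sets[[i]], n_bins = cfg$score$n_bins,
                     n_ctrl_per_gene = cfg$score$n_ctrl_per_gene,
                     seed = derive_seed(cfg$seed, 3000L + i),
                     name = names(sets)[i])))
      names(scores) <- names(sets)
      scores$cell_type <- truth_type[colnames(sce)]
      scores$sample <- SummarizedExperiment::colData(sce)$sample
      list(scaled_by_type = scaled_group_summary(
        scores, c("cell_type", "sample")))
    })
  }

  # ---- staging --------------------------------------------------------------
  if (isTRUE(cfg$stages$staging)) {
    report$staging <- stage("staging", {
      # self-consistent staging demonstration: queries drawn from the same
      # age-graded generative model at known ages, then re-staged
      query_ages <- cfg$stage$ages
      ref <- simulate_reference_series(cfg$stage$ages,
                                       n_genes = cfg$sim$n_genes,
                                       seed = derive_seed(cfg$seed, 4000L),
                                       query_ages = query_ages)
      st <- stage_by_correlation(ref$query_counts, ref,
                                 n_hvg = cfg$stage$n_hvg)
      list(by_age = st$by_age, best_age = st$best_age,
           true_query_age = query_ages,
           age_recovery = mean(st$best_age == query_ages))
    })
  }

  # ---- crosstalk ------------------------------------------------------------
  if (isTRUE(cfg$stages$crosstalk)) {
    report$crosstalk <- stage("crosstalk", {
      lig <- head(sim$truth$marker_genes$astrocytes, 5)
      rec <- head(sim$truth$tumor_marker_genes, 5)
      null_g <- head(sim$truth$marker_genes$radial_glia, 5)
      pairs <- lr_pairs(
        pair_id = c(paste0("planted_", seq_len(5)), paste0("null_", 1:5)),
        ligand_genes = as.list(c(lig, null_g)),
        receptor_genes = as.list(c(rec, rev(null_g))))
      labels <- truth_type[colnames(sce)]
      inp <- prepare_crosstalk_input(sce, labels, character(0), pairs,
                                     n_hvg = min(cfg$hvg$n_top, nrow(sce)))
      res <- lr_permutation_test(
        inp$sce, inp$labels, pairs,
        n_permutations = cfg$crosstalk$n_permutations,
        min_expressed_fraction = cfg$crosstalk$min_expressed_fraction,
        alpha = cfg$crosstalk$alpha, seed = cfg$seed)
      list(counts = interaction_counts(res),
           tumor_directed = directional_filter(res, "tumor"))
    })
  }

  report <- structure(report, class = c("run_report", "list"))
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    tmp <- tempfile(tmpdir = cfg$outdir, fileext = ".json")
    jsonlite::write_json(strip_classes(report), tmp, auto_unbox = TRUE,
                         digits = NA, force = TRUE, pretty = TRUE)
    file.rename(tmp, file.path(cfg$outdir, "report.json"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("glicomix run_report (seed", x$provenance$seed, ")\n")
  for (s in setdiff(names(x), "provenance")) cat("  section:", s, "\n")
  if (!is.null(x$demux))
    cat("  demux:", x$demux$pct_labeled, "% labeled, accuracy",
        signif(x$demux$accuracy_vs_truth, 4), "\n")
  invisible(x)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  } else if (is.matrix(x)) {
    x <- as.data.frame(x)
  }
  x
}

combine_sim_runs <- function(runs, gp) {
  sces <- lapply(runs, `[[`, "sce")
  # disambiguate barcodes across samples
  for (i in seq_along(sces)) {
    bc <- paste0(SummarizedExperiment::colData(sces[[i]])$sample, "_",
                 colnames(sces[[i]]))
    colnames(sces[[i]]) <- bc
    SummarizedExperiment::colData(sces[[i]])$barcode <- bc
  }
  sce <- do.call(BiocGenerics::cbind, sces)
  acs <- lapply(runs, `[[`, "allele_counts")
  barcodes <- unlist(lapply(sces, colnames), use.names = FALSE)
  ac <- allele_counts(sites = gp$sites, barcodes = barcodes,
                      ref = do.call(cbind, lapply(acs, `[[`, "ref")),
                      alt = do.call(cbind, lapply(acs, `[[`, "alt")))
  truths <- lapply(runs, `[[`, "truth")
  truth <- truths[[1]]
  truth$barcode <- barcodes
  truth$genotype <- unlist(lapply(truths, `[[`, "genotype"), use.names = FALSE)
  truth$is_tumor <- unlist(lapply(truths, `[[`, "is_tumor"), use.names = FALSE)
  truth$cell_type <- unlist(lapply(truths, `[[`, "cell_type"),
                            use.names = FALSE)
  truth$tumor_fraction <- mean(truth$is_tumor)
  list(sce = sce, allele_counts = ac, truth = truth)
}

subset_allele_cells <- function(ac, idx) {
  allele_counts(sites = ac$sites, barcodes = ac$barcodes[idx],
                ref = ac$ref[, idx, drop = FALSE],
                alt = ac$alt[, idx, drop = FALSE])
}
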