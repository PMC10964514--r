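#' Build mutually exclusive germline SNP fingerprint panels
#'
#' Compares two germline variant callsets and extracts, per genotype, the
#' biallelic SNP sites that are alt-carrying (het or hom-alt) in that
#' genotype and confidently hom-ref in the other. Confidence requires an
#' explicit 0/0 call with depth of at least `min_depth` in the other
#' callset (absence of a record is NOT treated as reference) and a quality
#' of at least `min_quality` plus `min_depth` coverage on the alt-carrying
#' side. Multiallelic records and indels are skipped and counted.
#'
#' @param callset_a,callset_b paths to VCF v4.2 files (GT required, DP used
#'   when present) or `vcfR` objects. Both callsets must report every site
#'   (joint calling or forced emission); contigs present in only one
#'   callset raise an error.
#' @param min_depth minimum depth in BOTH callsets (default 10).
#' @param min_quality minimum QUAL of the alt-carrying record (default 30;
#'   records with missing QUAL pass).
#' @return object of class `fingerprint_panel`: list with data.frames `a`
#'   and `b` (chrom, pos, ref, alt, zygosity), the filters used, and
#'   `skipped` counts (multiallelic, indel).
#' @export
build_fingerprints <- function(callset_a, callset_b, min_depth = 10L,
                               min_quality = 30) {
  va <- read_callset(callset_a)
  vb <- read_callset(callset_b)
  only_a <- setdiff(unique(va$records$chrom), unique(vb$records$chrom))
  only_b <- setdiff(unique(vb$records$chrom), unique(va$records$chrom))
  if (length(only_a) || length(only_b))
    stop("contig name mismatch between callsets: ",
         paste(c(only_a, only_b), collapse = ", "), call. = FALSE)

  key_a <- with(va$records, paste(chrom, pos, ref, alt))
  key_b <- with(vb$records, paste(chrom, pos, ref, alt))
  shared <- intersect(key_a, key_b)
  ra <- va$records[match(shared, key_a), ]
  rb <- vb$records[match(shared, key_b), ]

  pick <- function(owner, other) {
    owner_alt <- owner$gt %in% c(1L, 2L)
    other_ref <- !is.na(other$gt) & other$gt == 0L
    depth_ok <- (is.na(owner$dp) | owner$dp >= min_depth) &
      (is.na(other$dp) | other$dp >= min_depth)
    # explicit hom-ref call requires a depth value on the other side
    other_called <- other_ref & !is.na(other$dp) & other$dp >= min_depth
    qual_ok <- is.na(owner$qual) | owner$qual >= min_quality
    sel <- owner_alt & other_called & depth_ok & qual_ok
    data.frame(chrom = owner$chrom[sel], pos = owner$pos[sel],
               ref = owner$ref[sel], alt = owner$alt[sel],
               zygosity = ifelse(owner$gt[sel] == 1L, "het", "hom_alt"),
               stringsAsFactors = FALSE)
  }

  structure(list(a = pick(ra, rb), b = pick(rb, ra),
                 filters = list(min_depth = min_depth,
                                min_quality = min_quality),
                 skipped = list(multiallelic = va$n_multi + vb$n_multi,
                                indel = va$n_indel + vb$n_indel)),
            class = "fingerprint_panel")
}

# normalize a VCF (path or vcfR object) into a biallelic-SNP record table
read_callset <- function(x) {
  v <- if (inherits(x, "vcfR")) x else vcfR::read.vcfR(x, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  alt <- fix$ALT
  multi <- grepl(",", alt)
  indel <- nchar(fix$REF) != 1L | (nchar(alt) != 1L & !multi)
  keep <- !multi & !indel
  gt_raw <- vcfR::extract.gt(v, element = "GT")[keep, 1L]
  dp_raw <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, 1L],
                     error = function(e) rep(NA_real_, sum(keep)))
  gt <- rep(NA_integer_, length(gt_raw))
  gt[gt_raw %in% c("0/0", "0|0")] <- 0L
  gt[gt_raw %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  gt[gt_raw %in% c("1/1", "1|1")] <- 2L
  qual <- suppressWarnings(as.numeric(fix$QUAL[keep]))
  list(records = data.frame(chrom = fix$CHROM[keep],
                            pos = as.integer(fix$POS[keep]),
                            ref = fix$REF[keep], alt = alt[keep],
                            gt = gt, dp = dp_raw, qual = qual,
                            stringsAsFactors = FALSE),
       n_multi = sum(multi), n_indel = sum(indel & !multi))
}

#' @export
print.fingerprint_panel <- function(x, ...) {
  cat("fingerprint_panel:", nrow(x$a), "sites exclusive to A,",
      nrow(x$b), "to B (min_depth", x$filters$min_depth,
      ", min_quality", x$filters$min_quality, ")\n")
  if (x$skipped$multiallelic || x$skipped$indel)
    cat("  skipped:", x$skipped$multiallelic, "multiallelic,",
        x$skipped$indel, "indel record(s)\n")
  invisible(x)
}

#' Detect genotype fingerprints in bulk allele counts
#'
#' Scores a bulk DNA sample against a fingerprint panel: a panel site is
#' evaluable when its bulk depth reaches `min_depth`, and detected when its
#' alternate read count reaches `min_alt_reads`. The per-genotype detected
#' fraction (detected / evaluable) is the mixture readout. Panel sites
#' absent from the bulk table are non-evaluable and reported.
#'
#' @param panel a [build_fingerprints()] `fingerprint_panel`.
#' @param bulk data.frame with chrom, pos, ref, alt, ref_count, alt_count.
#' @param min_depth minimum depth for a site to be evaluable (default 10).
#' @param min_alt_reads minimum alt reads for detection (default 3).
#' @param sample_id sample identifier carried into the output.
#' @return object of class `mixture_estimate`: data.frame with one row per
#'   genotype (sample, genotype, n_panel, n_absent, n_evaluable,
#'   n_detected, detected_fraction; the fraction is NA when no site is
#'   evaluable) plus the thresholds as attributes.
#' @export
detect_fingerprints <- function(panel, bulk, min_depth = 10L,
                                min_alt_reads = 3L, sample_id = "sample") {
  stopifnot(inherits(panel, "fingerprint_panel"))
  need <- c("chrom", "pos", "ref", "alt", "ref_count", "alt_count")
  if (!all(need %in% names(bulk)))
    stop("bulk table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bulk_key <- with(bulk, paste(chrom, pos, ref, alt))

  one <- function(sites, genotype) {
    idx <- match(with(sites, paste(chrom, pos, ref, alt)), bulk_key)
    present <- !is.na(idx)
    depth <- bulk$ref_count[idx[present]] + bulk$alt_count[idx[present]]
    evaluable <- depth >= min_depth
    detected <- evaluable & bulk$alt_count[idx[present]] >= min_alt_reads
    n_eval <- sum(evaluable)
    data.frame(sample = sample_id, genotype = genotype,
               n_panel = nrow(sites), n_absent = sum(!present),
               n_evaluable = n_eval, n_detected = sum(detected),
               detected_fraction = if (n_eval > 0) sum(detected) / n_eval
                                   else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(panel$a, "A"), one(panel$b, "B"))
  structure(out, class = c("mixture_estimate", "data.frame"),
            min_depth = min_depth, min_alt_reads = min_alt_reads)
}

#' Compare fingerprint detection across samples
#'
#' Lays detected fractions side by side per genotype and reports each
#' sample's difference from the first (reference/control) sample,
#' mirroring the paired bar readout used to compare treated and control
#' organoid samples.
#'
#' @param estimates list of [detect_fingerprints()] results with distinct
#'   sample ids; at least 2.
#' @return data.frame with one row per (sample, genotype):
#'   detected_fraction and diff_vs_first.
#' @export
compare_samples <- function(estimates) {
  if (!is.list(estimates) || length(estimates) < 2 ||
      !all(vapply(estimates, inherits, logical(1), "mixture_estimate")))
    stop("need a list of >= 2 mixture_estimate objects", call. = FALSE)
  tab <- do.call(rbind, lapply(estimates, as.data.frame))
  ids <- unique(tab$sample)
  if (length(ids) != length(estimates))
    stop("duplicated sample ids: ",
         paste(names(which(table(vapply(estimates, function(e)
           e$sample[1], character(1))) > 1)), collapse = ", "), call. = FALSE)
  first <- tab[tab$sample == ids[1], ]
  tab$diff_vs_first <- tab$detected_fraction -
    first$detected_fraction[match(tab$genotype, first$genotype)]
  tab[, c("sample", "genotype", "n_evaluable", "n_detected",
          "detected_fraction", "diff_vs_first")]
}

#' Maximum-likelihood mixture fraction from bulk allele counts
#'
#' Optional extra beyond the binary detected-fraction readout: estimates
#' the bulk mixture fraction of one genotype by maximizing the binomial
#' likelihood of alt counts at that genotype's exclusive het/hom-alt sites,
#' where the expected alt fraction at a site of zygosity z is
#' fraction * z/2 blended with the error rate.
#'
#' @param panel a `fingerprint_panel`.
#' @param bulk bulk allele-count data.frame (as in
#'   [detect_fingerprints()]).
#' @param genotype which genotype's fraction to estimate ("A" or "B").
#' @param error_rate sequencing error rate.
#' @return the ML fraction estimate in [0, 1] (NA if no panel site has
#'   coverage).
#' @export
estimate_mixture_fraction <- function(panel, bulk, genotype = c("B", "A"),
                                      error_rate = 1e-3) {
  genotype <- match.arg(genotype)
  sites <- if (genotype == "A") panel$a else panel$b
  bulk_key <- with(bulk, paste(chrom, pos, ref, alt))
  idx <- match(with(sites, paste(chrom, pos, ref, alt)), bulk_key)
  ok <- !is.na(idx)
  if (!any(ok)) return(NA_real_)
  alt <- bulk$alt_count[idx[ok]]
  depth <- alt + bulk$ref_count[idx[ok]]
  vaf_site <- ifelse(sites$zygosity[ok] == "het", 0.5, 1)
  nll <- function(f) {
    p <- f * vaf_site
    p <- p * (1 - error_rate) + (1 - p) * error_rate
    -sum(alt * log(p) + (depth - alt) * log1p(-p))
  }
  stats::optimize(nll, c(0, 1))$minimum
}
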