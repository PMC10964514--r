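#' Reference-free two-genotype demultiplexing by EM
#'
#' Fits a two-component mixture to per-cell SNP allele counts. Each
#' component g carries a diploid genotype state per site, so its alt-allele
#' probability is restricted to theta in {eps, 0.5, 1 - eps} with
#' eps = `error_rate` (hom-ref, het, hom-alt under sequencing error). The
#' M-step picks, per component and site, the state maximizing the expected
#' complete-data binomial log-likelihood; the E-step computes cell
#' posteriors from the total log-likelihood of the cell's alt/ref counts
#' plus the estimated mixing proportions. Cells are labeled A or B when the
#' larger posterior reaches `posterior_threshold`, and left unassigned
#' otherwise; cells with zero covered sites are always unassigned.
#'
#' Initialization is k-means++ on zero-imputed per-cell alt-fraction
#' vectors with `n_restarts` seed-controlled restarts; the restart with the
#' best final log-likelihood is kept.
#'
#' @param ac an [allele_counts()] object.
#' @param error_rate sequencing error rate eps, in (0, 0.5).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param posterior_threshold minimum posterior for an unambiguous label.
#' @param seed integer seed for initialization.
#' @param n_restarts number of k-means++ restarts (default 20).
#'
#' @return object of class `genotype_mixture`: list with `assignments`
#'   (data.frame barcode, posterior_a, posterior_b, label in A/B/unassigned,
#'   method, genotype NA until CNV labeling), `theta` (2 x sites matrix of
#'   component alt probabilities), `vaf` (2 x sites allele fractions in
#'   {0, 0.5, 1}), `pi` (mixing proportions), `loglik`, `n_iter`,
#'   `converged`.
#' @export
fit_two_genotype_mixture <- function(ac, error_rate = 1e-3, max_iter = 200L,
                                     tol = 1e-8, posterior_threshold = 0.99,
                                     seed = 1L, n_restarts = 20L) {
  stopifnot(inherits(ac, "allele_counts"))
  stopifnot_scalar_prob(error_rate, "error_rate", allow_zero = FALSE,
                        allow_one = FALSE)
  if (error_rate >= 0.5) stop("'error_rate' must be < 0.5", call. = FALSE)
  stopifnot_scalar_prob(posterior_threshold, "posterior_threshold")
  A <- ac$alt; R <- ac$ref
  n_cells <- ncol(A); n_sites <- nrow(A)
  if (n_cells < 2) stop("need >= 2 cells", call. = FALSE)
  cov <- A + R
  covered <- Matrix::colSums(cov) > 0
  if (!any(Matrix::rowSums(cov) > 0))
    stop("no site has nonzero coverage", call. = FALSE)

  states <- c(error_rate, 0.5, 1 - error_rate)
  # sufficient statistics per cell are linear in A and R, so the per-cell
  # log-likelihood under any theta is t(A) %*% log(theta) + t(R) %*% log(1-theta)
  tA <- Matrix::t(A); tR <- Matrix::t(R)

  cell_loglik <- function(theta) {
    # theta: 2 x n_sites -> returns n_cells x 2
    cbind(as.numeric(tA %*% log(theta[1, ]) + tR %*% log1p(-theta[1, ])),
          as.numeric(tA %*% log(theta[2, ]) + tR %*% log1p(-theta[2, ])))
  }

  m_step <- function(resp) {
    # resp: n_cells x 2 posteriors; choose best state per component/site
    theta <- matrix(0.5, 2, n_sites)
    for (g in 1:2) {
      ag <- as.numeric(A %*% resp[, g])
      rg <- as.numeric(R %*% resp[, g])
      q <- vapply(states, function(th) ag * log(th) + rg * log1p(-th),
                  numeric(n_sites))
      q <- matrix(q, nrow = n_sites)
      theta[g, ] <- states[max.col(q, ties.method = "first")]
    }
    theta
  }

  em_step <- function(resp, hard) {
    theta <- m_step(resp)
    pi_ <- pmax(colMeans(resp), 1e-12)
    lg <- cell_loglik(theta)
    lg_p <- sweep(lg, 2L, log(pi_), "+")
    m <- pmax(lg_p[, 1], lg_p[, 2])
    ll <- sum(m + log(exp(lg_p[, 1] - m) + exp(lg_p[, 2] - m)))
    resp <- exp(lg_p - m)
    resp <- resp / rowSums(resp)
    # hard (classification) updates keep the minority component's genotype
    # estimates free of soft-responsibility contamination from the larger
    # component; used as a warm-up phase before the soft iterations
    if (hard) resp <- cbind(resp[, 1] >= 0.5, resp[, 1] < 0.5) * 1.0
    list(resp = resp, theta = theta, pi = pi_, loglik = ll)
  }

  run_em <- function(resp0) {
    resp <- resp0
    prev_part <- resp[, 1] >= 0.5
    for (it_h in seq_len(min(50L, max_iter))) {
      s <- em_step(resp, hard = TRUE)
      resp <- s$resp
      part <- resp[, 1] >= 0.5
      if (identical(part, prev_part)) break
      prev_part <- part
    }
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      s <- em_step(resp, hard = FALSE)
      resp <- s$resp
      if (is.finite(ll_old) &&
          abs(s$loglik - ll_old) <= tol * (abs(ll_old) + .Machine$double.eps)) {
        return(list(resp = resp, theta = s$theta, pi = s$pi,
                    loglik = s$loglik, n_iter = it, converged = TRUE))
      }
      ll_old <- s$loglik
    }
    list(resp = resp, theta = s$theta, pi = s$pi, loglik = s$loglik,
         n_iter = max_iter, converged = FALSE)
  }

  # k-means (k-means++ seeded) initialization on zero-imputed alt fractions
  f <- as.matrix(tA / pmax(as.matrix(Matrix::t(cov)), 1))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, 503L + r))
    centers <- kmeanspp_centers(f, 2L)
    cl <- tryCatch(kmeans(f, centers = centers)$cluster,
                   error = function(e) {
                     d1 <- rowSums(sweep(f, 2L, centers[1, ])^2)
                     d2 <- rowSums(sweep(f, 2L, centers[2, ])^2)
                     1L + (d1 >= d2)
                   })
    resp0 <- cbind(cl == 1L, cl == 2L) * 1.0
    fit <- run_em(resp0)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  informative <- any(best$theta[1, ] != best$theta[2, ])
  post_a <- best$resp[, 1]
  post_a[!covered] <- 0.5
  label <- ifelse(pmax(post_a, 1 - post_a) >= posterior_threshold & covered,
                  ifelse(post_a >= 0.5, "A", "B"), "unassigned")
  if (!informative) {
    warning("no informative sites: components are identical; ",
            "all cells unassigned")
    label[] <- "unassigned"
  }

  structure(list(
    assignments = data.frame(
      barcode = ac$barcodes, posterior_a = post_a, posterior_b = 1 - post_a,
      label = label,
      method = ifelse(label == "unassigned", NA_character_, "mixture"),
      genotype = NA_character_, stringsAsFactors = FALSE),
    theta = best$theta,
    vaf = matrix(states_to_vaf(best$theta, error_rate), 2,
                 dimnames = list(c("A", "B"), rownames(A))),
    pi = best$pi, loglik = best$loglik, n_iter = best$n_iter,
    converged = best$converged,
    posterior_threshold = posterior_threshold, error_rate = error_rate
  ), class = "genotype_mixture")
}

states_to_vaf <- function(theta, eps) {
  out <- theta
  out[theta <= eps] <- 0
  out[theta >= 1 - eps] <- 1
  out[theta == 0.5] <- 0.5
  out
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1L)
  for (j in seq_len(k - 1L)) {
    d2 <- apply(vapply(idx, function(i) rowSums(sweep(x, 2L, x[i, ])^2),
                       numeric(n)), 1L, min)
    if (all(d2 == 0)) idx <- c(idx, sample.int(n, 1L))
    else idx <- c(idx, sample.int(n, 1L, prob = d2))
  }
  x[idx, , drop = FALSE]
}

#' @export
print.genotype_mixture <- function(x, ...) {
  tab <- table(x$assignments$label)
  cat("genotype_mixture: loglik", format(x$loglik), "in", x$n_iter,
      "iterations", if (x$converged) "(converged)" else "(max_iter)", "\n")
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Per-sample genotype fractions
#'
#' Computes, per sample, the fraction of labeled cells carrying the tumor
#' genotype. Unassigned cells are excluded from the denominator and
#' reported separately.
#'
#' @param assignments assignment data.frame with `genotype` filled in (see
#'   [label_components_by_cnv()]), or a `genotype_mixture`.
#' @param sample_labels sample id per cell (same order as assignments).
#' @return data.frame with sample, n_cells, n_tumor, n_organoid,
#'   n_unassigned, tumor_fraction.
#' @export
genotype_fractions <- function(assignments, sample_labels) {
  asg <- as_assignments(assignments)
  if (length(sample_labels) != nrow(asg))
    stop("'sample_labels' must have one entry per cell", call. = FALSE)
  if (anyNA(sample_labels))
    stop("unknown (NA) sample label", call. = FALSE)
  out <- do.call(rbind, lapply(split(asg, sample_labels), function(d) {
    labeled <- !is.na(d$genotype)
    data.frame(n_cells = nrow(d),
               n_tumor = sum(d$genotype == "tumor", na.rm = TRUE),
               n_organoid = sum(d$genotype == "organoid", na.rm = TRUE),
               n_unassigned = sum(!labeled),
               tumor_fraction = if (any(labeled))
                 sum(d$genotype == "tumor", na.rm = TRUE) / sum(labeled)
               else NA_real_)
  }))
  data.frame(sample = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

as_assignments <- function(x) {
  if (inherits(x, "genotype_mixture")) x$assignments
  else if (is.data.frame(x)) x
  else stop("expected a genotype_mixture or assignment data.frame",
            call. = FALSE)
}
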