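#' @import methods
#' @importFrom stats rpois rbinom rnbinom rlnorm rnorm runif median cor sd
#'   quantile prcomp p.adjust pnorm pwilcox setNames aggregate kmeans var lm
#'   poly predict complete.cases
#' @importFrom utils combn read.delim write.table head
NULL

# derive a reproducible sub-stream seed from a top-level seed; keeps results
# below .Machine$integer.max so the same derivation works on 32-bit integers
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok)
    stop(sprintf("'%s' must be a probability in the valid range, got %s",
                 name, format(x)), call. = FALSE)
  invisible(x)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# counts-per-million followed by log1p, the bulk normalization used throughout
cpm_log1p <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("cannot cpm-normalize: sample(s) with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  log1p(sweep(as.matrix(counts), 2L, tot, "/") * 1e6)
}
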