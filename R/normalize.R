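#' Per-sample abundance: counts scaled to one million
#'
#' The length-free "TPM" used throughout the pipeline: the count of each TE
#' divided by the sample's total count, times one million. (Formally this
#' is CPM; a length-normalized variant is available as
#' [calc_tpm_length_normalized()].) Every column sums to 1e6.
#'
#' @param counts Counts tibble (`locus_id` + one numeric column per
#'   sample).
#' @return A tibble of the same shape with scaled values.
#' @export
calc_tpm <- function(counts) {
  m <- counts_matrix(counts)
  n <- colSums(m)
  if (any(n == 0)) {
    abort(sprintf("All-zero sample(s): %s",
                  paste(colnames(m)[n == 0], collapse = ", ")))
  }
  matrix_to_counts(sweep(m, 2, n, "/") * 1e6)
}

#' Length-normalized TPM
#'
#' Standard TPM: per-locus counts are first divided by locus length, then
#' each sample's rates are scaled to sum to one million. Reduces to
#' [calc_tpm()] when all lengths are equal.
#'
#' @inheritParams calc_tpm
#' @param lengths Named numeric vector (or tibble with `locus_id` and
#'   `length`) of locus lengths in nt; must be positive.
#' @return A tibble of TPM values; columns sum to 1e6.
#' @export
calc_tpm_length_normalized <- function(counts, lengths) {
  m <- counts_matrix(counts)
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$locus_id)
  }
  L <- lengths[rownames(m)]
  if (any(is.na(L)) || any(L <= 0)) {
    abort("Every locus needs a positive length.")
  }
  rate <- m / L
  matrix_to_counts(sweep(rate, 2, colSums(rate), "/") * 1e6)
}

#' Expression filter: minimum CPM in a minimum number of samples
#'
#' Keeps loci with at least `min_cpm` counts per million (computed on raw
#' library sizes) in at least `min_samples` samples.
#'
#' @inheritParams calc_tpm
#' @param min_cpm Minimum counts-per-million. Default 1.
#' @param min_samples Minimum number of samples meeting `min_cpm`. Default 2.
#' @return Character vector of retained locus ids.
#' @export
filter_expressed <- function(counts, min_cpm = 1, min_samples = 2) {
  m <- counts_matrix(counts)
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  rownames(m)[rowSums(cpm >= min_cpm) >= min_samples]
}

# 75th-percentile-of-CPM rule for the automatic reference sample
.tmm_ref_auto <- function(m) {
  q75 <- apply(sweep(m, 2, colSums(m), "/"), 2, quantile, p = 0.75)
  which.min(abs(q75 - mean(q75)))
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample against a reference sample,
#' per-locus log2 expression ratios (M), log2 average abundances (A) and
#' delta-method inverse-precision weights are computed on loci with
#' positive counts in both samples; after two-sided trimming of the most
#' extreme `trim_m` fraction by M and `trim_a` fraction by A, the factor is
#' the precision-weighted mean of the surviving M values. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @inheritParams calc_tpm
#' @param trim_m Two-sided trim fraction on M (log-ratios). Default 0.30.
#' @param trim_a Two-sided trim fraction on A (log-abundance). Default 0.05.
#' @param ref Reference sample id, or `NULL` for the sample whose
#'   75th-percentile CPM is closest to the mean of those percentiles.
#' @return A tibble (sample_id, factor) of class `telex_norm`, with the
#'   reference sample and the per-gene M/A/weight audit tables as
#'   attributes.
#' @export
calc_tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, ref = NULL) {
  m <- counts_matrix(counts)
  if (ncol(m) < 2) abort("TMM needs at least 2 samples.")
  N <- colSums(m)
  r <- if (is.null(ref)) .tmm_ref_auto(m) else {
    if (!ref %in% colnames(m)) abort(sprintf("Unknown reference sample '%s'.", ref))
    which(colnames(m) == ref)
  }
  yr <- m[, r]
  nr <- N[r]
  audit <- vector("list", ncol(m))
  logf <- vapply(seq_len(ncol(m)), function(k) {
    yk <- m[, k]
    nk <- N[k]
    ok <- yk > 0 & yr > 0
    if (!any(ok)) {
      warn(sprintf("No loci usable for sample '%s'; factor set to 1.", colnames(m)[k]))
      return(0)
    }
    M <- log2((yk[ok] / nk) / (yr[ok] / nr))
    A <- 0.5 * log2((yk[ok] / nk) * (yr[ok] / nr))
    w <- (nk - yk[ok]) / (nk * yk[ok]) + (nr - yr[ok]) / (nr * yr[ok])
    n <- length(M)
    loM <- floor(n * trim_m) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1
    hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    audit[[k]] <<- tibble(sample_id = colnames(m)[k],
                          locus_id = rownames(m)[ok], M = M, A = A, w = w,
                          trimmed = !keep)
    if (!any(keep)) {
      warn(sprintf("No loci survive trimming for sample '%s'; factor set to 1.",
                   colnames(m)[k]))
      return(0)
    }
    if (k == r) return(0)
    sum(M[keep] / w[keep]) / sum(1 / w[keep])
  }, numeric(1))
  f <- 2^logf
  f <- f / exp(mean(log(f)))
  structure(
    tibble(sample_id = colnames(m), factor = f),
    reference_sample = colnames(m)[r],
    audit = bind_rows(audit),
    class = c("telex_norm", class(tibble())))
}

#' log2 counts per million with a prior count
#'
#' `log2((Y + prior) / (N * f + 2 * prior) * 1e6)` on effective library
#' sizes (raw library size times TMM factor).
#'
#' @inheritParams calc_tpm
#' @param factors A `telex_norm` tibble from [calc_tmm_factors()], or
#'   `NULL` for unit factors.
#' @param prior Prior count added to Y. Default 0.5.
#' @return A tibble (`locus_id` + sample columns) of logCPM values.
#' @export
calc_logcpm <- function(counts, factors = NULL, prior = 0.5) {
  m <- counts_matrix(counts)
  f <- if (is.null(factors)) rep(1, ncol(m)) else {
    setNames(factors$factor, factors$sample_id)[colnames(m)]
  }
  eff <- colSums(m) * f
  matrix_to_counts(log2(sweep(m + prior, 2, eff + 2 * prior, "/") * 1e6))
}
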