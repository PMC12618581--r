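#' Counts per million
#'
#' CPM per gene and sample, optionally with TMM-corrected effective library
#' sizes: CPM_gs = count_gs / effective_size_s * 1e6.
#'
#' @param x an `expr_matrix` or a bare counts matrix.
#' @param norm optional `tmm_norm` result from [tmm_factors()]; when absent,
#'   effective sizes are the raw library sizes.
#' @return numeric matrix of CPM values, same dimensions as the counts.
#' @export
compute_cpm <- function(x, norm = NULL) {
  counts <- if (inherits(x, "expr_matrix")) x$counts else as.matrix(x)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero-library sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  eff <- lib
  if (!is.null(norm)) {
    stopifnot(inherits(norm, "tmm_norm"))
    eff <- norm$effective_size[match(colnames(counts), norm$sample_id)]
    if (anyNA(eff)) stop("normalization result does not cover all samples")
  }
  sweep(counts, 2, eff, "/") * 1e6
}

#' Transcripts per million
#'
#' Length-normalized within-sample composition: rate_g = count_g /
#' (length_g / 1000), TPM_g = rate_g / sum(rate) * 1e6, so TPM sums to 1e6
#' per sample.
#'
#' @param counts numeric vector or gene x sample matrix of read counts.
#' @param lengths numeric vector of transcript lengths in bases (recycled
#'   over samples for a matrix input); for an `expr_matrix` first argument,
#'   taken from its `gene_lengths`.
#' @return TPM values with the shape of `counts`.
#' @export
compute_tpm <- function(counts, lengths = NULL) {
  if (inherits(counts, "expr_matrix")) {
    if (is.null(counts$gene_lengths))
      stop("expression matrix carries no gene lengths")
    lengths <- counts$gene_lengths
    counts <- counts$counts
  }
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (is.matrix(counts)) {
    rate <- counts / (lengths / 1000)
    tot <- colSums(rate)
    if (any(tot == 0)) stop("all-zero counts in sample(s): ",
                            paste(colnames(counts)[tot == 0], collapse = ", "))
    return(sweep(rate, 2, tot, "/") * 1e6)
  }
  if (all(counts == 0)) stop("TPM undefined for all-zero counts")
  rate <- counts / (lengths / 1000)
  rate / sum(rate) * 1e6
}

#' Expression-presence filter
#'
#' A gene is retained when its CPM is strictly greater than `min_cpm` in at
#' least `min_samples` samples ("more than one count per million in at least
#' three samples" at the defaults).
#'
#' @param cpm gene x sample CPM matrix (from [compute_cpm()]).
#' @param min_cpm,min_samples filter parameters.
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(cpm, min_cpm = 1, min_samples = 3) {
  cpm <- as.matrix(cpm)
  if (min_samples > ncol(cpm))
    stop("min_samples exceeds the number of samples")
  keep <- rowSums(cpm > min_cpm) >= min_samples
  rownames(cpm)[keep]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values library normalization. The reference sample is
#' the one whose 75th-percentile CPM is closest to the mean 75th percentile
#' (ties broken by lowest column index). For each sample, M (log2 expression
#' ratio vs the reference) and A (average log2 abundance) are computed on
#' genes positive in both; the upper and lower `tmm_logratio_trim` of M and
#' `tmm_abs_trim` of A are trimmed two-sidedly; the factor is 2 to the
#' inverse-variance-weighted mean of the surviving M-values. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param x an `expr_matrix` or counts matrix with >= 2 samples, each with
#'   positive library size.
#' @param config an [analysis_config()] supplying the trim fractions.
#' @return an object of class `tmm_norm`: data.frame-like list with
#'   `sample_id`, `lib_size`, `factor`, `effective_size`.
#' @export
tmm_factors <- function(x, config = analysis_config()) {
  counts <- if (inherits(x, "expr_matrix")) x$counts else as.matrix(x)
  if (ncol(counts) < 2) stop("TMM requires at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero-library sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  # reference: 75th-percentile CPM closest to the mean across samples
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                    config$tmm_logratio_trim, config$tmm_abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(sample_id = colnames(counts), lib_size = unname(lib),
                 factor = unname(f),
                 effective_size = unname(lib * f), ref_sample = ref),
            class = "tmm_norm")
}

# one observation/reference TMM factor (unscaled)
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim = 0.3, abs_trim = 0.05) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  M <- log2(p_obs[keep] / p_ref[keep])
  A <- (log2(p_obs[keep]) + log2(p_ref[keep])) / 2
  # delta-method binomial variance of M
  v <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
    (n_ref - ref[keep]) / (n_ref * ref[keep])
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1
  hiA <- n + 1 - loA
  in_trim <- rank(M) >= loM & rank(M) <= hiM &
    rank(A) >= loA & rank(A) <= hiA
  if (!any(in_trim)) return(1)
  w <- 1 / v[in_trim]
  2^(sum(M[in_trim] * w) / sum(w))
}

#' @export
print.tmm_norm <- function(x, ...) {
  df <- data.frame(sample_id = x$sample_id, lib_size = x$lib_size,
                   factor = x$factor, effective_size = x$effective_size)
  cat("TMM normalization (reference sample:",
      x$sample_id[x$ref_sample], ")\n")
  print(df)
  invisible(x)
}
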