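#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with its default. Defaults
#' follow the published analysis: FDR controlled at 5%, fold-change threshold
#' of one on the log2 scale, genes kept when CPM exceeds 1 in at least three
#' samples (the estuarine metatranscriptome preset relaxes this to CPM > 0.1
#' in at least two samples), marker thresholds at the 95th TPM percentile with
#' at least two supporting reads, events requiring at least two co-markers
#' besides the positive control, MAG x sample cells kept at >= 10,000 reads
#' and >= 1,000 expressed genes, HMM hits kept at bit score >= 50 and
#' E-value < 1e-10, and ASVs dropped below a relative abundance of 1e-7
#' (i.e. 1e-5 %).
#'
#' @param fdr_alpha overall false discovery rate for stage-wise testing.
#' @param logfc_threshold fold-change threshold tau (log2 units) the DE test
#'   is performed against.
#' @param min_cpm,min_samples expression-presence filter: a gene is expressed
#'   when CPM is strictly greater than `min_cpm` in at least `min_samples`
#'   samples.
#' @param percentile_q percentile (in (0,100)) used to calibrate per-marker
#'   vegetative TPM thresholds.
#' @param min_marker_reads minimum read support for a marker call in a
#'   MAG x sample cell.
#' @param min_comarkers markers (besides the positive control) that must pass
#'   for a cell to be called a sexual-reproduction event.
#' @param mag_min_reads,mag_min_genes MAG x sample retention filter.
#' @param hmm_min_score,hmm_max_evalue HMMER hit filter (score inclusive,
#'   E-value strict).
#' @param asv_min_rel_abund minimum ASV relative abundance (fraction).
#' @param max_nonsexual_tpm,min_fold_separation atlas specificity rule: a
#'   candidate passes when its maximum TPM over non-sexual atlas samples is
#'   at most `max_nonsexual_tpm`, or its sexual-mean/atlas-max fold
#'   separation is at least `min_fold_separation`.
#' @param min_species_expressed species a candidate family must be expressed
#'   in (discovery step 1).
#' @param tmm_logratio_trim,tmm_abs_trim two-sided trim fractions of the TMM
#'   procedure on M-values and A-values respectively.
#' @param spo11_lenient when TRUE the positive control only needs >= 1 read
#'   (no threshold) to gate a cell; default applies the same rule as markers.
#' @param rng_seed seed recorded in the configuration for provenance.
#'
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(fdr_alpha = 0.05,
                            logfc_threshold = 1,
                            min_cpm = 1,
                            min_samples = 3,
                            percentile_q = 95,
                            min_marker_reads = 2,
                            min_comarkers = 2,
                            mag_min_reads = 10000,
                            mag_min_genes = 1000,
                            hmm_min_score = 50,
                            hmm_max_evalue = 1e-10,
                            asv_min_rel_abund = 1e-7,
                            max_nonsexual_tpm = 2,
                            min_fold_separation = 5,
                            min_species_expressed = 3,
                            tmm_logratio_trim = 0.3,
                            tmm_abs_trim = 0.05,
                            spo11_lenient = FALSE,
                            rng_seed = NULL) {
  cfg <- list(
    fdr_alpha = fdr_alpha, logfc_threshold = logfc_threshold,
    min_cpm = min_cpm, min_samples = min_samples,
    percentile_q = percentile_q, min_marker_reads = min_marker_reads,
    min_comarkers = min_comarkers, mag_min_reads = mag_min_reads,
    mag_min_genes = mag_min_genes, hmm_min_score = hmm_min_score,
    hmm_max_evalue = hmm_max_evalue, asv_min_rel_abund = asv_min_rel_abund,
    max_nonsexual_tpm = max_nonsexual_tpm,
    min_fold_separation = min_fold_separation,
    min_species_expressed = min_species_expressed,
    tmm_logratio_trim = tmm_logratio_trim, tmm_abs_trim = tmm_abs_trim,
    spo11_lenient = spo11_lenient, rng_seed = rng_seed
  )
  num <- cfg[!vapply(cfg, is.null, logical(1))]
  num <- num[vapply(num, is.numeric, logical(1))]
  if (any(unlist(num) < 0)) stop("all configuration thresholds must be >= 0")
  if (fdr_alpha <= 0 || fdr_alpha >= 1) stop("fdr_alpha must lie in (0, 1)")
  if (percentile_q <= 0 || percentile_q >= 100)
    stop("percentile_q must lie in (0, 100)")
  structure(cfg, class = "analysis_config")
}

#' Estuarine metatranscriptome preset
#'
#' The relaxed expression-presence filter used for microcosm assemblies:
#' CPM > 0.1 in at least two samples.
#'
#' @param ... overrides passed to [analysis_config()].
#' @return an `analysis_config`.
#' @export
scheldt_config <- function(...) {
  analysis_config(min_cpm = 0.1, min_samples = 2, ...)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  }
  invisible(x)
}
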