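#' Genus-level relative abundance
#'
#' Fraction of total diatom reads per sample attributed to each diatom
#' genus. Samples with zero diatom reads are dropped (with a message).
#'
#' @param reads data.frame with columns sample_id, genus, reads.
#' @param diatom_genera character vector of genera counted as diatoms.
#' @return data.frame (sample_id, genus, rel_abundance); fractions sum to 1
#'   per retained sample.
#' @export
relative_abundance <- function(reads, diatom_genera) {
  d <- reads[reads$genus %in% diatom_genera, , drop = FALSE]
  tot <- tapply(d$reads, d$sample_id, sum)
  zero <- names(tot)[tot == 0]
  dropped <- union(zero, setdiff(unique(reads$sample_id), names(tot)))
  if (length(dropped))
    message("dropping sample(s) with zero diatom reads: ",
            paste(dropped, collapse = ", "))
  d <- d[!d$sample_id %in% zero, , drop = FALSE]
  d$rel_abundance <- d$reads / as.numeric(tot[d$sample_id])
  d[c("sample_id", "genus", "rel_abundance")]
}

#' Mann-Whitney association of abundance with sexual signal
#'
#' Two-sided Mann-Whitney U test comparing the abundance of a genus in
#' samples with a sexual signal against the remaining samples. U counts
#' winning pairs (ties half); the p-value uses the exact null distribution
#' when there are no ties and n1*n2 <= 10,000, and a tie-corrected normal
#' approximation with continuity correction otherwise. The effect size is
#' the rank-biserial correlation r = 2U/(n1 n2) - 1, with a percentile
#' bootstrap 95% confidence interval, and the Bonferroni-corrected p-value
#' min(1, p * m_tests).
#'
#' @param abundance named numeric vector of abundances (names are sample
#'   ids), or unnamed with `signal` a logical vector.
#' @param signal character vector of signal sample ids, or logical vector
#'   parallel to `abundance`.
#' @param m_tests number of tests for the Bonferroni correction.
#' @param n_boot bootstrap resamples for the CI.
#' @param conf confidence level.
#' @return list of class `assoc_result`: n_signal, n_other, U, p_two_sided,
#'   p_bonferroni, effect_size, ci95, method.
#' @export
mannwhitney_assoc <- function(abundance, signal, m_tests = 1,
                              n_boot = 10000, conf = 0.95) {
  if (is.logical(signal)) {
    grp1 <- abundance[signal]
    grp2 <- abundance[!signal]
  } else {
    grp1 <- abundance[names(abundance) %in% signal]
    grp2 <- abundance[!names(abundance) %in% signal]
  }
  n1 <- length(grp1); n2 <- length(grp2)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  res <- mw_u_test(grp1, grp2)
  rb <- 2 * res$U / (n1 * n2) - 1
  boot <- vapply(seq_len(n_boot), function(i) {
    a <- sample(grp1, n1, replace = TRUE)
    b <- sample(grp2, n2, replace = TRUE)
    2 * mw_u_stat(a, b) / (n1 * n2) - 1
  }, numeric(1))
  ci <- unname(stats::quantile(boot, c((1 - conf) / 2, (1 + conf) / 2)))
  structure(list(n_signal = n1, n_other = n2, U = res$U,
                 p_two_sided = res$p,
                 p_bonferroni = min(1, res$p * m_tests),
                 effect_size = rb, ci95 = ci, method = res$method),
            class = "assoc_result")
}

# U statistic of group 1 vs group 2 (wins + half-ties) via ranks
mw_u_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

mw_u_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  U <- mw_u_stat(x, y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 * n2 <= 10000) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)))
    return(list(U = U, p = p, method = "exact"))
  }
  n <- n1 + n2
  tie_tab <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  mu <- n1 * n2 / 2
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  p <- 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
  list(U = U, p = min(1, p),
       method = "normal approximation, tie-corrected")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U(%d, %d) = %g, p = %.3g (%s)\n",
              x$n_signal, x$n_other, x$U, x$p_two_sided, x$method))
  cat(sprintf("  Bonferroni p = %.3g; effect size (rank-biserial) = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$p_bonferroni, x$effect_size, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Filter a metabarcoding ASV table
#'
#' Removes ASVs that are unidentified at kingdom or infrakingdom level,
#' belong to the phylum Metazoa or the classes Embryophyceae/Streptophyta,
#' or fall below the minimum relative abundance (fraction of total reads
#' after the taxonomic removal; default 1e-7, i.e. 1e-5 %). Relative
#' abundances are recomputed after removal.
#'
#' @param counts data.frame with columns asv_id, sample_id, reads.
#' @param taxonomy data.frame with columns asv_id, kingdom, infrakingdom,
#'   phylum, class (NA or "" meaning unidentified).
#' @param config an [analysis_config()].
#' @return list: `counts` (filtered rows with a rel_abundance column over
#'   the retained total) and `removed` (asv_id, reason).
#' @export
filter_asv_table <- function(counts, taxonomy,
                             config = analysis_config()) {
  tax <- taxonomy
  unident <- function(v) is.na(v) | v == "" | grepl("^unidentified$", v,
                                                    ignore.case = TRUE)
  reason <- rep(NA_character_, nrow(tax))
  reason[unident(tax$kingdom) | unident(tax$infrakingdom)] <-
    "unidentified kingdom/infrakingdom"
  reason[is.na(reason) & tax$phylum %in% "Metazoa"] <- "Metazoa"
  reason[is.na(reason) & tax$class %in% c("Embryophyceae", "Streptophyta")] <-
    "Embryophyceae/Streptophyta"
  bad_tax <- tax$asv_id[!is.na(reason)]
  kept <- counts[!counts$asv_id %in% bad_tax, , drop = FALSE]
  tot <- sum(kept$reads)
  asv_tot <- tapply(kept$reads, kept$asv_id, sum)
  low <- names(asv_tot)[asv_tot / tot < config$asv_min_rel_abund]
  removed <- rbind(
    data.frame(asv_id = bad_tax, reason = reason[!is.na(reason)],
               stringsAsFactors = FALSE),
    if (length(low))
      data.frame(asv_id = low, reason = "low abundance",
                 stringsAsFactors = FALSE))
  kept <- kept[!kept$asv_id %in% low, , drop = FALSE]
  tot2 <- sum(kept$reads)
  kept$rel_abundance <- kept$reads / tot2
  list(counts = kept, removed = removed)
}
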