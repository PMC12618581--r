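#' Fold-change-threshold differential expression test for one stage
#'
#' Stand-in DE engine contrasting sexual samples of one mating stage against
#' the vegetative controls of the same species, on TMM-normalized log2(CPM +
#' 0.5). The effect is the difference of group means. The p-value tests
#' against the fold-change threshold tau (TREAT-style): the t statistic is
#' (|log2FC| - tau)/se, floored at 0 when |log2FC| <= tau (then p = 1), and
#' p = P(|T_df| >= t).
#'
#' Two variance estimators are available. The default, `"moderated"`,
#' estimates each gene's residual variance from the one-way layout over all
#' condition groups of the species (every stage plus the control) and
#' squeezes it towards a mean-expression-dependent prior by empirical Bayes
#' (log-variance lowess trend on average log-CPM; prior df by the standard
#' moments estimator), adding the prior df to the residual df. With few
#' replicates this is essential: an unmoderated t null has so few df that no
#' gene can reach the small p-values that survive genome-wide screening.
#' `"welch"` uses the plain per-contrast Welch standard error and
#' Satterthwaite df.
#'
#' Externally produced per-gene DE summaries (e.g. from a negative-binomial
#' GLM engine) can be substituted anywhere downstream: all integration
#' functions consume plain DE record data frames with columns `gene_id`,
#' `species`, `stage`, `log2fc`, `se`, `p_raw`.
#'
#' @param x an `expr_matrix` for one or more species.
#' @param species species to contrast.
#' @param stage mating stage ("S", "P", "GZ" or "A").
#' @param config an [analysis_config()]; uses `logfc_threshold` and the CPM
#'   presence filter.
#' @param norm optional precomputed `tmm_norm` for the species' samples.
#' @param var_mode "moderated" (default) or "welch".
#' @return data.frame of DE records for the retained genes.
#' @export
de_test_stage <- function(x, species, stage, config = analysis_config(),
                          norm = NULL, var_mode = c("moderated", "welch")) {
  stopifnot(inherits(x, "expr_matrix"))
  var_mode <- match.arg(var_mode)
  sel <- x$samples$species == species
  if (!any(sel)) stop("no samples for species ", species)
  xs <- subset_samples(x, which(sel))
  grp_sex <- xs$samples$condition_class == "sexual" & xs$samples$stage == stage
  grp_ctl <- xs$samples$condition_class == "vegetative_control"
  if (sum(grp_sex) < 2 || sum(grp_ctl) < 2)
    stop(sprintf("contrast %s/%s needs >= 2 sexual and >= 2 control replicates",
                 species, stage))
  if (is.null(norm)) norm <- tmm_factors(xs, config)
  cpm <- compute_cpm(xs, norm)
  keep <- filter_expressed(cpm, config$min_cpm, config$min_samples)
  lcpm <- log2(cpm[keep, , drop = FALSE] + 0.5)
  a <- lcpm[, grp_sex, drop = FALSE]
  b <- lcpm[, grp_ctl, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  lfc <- rowMeans(a) - rowMeans(b)
  if (var_mode == "welch") {
    v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
    se <- pmax(sqrt(v1 / n1 + v2 / n2), 1e-8)
    df <- (v1 / n1 + v2 / n2)^2 /
      (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    df[!is.finite(df)] <- n1 + n2 - 2
  } else {
    grp <- paste(xs$samples$condition_class, xs$samples$stage)
    vs <- pooled_group_variance(lcpm, grp)
    sq <- squeeze_variance(vs$s2, vs$df, A = rowMeans(lcpm))
    se <- pmax(sqrt(sq$s2_post * (1 / n1 + 1 / n2)), 1e-8)
    df <- vs$df + sq$df_prior
  }
  tstat <- pmax(abs(lfc) - config$logfc_threshold, 0) / se
  p <- pmin(1, 2 * stats::pt(tstat, df, lower.tail = FALSE))
  data.frame(gene_id = rownames(a), species = species, stage = stage,
             log2fc = unname(lfc), se = unname(se), p_raw = unname(p),
             stringsAsFactors = FALSE)
}

# residual variance of a one-way layout (per-gene), pooled across groups
pooled_group_variance <- function(lcpm, groups) {
  groups <- as.character(groups)
  rss <- 0
  df <- 0
  for (g in unique(groups)) {
    m <- lcpm[, groups == g, drop = FALSE]
    if (ncol(m) < 2) next
    rss <- rss + rowSums((m - rowMeans(m))^2)
    df <- df + ncol(m) - 1
  }
  if (df < 1) stop("no residual degrees of freedom for variance estimation")
  list(s2 = rss / df, df = df)
}

# empirical-Bayes squeezing of sample variances towards a trend prior
# (scaled-F moments estimator for the prior df; lowess of the log-variance
# on average log-CPM for the prior value)
squeeze_variance <- function(s2, df, A = NULL) {
  e <- log(pmax(s2, 1e-10)) - digamma(df / 2) + log(df / 2)
  if (!is.null(A) && length(s2) >= 10) {
    lo <- stats::lowess(A, e, f = 0.5)
    ebar <- stats::approx(lo$x, lo$y, xout = A, rule = 2, ties = mean)$y
  } else {
    ebar <- rep(mean(e), length(e))
  }
  evar <- stats::var(e - ebar) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(ebar + digamma(df_prior / 2) - log(df_prior / 2))
    s2_post <- (df_prior * s2_prior + df * s2) / (df_prior + df)
  } else {
    df_prior <- Inf
    s2_prior <- exp(ebar)
    s2_post <- s2_prior
  }
  list(s2_post = s2_post, df_prior = df_prior, s2_prior = s2_prior)
}

# Newton solve of trigamma(y) = x
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Sidak aggregation of stage p-values
#'
#' Gene-level p-value over k per-stage p-values: 1 - (1 - min p)^k.
#'
#' @param p numeric vector of p-values in `[0, 1]` (one gene's stages).
#' @return a single aggregated p-value.
#' @export
sidak_aggregate <- function(p) {
  if (length(p) == 0) stop("sidak_aggregate needs at least one p-value")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  1 - (1 - min(p))^length(p)
}

#' Stage-wise multiple-testing adjustment
#'
#' Two-step procedure controlling the overall FDR: per-gene Sidak
#' aggregation of stage p-values, Benjamini-Hochberg screening of the
#' aggregates at level alpha, then within each passing gene a Holm
#' adjustment of its stage p-values compared against the adjusted
#' confirmation level alpha * R / m (R = genes passing screening, m = genes
#' tested). A stage can only be significant for a gene that passed
#' screening.
#'
#' @param records data.frame of DE records (one species), columns `gene_id`,
#'   `stage`, `log2fc`, `p_raw` (plus any others, carried through).
#' @param alpha overall FDR level.
#' @return an object of class `stagewise_de`: list with `genes` (gene_id,
#'   p_aggregate, q_screen, passes_screen), `stages` (per gene x stage:
#'   p_holm, significant, direction) and `alpha_conf`.
#' @export
stagewise_adjust <- function(records, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stopifnot(all(c("gene_id", "stage", "log2fc", "p_raw") %in% names(records)))
  sp <- split(records$p_raw, records$gene_id)
  p_agg <- vapply(sp, sidak_aggregate, numeric(1))
  genes <- data.frame(gene_id = names(sp), p_aggregate = unname(p_agg),
                      stringsAsFactors = FALSE)
  genes$q_screen <- stats::p.adjust(genes$p_aggregate, method = "BH")
  genes$passes_screen <- genes$q_screen <= alpha
  m <- nrow(genes)
  R <- sum(genes$passes_screen)
  alpha_conf <- alpha * R / m
  stages <- records
  stages$p_holm <- NA_real_
  stages$significant <- FALSE
  for (g in genes$gene_id[genes$passes_screen]) {
    idx <- which(stages$gene_id == g)
    stages$p_holm[idx] <- stats::p.adjust(stages$p_raw[idx], method = "holm")
    stages$significant[idx] <- stages$p_holm[idx] <= alpha_conf
  }
  stages$direction <- ifelse(stages$log2fc >= 0, "up", "down")
  structure(list(genes = genes, stages = stages, alpha = alpha,
                 alpha_conf = alpha_conf, n_screened = m, n_passing = R),
            class = "stagewise_de")
}

#' @export
print.stagewise_de <- function(x, ...) {
  cat(sprintf(
    "Stage-wise DE: %d genes screened, %d passing (alpha = %g, alpha_conf = %g)\n",
    x$n_screened, x$n_passing, x$alpha, x$alpha_conf))
  cat(sprintf("  %d significant gene x stage records\n",
              sum(x$stages$significant)))
  invisible(x)
}

#' Run the per-stage DE tests and stage-wise adjustment for one species
#'
#' @param x an `expr_matrix`.
#' @param species species to analyse.
#' @param config an [analysis_config()].
#' @return a `stagewise_de` object carrying species/stage columns.
#' @export
de_integrate_species <- function(x, species, config = analysis_config()) {
  sel <- x$samples$species == species & x$samples$condition_class == "sexual"
  stages <- unique(x$samples$stage[sel])
  if (!length(stages)) stop("no sexual samples for species ", species)
  xs <- subset_samples(x, which(x$samples$species == species))
  norm <- tmm_factors(xs, config)
  recs <- do.call(rbind, lapply(stages, function(st)
    de_test_stage(xs, species, st, config, norm = norm)))
  stagewise_adjust(recs, config$fdr_alpha)
}

#' Family-level fold-change profiles
#'
#' Average log2 fold change of the significantly DE member genes of each
#' gene family, per (species, stage) cell; cells with no significant member
#' are omitted.
#'
#' @param stagewise a `stagewise_de` (or a list of them, one per species)
#'   whose `stages` carry `species` columns.
#' @param families a `gene_family_table`.
#' @return data.frame with columns family_id, species, stage, mean_log2fc,
#'   n_de_genes.
#' @export
family_logfc_profile <- function(stagewise, families) {
  if (inherits(stagewise, "stagewise_de")) stagewise <- list(stagewise)
  st <- do.call(rbind, lapply(stagewise, function(s) s$stages))
  st <- st[st$significant, , drop = FALSE]
  st$family_id <- family_of(families, st$gene_id)
  st <- st[!is.na(st$family_id), , drop = FALSE]
  if (!nrow(st))
    return(data.frame(family_id = character(), species = character(),
                      stage = character(), mean_log2fc = numeric(),
                      n_de_genes = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(log2fc ~ family_id + species + stage, st, mean)
  n <- stats::aggregate(log2fc ~ family_id + species + stage, st, length)
  names(agg)[4] <- "mean_log2fc"
  agg$n_de_genes <- n$log2fc
  agg[order(agg$family_id, agg$species, agg$stage), , drop = FALSE]
}

#' Cross-species/stage sharing and correlation of family fold changes
#'
#' For every pair of (species, stage) cells: the number of gene families
#' with significantly DE genes in both, and the Pearson correlation between
#' the families' average fold changes over the shared families (reported
#' only when >= 3 families are shared; two-sided t-based p-value with
#' n_shared - 2 degrees of freedom).
#'
#' @param profile output of [family_logfc_profile()].
#' @return list of class `cross_correlation` with matrices `n_shared`, `r`,
#'   `p` (cells as rows/columns) and `diag_counts` (families with DE genes
#'   per cell).
#' @export
cross_stage_correlation <- function(profile) {
  cells <- unique(profile[c("species", "stage")])
  if (nrow(cells) < 2) stop("need at least two (species, stage) cells")
  cells <- cells[order(cells$species, cells$stage), , drop = FALSE]
  ids <- paste(cells$species, cells$stage, sep = ":")
  k <- length(ids)
  key <- paste(profile$species, profile$stage, sep = ":")
  vecs <- lapply(ids, function(id) {
    pr <- profile[key == id, , drop = FALSE]
    stats::setNames(pr$mean_log2fc, pr$family_id)
  })
  names(vecs) <- ids
  n_shared <- matrix(0L, k, k, dimnames = list(ids, ids))
  r <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  p <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      shared <- intersect(names(vecs[[i]]), names(vecs[[j]]))
      n_shared[i, j] <- length(shared)
      if (i == j) { r[i, j] <- 1; next }
      if (length(shared) >= 3) {
        a <- vecs[[i]][shared]; b <- vecs[[j]][shared]
        if (stats::sd(a) > 0 && stats::sd(b) > 0) {
          rr <- stats::cor(a, b)
          r[i, j] <- rr
          dfree <- length(shared) - 2
          tt <- rr * sqrt(dfree / max(1 - rr^2, 1e-12))
          p[i, j] <- 2 * stats::pt(abs(tt), dfree, lower.tail = FALSE)
        }
      }
    }
  }
  structure(list(n_shared = n_shared, r = r, p = p,
                 diag_counts = diag(n_shared)),
            class = "cross_correlation")
}

#' @export
print.cross_correlation <- function(x, ...) {
  cat("Shared DE families (upper) / Pearson r (lower):\n")
  k <- nrow(x$n_shared)
  out <- matrix("", k, k, dimnames = dimnames(x$n_shared))
  out[upper.tri(out)] <- x$n_shared[upper.tri(out)]
  diag(out) <- x$diag_counts
  out[lower.tri(out)] <- ifelse(is.na(x$r[lower.tri(out)]), ".",
                                sprintf("%.2f", x$r[lower.tri(out)]))
  print(out, quote = FALSE)
  invisible(x)
}
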