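#' Five-step data-driven discovery of conserved sex marker families
#'
#' Steps 1-3 of the discovery procedure. Step 1 keeps diatom-specific
#' families expressed (per the CPM presence filter) in at least
#' `config$min_species_expressed` of the species analysed. Step 2 keeps
#' families for which, in every species where the family is expressed, every
#' expressed member gene is significantly upregulated (significant in at
#' least one stage with positive fold change, and significantly
#' downregulated in none). Step 3 ranks the survivors by the average log2
#' fold change pooled over all significant upregulated (gene, stage)
#' observations across species, descending, ties broken by family id.
#' Steps 4-5 (atlas specificity verification and top-k selection) are
#' performed by [specificity_filter()].
#'
#' @param families a `gene_family_table`.
#' @param stagewise named list of `stagewise_de` results, one per species.
#' @param expr named list of `expr_matrix`, one per species (the sexual
#'   experiment of each species), used for the expression-presence filter.
#' @param config an [analysis_config()].
#' @return data.frame of class `marker_candidates`: family_id, status
#'   ("excluded_step1", "excluded_step2" or "ranked"), exclusion_step (NA or
#'   1:2), n_species_expressed, rank_score, rank (NA unless ranked).
#' @export
discover_markers <- function(families, stagewise, expr,
                             config = analysis_config()) {
  stopifnot(inherits(families, "gene_family_table"))
  if (length(expr) < config$min_species_expressed)
    stop("need expression data for at least ",
         config$min_species_expressed, " species")
  fams <- family_ids(families)
  if (!length(fams)) stop("empty family table")
  specific <- is_diatom_specific(families)

  # per species, the set of expressed genes at the default presence filter
  expressed <- lapply(expr, function(x)
    filter_expressed(compute_cpm(x), config$min_cpm, config$min_samples))

  gene_fam <- families$genes
  res <- data.frame(family_id = fams, status = "ranked",
                    exclusion_step = NA_integer_,
                    n_species_expressed = 0L, rank_score = NA_real_,
                    rank = NA_integer_, stringsAsFactors = FALSE)

  # species where each family is expressed (>=1 expressed member gene)
  fam_expr_species <- lapply(fams, function(f) {
    members <- gene_fam[gene_fam$family_id == f, , drop = FALSE]
    sps <- unique(members$species[members$gene_id %in%
                                    unlist(expressed, use.names = FALSE)])
    intersect(sps, names(expr))
  })
  names(fam_expr_species) <- fams
  res$n_species_expressed <- lengths(fam_expr_species)

  # step 1: diatom-specific, expressed in >= min_species_expressed species
  step1_fail <- !(specific[fams] & res$n_species_expressed >=
                    config$min_species_expressed)
  res$status[step1_fail] <- "excluded_step1"
  res$exclusion_step[step1_fail] <- 1L

  # per-gene significance summary across the species' stage-wise results
  st <- do.call(rbind, lapply(stagewise, function(s) s$stages))
  sig_up <- st$significant & st$direction == "up"
  sig_down <- st$significant & st$direction == "down"
  gene_up <- tapply(sig_up, st$gene_id, any)
  gene_down <- tapply(sig_down, st$gene_id, any)

  for (i in which(!step1_fail)) {
    f <- fams[i]
    ok <- TRUE
    for (sp in fam_expr_species[[f]]) {
      members <- genes_of(families, f, sp)
      members <- intersect(members, expressed[[sp]])
      up <- gene_up[members]
      down <- gene_down[members]
      up[is.na(up)] <- FALSE
      down[is.na(down)] <- FALSE
      if (!all(up) || any(down)) { ok <- FALSE; break }
    }
    if (!ok) {
      res$status[i] <- "excluded_step2"
      res$exclusion_step[i] <- 2L
    }
  }

  # step 3: pooled mean log2FC over significant upregulated observations
  st_up <- st[sig_up, , drop = FALSE]
  st_up$family_id <- family_of(families, st_up$gene_id)
  ranked <- which(res$status == "ranked")
  pooled <- tapply(st_up$log2fc, st_up$family_id, mean)
  res$rank_score[ranked] <- unname(pooled[res$family_id[ranked]])
  ord <- ranked[order(-res$rank_score[ranked], res$family_id[ranked])]
  res$rank[ord] <- seq_along(ord)
  res <- res[order(is.na(res$rank), res$rank, res$family_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("marker_candidates", "data.frame")
  res
}

#' Atlas specificity filter and top-k marker selection
#'
#' Steps 4-5 of the discovery procedure: the sex-specific expression of the
#' top-ranked candidate families is verified against a vegetative expression
#' atlas. A candidate passes when its maximum TPM over non-sexual atlas
#' samples is at most `config$max_nonsexual_tpm`, or when the ratio of its
#' mean sexual TPM to that maximum is at least `config$min_fold_separation`.
#' The atlas was inspected visually in the original analysis; this rule is
#' the configurable operationalization of "negligible expression".
#'
#' @param candidates `marker_candidates` from [discover_markers()].
#' @param atlas an `expr_matrix` with condition_class "atlas" samples and
#'   gene lengths (the atlas species).
#' @param sexual an `expr_matrix` with sexual samples and gene lengths for
#'   the same species.
#' @param families a `gene_family_table`.
#' @param config an [analysis_config()].
#' @param top_n how many top-ranked candidates to verify (default 10).
#' @param k how many passing candidates to select (default 4).
#' @return list of class `specificity_result`: `table` (per verified
#'   candidate: max_nonsexual_tpm, sexual_mean_tpm, fold_separation, passes,
#'   testable) and `selected` (family ids of the top `k` passing
#'   candidates, in rank order).
#' @export
specificity_filter <- function(candidates, atlas, sexual, families,
                               config = analysis_config(),
                               top_n = 10, k = 4) {
  stopifnot(inherits(candidates, "marker_candidates"))
  ranked <- candidates[!is.na(candidates$rank), , drop = FALSE]
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  ranked <- utils::head(ranked, top_n)
  atlas_sp <- unique(atlas$samples$species)
  tpm_atlas <- compute_tpm(atlas)
  nonsex <- atlas$samples$condition_class != "sexual"
  tpm_sex <- compute_tpm(sexual)
  sex_cols <- sexual$samples$condition_class == "sexual"
  eps <- 1e-6
  rows <- lapply(seq_len(nrow(ranked)), function(i) {
    f <- ranked$family_id[i]
    members <- genes_of(families, f, atlas_sp)
    members_a <- intersect(members, rownames(tpm_atlas))
    if (!length(members_a)) {
      return(data.frame(family_id = f, rank = ranked$rank[i],
                        max_nonsexual_tpm = NA_real_,
                        sexual_mean_tpm = NA_real_,
                        fold_separation = NA_real_, testable = FALSE,
                        passes = FALSE, stringsAsFactors = FALSE))
    }
    mx <- max(tpm_atlas[members_a, nonsex, drop = FALSE])
    members_s <- intersect(members, rownames(tpm_sex))
    sm <- if (length(members_s))
      mean(tpm_sex[members_s, sex_cols, drop = FALSE]) else 0
    fs <- sm / (mx + eps)
    data.frame(family_id = f, rank = ranked$rank[i],
               max_nonsexual_tpm = mx, sexual_mean_tpm = sm,
               fold_separation = fs, testable = TRUE,
               passes = mx <= config$max_nonsexual_tpm ||
                 fs >= config$min_fold_separation,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  selected <- utils::head(tab$family_id[tab$passes], k)
  structure(list(table = tab, selected = selected), class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat("Atlas specificity verification:\n")
  print(x$table)
  cat("Selected markers:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Curated marker selection (flagella genes)
#'
#' Keep candidate genes that are expressed during sex and significantly
#' upregulated in at least one stage of the designated (centric) species.
#'
#' @param candidates data.frame with columns `gene_id`, `family_id`.
#' @param stagewise a `stagewise_de` for the designated species.
#' @param expr an `expr_matrix` for that species.
#' @param config an [analysis_config()].
#' @return the subset of `candidates` that pass, with their families.
#' @export
select_curated_markers <- function(candidates, stagewise, expr,
                                   config = analysis_config()) {
  if (!nrow(candidates)) stop("empty candidate list")
  sex_cols <- expr$samples$condition_class == "sexual"
  cpm <- compute_cpm(expr)[, sex_cols, drop = FALSE]
  expressed <- filter_expressed(cpm, config$min_cpm,
                                min(config$min_samples, ncol(cpm)))
  st <- stagewise$stages
  up <- st$gene_id[st$significant & st$direction == "up"]
  keep <- candidates$gene_id %in% expressed & candidates$gene_id %in% up
  candidates[keep, , drop = FALSE]
}

#' Matched control-marker selection
#'
#' Control families estimate the false-positive rate of event calling. A
#' family is eligible when it (1) occurs in at least three of the four
#' reference species, (2) consists of single-copy orthologs allowing one
#' duplication in a single species, and (3) shows no significant
#' upregulation during sex in any species. Each target marker is then
#' matched greedily (in target order) to the nearest unused eligible family
#' by Euclidean distance in (log10 mean non-sexual TPM, CV) space.
#'
#' @param families a `gene_family_table`.
#' @param stagewise named list of `stagewise_de` per species.
#' @param expr named list of `expr_matrix` per species with gene lengths;
#'   non-sexual samples are used for the TPM statistics.
#' @param targets character vector of target marker family ids, in matching
#'   order (e.g. M1-M4 then the positive control).
#' @param exclude family ids excluded a priori (e.g. poor phylogenetic
#'   resolution).
#' @param config an [analysis_config()].
#' @return data.frame of class `control_panel`: target_family, control_family,
#'   target mean/CV, control mean/CV, match_distance.
#' @export
select_control_markers <- function(families, stagewise, expr, targets,
                                   exclude = character(),
                                   config = analysis_config()) {
  cc <- copy_counts(families)
  n_present <- rowSums(cc >= 1)
  single_ok <- apply(cc, 1, function(x) {
    x <- x[x > 0]
    all(x <= 2) && sum(x == 2) <= 1
  })
  st <- do.call(rbind, lapply(stagewise, function(s) s$stages))
  up_genes <- st$gene_id[st$significant & st$direction == "up"]
  up_fams <- unique(family_of(families, up_genes))
  eligible <- rownames(cc)[n_present >= 3 & single_ok]
  eligible <- setdiff(eligible, c(up_fams, targets, exclude))

  fam_stats <- function(f) {
    vals <- unlist(lapply(expr, function(x) {
      if (is.null(x$gene_lengths)) return(NULL)
      members <- intersect(genes_of(families, f), rownames(x$counts))
      if (!length(members)) return(NULL)
      nonsex <- x$samples$condition_class != "sexual"
      if (!any(nonsex)) return(NULL)
      compute_tpm(x)[members, nonsex, drop = FALSE]
    }), use.names = FALSE)
    if (is.null(vals) || !length(vals)) return(c(NA_real_, NA_real_))
    m <- mean(vals)
    c(m, if (m > 0) stats::sd(vals) / m else 0)
  }
  eps <- 1e-6
  cand_stats <- t(vapply(eligible, fam_stats, numeric(2)))
  ok <- !is.na(cand_stats[, 1])
  eligible <- eligible[ok]
  cand_stats <- cand_stats[ok, , drop = FALSE]
  if (length(eligible) < length(targets))
    stop(sprintf("only %d eligible control families for %d targets",
                 length(eligible), length(targets)))
  tgt_stats <- t(vapply(targets, fam_stats, numeric(2)))
  used <- logical(length(eligible))
  out <- lapply(seq_along(targets), function(i) {
    d <- sqrt((log10(cand_stats[, 1] + eps) - log10(tgt_stats[i, 1] + eps))^2 +
                (cand_stats[, 2] - tgt_stats[i, 2])^2)
    d[used] <- Inf
    j <- which.min(d)
    used[j] <<- TRUE
    data.frame(target_family = targets[i], control_family = eligible[j],
               target_mean_tpm = tgt_stats[i, 1], target_cv = tgt_stats[i, 2],
               control_mean_tpm = cand_stats[j, 1], control_cv = cand_stats[j, 2],
               match_distance = d[j], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("control_panel", "data.frame")
  out
}

#' Marker panel
#'
#' An ordered set of marker families with display labels, a positive-control
#' family, and a clade-applicability tag per family determining which panel
#' is evaluated for a MAG ("raphid_pennate", "centric" or "all_diatoms").
#'
#' @param labels character vector of marker labels (e.g. M1-M4, SIG1, ...).
#' @param family_ids family id per label.
#' @param applicability per-label tag in c("raphid_pennate", "centric",
#'   "all_diatoms").
#' @param positive_control label of the positive-control marker (e.g.
#'   SPO11-2); must be one of `labels`.
#' @return data.frame of class `marker_panel`.
#' @export
marker_panel <- function(labels, family_ids, applicability,
                         positive_control) {
  stopifnot(length(labels) == length(family_ids),
            length(labels) == length(applicability))
  if (anyDuplicated(labels)) stop("marker labels must be unique")
  ok <- c("raphid_pennate", "centric", "all_diatoms")
  if (!all(applicability %in% ok))
    stop("applicability must be one of: ", paste(ok, collapse = ", "))
  if (!positive_control %in% labels)
    stop("positive_control must be one of the labels")
  out <- data.frame(label = labels, family_id = family_ids,
                    applicability = applicability,
                    is_positive_control = labels == positive_control,
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' Panel markers applicable to a MAG clade
#'
#' @param panel a `marker_panel`.
#' @param clade "raphid_pennate" or "centric".
#' @param include_pc include the positive control?
#' @return character vector of labels.
#' @export
panel_for_clade <- function(panel, clade, include_pc = FALSE) {
  keep <- panel$applicability %in% c(clade, "all_diatoms")
  if (!include_pc) keep <- keep & !panel$is_positive_control
  panel$label[keep]
}
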