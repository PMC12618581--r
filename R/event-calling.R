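#' MAG metatranscriptome dataset
#'
#' Long-format container for MAG-resolved metatranscriptomic expression:
#' one row per (MAG, sample, gene) with read count and gene length, plus MAG
#' metadata (clade, genus) and sample metadata (station, depth, size
#' fraction, season).
#'
#' @param expr data.frame with columns mag_id, sample_id, gene_id, count,
#'   length.
#' @param mags data.frame with columns mag_id, clade (one of
#'   "raphid_pennate", "centric", "other"), genus.
#' @param samples data.frame with columns sample_id, station, depth ("SRF"
#'   or "DCM"), size_fraction and optionally season.
#' @return an object of class `mag_dataset`.
#' @export
mag_dataset <- function(expr, mags, samples) {
  stopifnot(all(c("mag_id", "sample_id", "gene_id", "count", "length")
                %in% names(expr)),
            all(c("mag_id", "clade") %in% names(mags)),
            all(c("sample_id", "station") %in% names(samples)))
  if (any(expr$count < 0)) stop("counts must be non-negative")
  if (any(expr$length <= 0)) stop("gene lengths must be positive")
  if (!all(expr$mag_id %in% mags$mag_id)) stop("unknown MAG id in expr")
  if (!all(expr$sample_id %in% samples$sample_id))
    stop("unknown sample id in expr")
  structure(list(expr = as.data.frame(expr), mags = as.data.frame(mags),
                 samples = as.data.frame(samples)),
            class = "mag_dataset")
}

#' @export
print.mag_dataset <- function(x, ...) {
  cat(sprintf("MAG dataset: %d MAGs x %d samples (%d expression records)\n",
              nrow(x$mags), nrow(x$samples), nrow(x$expr)))
  invisible(x)
}

#' Retention filter for MAG x sample cells
#'
#' A cell is kept when the MAG has at least `mag_min_reads` reads (default
#' 10,000) and at least `mag_min_genes` genes with >= 1 read (default
#' 1,000) in that sample; cells below either bound are dropped.
#'
#' @param dataset a `mag_dataset`.
#' @param config an [analysis_config()].
#' @return data.frame: mag_id, sample_id, total_reads, n_genes, keep.
#' @export
filter_mag_samples <- function(dataset, config = analysis_config()) {
  e <- dataset$expr
  key <- paste(e$mag_id, e$sample_id, sep = "\r")
  tot <- tapply(e$count, key, sum)
  ng <- tapply(e$count >= 1, key, sum)
  ids <- strsplit(names(tot), "\r", fixed = TRUE)
  out <- data.frame(
    mag_id = vapply(ids, `[`, "", 1),
    sample_id = vapply(ids, `[`, "", 2),
    total_reads = unname(tot), n_genes = as.integer(unname(ng)),
    stringsAsFactors = FALSE)
  out$keep <- out$total_reads >= config$mag_min_reads &
    out$n_genes >= config$mag_min_genes
  out
}

#' MAG-level TPM
#'
#' TPM computed within each MAG x sample cell, i.e. relative to the reads
#' mapped to that MAG in that sample, correcting for the MAG's relative
#' abundance across samples.
#'
#' @param dataset a `mag_dataset`.
#' @param cells optional data.frame (mag_id, sample_id) restricting which
#'   cells to compute (e.g. the retained cells of [filter_mag_samples()]).
#' @return the expression data.frame with an added `tpm` column.
#' @export
mag_tpm <- function(dataset, cells = NULL) {
  e <- dataset$expr
  if (!is.null(cells)) {
    keep <- paste(e$mag_id, e$sample_id) %in%
      paste(cells$mag_id, cells$sample_id)
    e <- e[keep, , drop = FALSE]
  }
  key <- paste(e$mag_id, e$sample_id)
  rate <- e$count / (e$length / 1000)
  tot <- as.numeric(tapply(rate, key, sum)[key])
  if (any(tot == 0)) stop("cell(s) with zero reads: ",
                          paste(unique(key[tot == 0]), collapse = ", "))
  e$tpm <- rate / tot * 1e6
  e
}

#' Calibrate per-marker vegetative TPM thresholds
#'
#' For each marker family, pools the TPM of all member genes over all
#' non-sexual (vegetative/atlas) samples of the reference experiments and
#' takes the `percentile_q`-th percentile (linear interpolation between
#' order statistics).
#'
#' @param reference a single `expr_matrix` with gene lengths, or a list of
#'   them (one per reference species).
#' @param panel a `marker_panel` (markers and/or controls).
#' @param families a `gene_family_table`.
#' @param config an [analysis_config()].
#' @param per_species when TRUE, also returns per-species percentiles
#'   alongside the pooled threshold.
#' @return data.frame of class `threshold_table`: label, family_id,
#'   threshold, n_values.
#' @export
calibrate_thresholds <- function(reference, panel, families,
                                 config = analysis_config(),
                                 per_species = FALSE) {
  if (inherits(reference, "expr_matrix")) reference <- list(reference)
  q <- config$percentile_q / 100
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    f <- panel$family_id[i]
    vals <- unlist(lapply(reference, function(x) {
      members <- intersect(genes_of(families, f), rownames(x$counts))
      if (!length(members)) return(NULL)
      nonsex <- x$samples$condition_class != "sexual"
      if (!any(nonsex)) return(NULL)
      compute_tpm(x)[members, nonsex, drop = FALSE]
    }), use.names = FALSE)
    if (is.null(vals) || !length(vals))
      stop("family ", f, " has no member gene in any reference species")
    data.frame(label = panel$label[i], family_id = f,
               threshold = unname(stats::quantile(vals, q, type = 7)),
               n_values = length(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "percentile_q") <- config$percentile_q
  attr(out, "percentile_method") <- "linear interpolation (type 7)"
  class(out) <- c("threshold_table", "data.frame")
  out
}

#' Per-marker expression call in one MAG x sample cell
#'
#' A marker label is called expressed in a cell when at least one assigned
#' gene has MAG-level TPM strictly exceeding the marker's calibrated
#' threshold and is supported by at least `min_marker_reads` reads. Genes
#' assigned to a marker but absent from the cell count as zero.
#'
#' @param cell data.frame for one cell with columns gene_id, count, tpm.
#' @param assignment data.frame (gene_id, marker_label) mapping the cell's
#'   genes to markers; a gene maps to at most one marker.
#' @param thresholds a `threshold_table`.
#' @param config an [analysis_config()].
#' @return named logical vector: expressed flag per assigned marker label.
#' @export
call_marker_expression <- function(cell, assignment, thresholds,
                                   config = analysis_config()) {
  labs <- unique(assignment$marker_label)
  miss <- setdiff(labs, thresholds$label)
  if (length(miss))
    stop("no threshold for marker(s): ", paste(miss, collapse = ", "))
  thr <- stats::setNames(thresholds$threshold, thresholds$label)
  idx <- match(assignment$gene_id, cell$gene_id)
  tpm <- ifelse(is.na(idx), 0, cell$tpm[idx])
  cnt <- ifelse(is.na(idx), 0, cell$count[idx])
  pass <- tpm > thr[assignment$marker_label] &
    cnt >= config$min_marker_reads
  vapply(labs, function(l) any(pass[assignment$marker_label == l]),
         logical(1))
}

#' Call sexual-reproduction events
#'
#' For every retained MAG x sample cell: evaluates the positive-control
#' family (SPO11-2) and the clade-appropriate marker panel with
#' [call_marker_expression()]. A cell is an event when the positive control
#' passes and at least `min_comarkers` distinct panel markers pass. MAGs of
#' clade "other" are excluded. With `config$spo11_lenient = TRUE` the
#' positive control only needs >= 1 read.
#'
#' @param dataset a `mag_dataset`.
#' @param assignment data.frame (mag_id, gene_id, marker_label) from
#'   homolog mapping.
#' @param thresholds a `threshold_table` covering the panel and the positive
#'   control.
#' @param panel a `marker_panel` with a positive control.
#' @param config an [analysis_config()].
#' @return data.frame of class `sex_event_calls`: mag_id, sample_id,
#'   spo11_status, passing_markers (comma-separated), tier, is_event,
#'   panel_used.
#' @export
call_events <- function(dataset, assignment, thresholds, panel,
                        config = analysis_config()) {
  flt <- filter_mag_samples(dataset, config)
  cells <- flt[flt$keep, c("mag_id", "sample_id"), drop = FALSE]
  e <- mag_tpm(dataset, cells)
  # only the assigned (marker) genes are needed once cell TPM is computed
  e <- e[e$gene_id %in% assignment$gene_id, , drop = FALSE]
  cell_list <- split(e, paste(e$mag_id, e$sample_id, sep = "\r"))
  asg_by_mag <- split(assignment, assignment$mag_id)
  empty_cell <- data.frame(gene_id = character(), count = numeric(),
                           tpm = numeric(), stringsAsFactors = FALSE)
  clade <- stats::setNames(dataset$mags$clade, dataset$mags$mag_id)
  pc_label <- panel$label[panel$is_positive_control]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    mg <- cells$mag_id[i]; smp <- cells$sample_id[i]
    cl <- clade[[mg]]
    if (cl == "other") return(NULL)
    cell <- cell_list[[paste(mg, smp, sep = "\r")]]
    if (is.null(cell)) cell <- empty_cell
    asg <- asg_by_mag[[mg]]
    if (is.null(asg)) return(NULL)
    applicable <- panel_for_clade(panel, cl, include_pc = FALSE)
    asg <- asg[asg$marker_label %in% c(applicable, pc_label), , drop = FALSE]
    if (!nrow(asg)) return(NULL)
    flags <- call_marker_expression(cell, asg, thresholds, config)
    if (config$spo11_lenient) {
      pc_genes <- asg$gene_id[asg$marker_label == pc_label]
      idx <- match(pc_genes, cell$gene_id)
      spo11 <- any(!is.na(idx) & cell$count[idx] >= 1)
    } else {
      spo11 <- isTRUE(flags[pc_label])
    }
    passing <- names(flags)[flags & names(flags) %in% applicable]
    tier <- length(passing)
    data.frame(mag_id = mg, sample_id = smp, spo11_status = spo11,
               passing_markers = paste(sort(passing), collapse = ","),
               tier = tier,
               is_event = spo11 && tier >= config$min_comarkers,
               panel_used = cl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mag_id = character(), sample_id = character(),
                      spo11_status = logical(), passing_markers = character(),
                      tier = integer(), is_event = logical(),
                      panel_used = character(), stringsAsFactors = FALSE)
  class(out) <- c("sex_event_calls", "data.frame")
  out
}

#' Tier sweep of event counts
#'
#' Number of events at each minimum co-marker requirement 1..4; events at a
#' stricter tier are a subset of those at a looser one.
#'
#' @param calls a `sex_event_calls` data.frame.
#' @param tiers integer vector of co-marker minima.
#' @return named integer vector of event counts.
#' @export
tier_sweep <- function(calls, tiers = 1:4) {
  stats::setNames(vapply(tiers, function(k)
    sum(calls$spo11_status & calls$tier >= k), integer(1)),
    paste0("tier>=", tiers))
}

#' Control-marker false-positive audit
#'
#' Repeats the event calling with the control panel (C1-C4 as markers, PC
#' as positive control) under identical thresholds and rules, returning the
#' per-cell calls and the number of cells showing a control co-expression
#' signal.
#'
#' @param dataset a `mag_dataset`.
#' @param assignment control-gene assignment (mag_id, gene_id,
#'   marker_label).
#' @param thresholds `threshold_table` for the control families.
#' @param panel control `marker_panel` (positive control = PC).
#' @param config an [analysis_config()].
#' @return list: `calls` (per-cell) and `n_cases` (cells with is_event).
#' @export
audit_controls <- function(dataset, assignment, thresholds, panel,
                           config = analysis_config()) {
  calls <- call_events(dataset, assignment, thresholds, panel, config)
  list(calls = calls, n_cases = sum(calls$is_event))
}

#' Summaries of called events
#'
#' Case counts (a case is a MAG showing a signal in one sample) split by
#' MAG clade, distinct stations with at least one event, and the fractions
#' of stations and MAGs involved.
#'
#' @param calls a `sex_event_calls` data.frame.
#' @param dataset the `mag_dataset` the calls came from.
#' @return list of class `event_summary`.
#' @export
summarize_events <- function(calls, dataset) {
  ev <- calls[calls$is_event, , drop = FALSE]
  station <- stats::setNames(dataset$samples$station,
                             dataset$samples$sample_id)
  genus <- stats::setNames(
    if ("genus" %in% names(dataset$mags)) dataset$mags$genus
    else dataset$mags$mag_id, dataset$mags$mag_id)
  clade <- stats::setNames(dataset$mags$clade, dataset$mags$mag_id)
  ev_st <- unique(station[ev$sample_id])
  all_st <- unique(dataset$samples$station)
  ev_mags <- unique(ev$mag_id)
  by_clade <- table(factor(clade[ev$mag_id],
                           levels = c("raphid_pennate", "centric", "other")))
  genus_station <- if (nrow(ev)) {
    gs <- data.frame(station = station[ev$sample_id],
                     genus = genus[ev$mag_id], stringsAsFactors = FALSE)
    stats::aggregate(cbind(n_events = rep(1L, nrow(gs))) ~ station + genus,
                     gs, sum)
  } else data.frame(station = character(), genus = character(),
                    n_events = integer())
  structure(list(
    n_cases = nrow(ev),
    cases_by_clade = by_clade,
    n_event_stations = length(ev_st),
    n_stations = length(all_st),
    station_fraction = length(ev_st) / length(all_st),
    n_event_mags = length(ev_mags),
    n_mags = nrow(dataset$mags),
    mag_fraction = length(ev_mags) / nrow(dataset$mags),
    genus_station = genus_station
  ), class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf("Sexual-reproduction events: %d case(s)\n", x$n_cases))
  cat(sprintf("  stations with events: %d / %d (%.0f%%)\n",
              x$n_event_stations, x$n_stations, 100 * x$station_fraction))
  cat(sprintf("  MAGs with events:     %d / %d (%.0f%%)\n",
              x$n_event_mags, x$n_mags, 100 * x$mag_fraction))
  invisible(x)
}
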