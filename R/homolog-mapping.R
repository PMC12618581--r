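#' Parse a HMMER3 per-sequence hit table (tblout)
#'
#' Reads the whitespace-delimited per-sequence table written by hmmsearch
#' --tblout: field 1 is the target sequence, field 3 the query profile
#' (marker), field 5 the full-sequence E-value and field 6 the full-sequence
#' bit score. Comment lines (leading '#') are skipped. Per-domain tables are
#' not supported.
#'
#' @param path path to a tblout file, or a character vector of its lines.
#' @param source_taxon optional taxon (e.g. MAG id) attached to all hits, or
#'   a function mapping target ids to taxa.
#' @return data.frame with columns target_id, marker_label, evalue, score,
#'   source_taxon.
#' @export
parse_tblout <- function(path, source_taxon = NA_character_) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(data.frame(target_id = character(), marker_label = character(),
                      evalue = numeric(), score = numeric(),
                      source_taxon = character(), stringsAsFactors = FALSE))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 6)
      stop(sprintf("truncated tblout line %d: fewer than 6 fields", lineno[i]))
    ev <- suppressWarnings(as.numeric(f[5]))
    sc <- suppressWarnings(as.numeric(f[6]))
    if (is.na(ev) || is.na(sc))
      stop(sprintf("non-numeric E-value/score on tblout line %d", lineno[i]))
    data.frame(target_id = f[1], marker_label = f[3], evalue = ev, score = sc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$source_taxon <- if (is.function(source_taxon))
    source_taxon(out$target_id) else source_taxon
  out
}

#' Filter HMMER hits
#'
#' Keep hits with full-sequence score >= `hmm_min_score` (inclusive) and
#' E-value strictly below `hmm_max_evalue`, optionally restricted to an
#' allowed set of source taxa (e.g. diatom MAGs).
#'
#' @param hits data.frame from [parse_tblout()].
#' @param config an [analysis_config()].
#' @param allowed_taxa optional character vector of source taxa to retain.
#' @return filtered data.frame.
#' @export
filter_hits <- function(hits, config = analysis_config(),
                        allowed_taxa = NULL) {
  keep <- hits$score >= config$hmm_min_score &
    hits$evalue < config$hmm_max_evalue
  if (!is.null(allowed_taxa)) keep <- keep & hits$source_taxon %in% allowed_taxa
  hits[keep, , drop = FALSE]
}

#' Annotated phylogenetic tree
#'
#' A phylo tree (ape) together with a role per tip: "reference" (sequences
#' that define the marker clade), "outgroup", or "query" (environmental
#' sequences to be classified).
#'
#' @param tree an `ape::phylo` object with branch lengths; internal node
#'   labels, when present, are read as bootstrap support values in `[0,100]`.
#' @param roles named character vector tip_label -> role, covering all tips.
#' @return an object of class `annotated_tree`.
#' @export
annotated_tree <- function(tree, roles) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  if (!all(tree$tip.label %in% names(roles)))
    stop("every tip must have a role")
  roles <- roles[tree$tip.label]
  ok <- c("reference", "outgroup", "query")
  if (!all(roles %in% ok))
    stop("roles must be one of: ", paste(ok, collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("branch lengths must be non-negative")
  structure(list(tree = tree, roles = roles), class = "annotated_tree")
}

#' Read an annotated tree from newick
#'
#' @param path newick file or string.
#' @param roles named character vector tip -> role.
#' @return an `annotated_tree`.
#' @export
read_annotated_tree <- function(path, roles) {
  tree <- if (file.exists(path)) ape::read.tree(path)
  else ape::read.tree(text = path)
  annotated_tree(tree, roles)
}

#' Midpoint rooting
#'
#' Roots the tree at the midpoint of the longest tip-to-tip path,
#' preserving path lengths.
#'
#' @param x an `annotated_tree` or `ape::phylo`.
#' @return the rooted tree, same class as the input.
#' @export
midpoint_root <- function(x) {
  tree <- if (inherits(x, "annotated_tree")) x$tree else x
  if (length(tree$tip.label) < 2) stop("midpoint rooting needs >= 2 tips")
  if (is.null(tree$edge.length)) stop("branch lengths required")
  if (all(tree$edge.length == 0)) stop("all branch lengths are zero")
  rooted <- phangorn::midpoint(tree)
  if (inherits(x, "annotated_tree")) annotated_tree(rooted, x$roles) else rooted
}

#' Phylogenetic selection of environmental marker homologs
#'
#' After midpoint rooting, selects the maximal clades that contain at least
#' one reference tip and no outgroup tips, and whose subtending branch
#' support (internal node label) is at least `min_support`; the support
#' check is skipped when `min_support = 0` or supports are absent. Returns
#' the query tips inside the union of selected clades. This automates the
#' manual "clustering within the original marker clade" curation; the
#' default `min_support = 0` reflects that no numeric support cutoff was
#' applied in the original analysis.
#'
#' @param x an `annotated_tree`.
#' @param min_support minimum bootstrap support of a selected clade.
#' @param reroot midpoint-root the tree first (default TRUE).
#' @return list of class `clade_selection`: `selected_queries` (character),
#'   `clades` (data.frame: clade_id, n_reference, n_query, support) and
#'   `tips_per_clade` (list).
#' @export
select_marker_clade <- function(x, min_support = 0, reroot = TRUE) {
  stopifnot(inherits(x, "annotated_tree"))
  if (!any(x$roles == "reference")) stop("tree contains no reference tips")
  if (reroot) x <- midpoint_root(x)
  tree <- x$tree
  roles <- x$roles
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  support <- rep(NA_real_, ntip + nnode)
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    support[ntip + seq_len(nnode)] <- sup
  }
  # per node: counts of tip roles below it
  n_ref <- n_out <- n_qry <- integer(ntip + nnode)
  tips_below <- vector("list", ntip + nnode)
  count <- function(node) {
    if (node <= ntip) {
      tips_below[[node]] <<- tree$tip.label[node]
      r <- roles[tree$tip.label[node]]
      n_ref[node] <<- r == "reference"
      n_out[node] <<- r == "outgroup"
      n_qry[node] <<- r == "query"
      return(invisible())
    }
    for (k in kids[[as.character(node)]]) count(k)
    ks <- kids[[as.character(node)]]
    tips_below[[node]] <<- unlist(tips_below[ks], use.names = FALSE)
    n_ref[node] <<- sum(n_ref[ks])
    n_out[node] <<- sum(n_out[ks])
    n_qry[node] <<- sum(n_qry[ks])
    invisible()
  }
  count(root)
  qualifies <- function(node) {
    if (n_ref[node] < 1 || n_out[node] > 0) return(FALSE)
    if (min_support > 0 && node > ntip && node != root) {
      s <- support[node]
      if (!is.na(s) && s < min_support) return(FALSE)
    }
    TRUE
  }
  selected <- integer(0)
  walk <- function(node) {
    if (qualifies(node)) { selected <<- c(selected, node); return(invisible()) }
    if (node > ntip) for (k in kids[[as.character(node)]]) walk(k)
    invisible()
  }
  walk(root)
  clades <- data.frame(
    clade_id = paste0("clade", seq_along(selected)),
    node = selected,
    n_reference = n_ref[selected], n_query = n_qry[selected],
    support = support[selected], stringsAsFactors = FALSE)
  tips <- tips_below[selected]
  names(tips) <- clades$clade_id
  queries <- sort(unique(unlist(lapply(tips, function(tp)
    tp[roles[tp] == "query"]), use.names = FALSE)))
  structure(list(selected_queries = queries, clades = clades,
                 tips_per_clade = tips),
            class = "clade_selection")
}

#' @export
print.clade_selection <- function(x, ...) {
  cat(sprintf("Phylogenetic selection: %d clade(s), %d query tip(s) selected\n",
              nrow(x$clades), length(x$selected_queries)))
  if (nrow(x$clades)) print(x$clades[, c("clade_id", "n_reference",
                                         "n_query", "support")])
  invisible(x)
}
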