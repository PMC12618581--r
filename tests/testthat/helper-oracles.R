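# Independent oracles and small fixture builders shared across tests.

# Direct implementation of the trimmed-mean-of-M definition, written with
# order()-based trimming (the package uses rank-based trimming); agrees on
# matrices without tied M/A values.
tmm_oracle <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  fs <- vapply(seq_len(ncol(counts)), function(j) {
    o <- counts[, j]; r <- counts[, ref]
    keep <- o > 0 & r > 0
    if (!any(keep)) return(1)
    M <- log2((o[keep] / lib[j]) / (r[keep] / lib[ref]))
    A <- 0.5 * log2((o[keep] / lib[j]) * (r[keep] / lib[ref]))
    w <- 1 / ((lib[j] - o[keep]) / (lib[j] * o[keep]) +
                (lib[ref] - r[keep]) / (lib[ref] * r[keep]))
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    sel_M <- order(M)[loM:hiM]
    sel_A <- order(A)[loA:hiA]
    sel <- intersect(sel_M, sel_A)
    if (!length(sel)) return(1)
    2^(sum(M[sel] * w[sel]) / sum(w[sel]))
  }, numeric(1))
  fs / exp(mean(log(fs)))
}

# Mann-Whitney U by exhaustive pair enumeration (wins + half ties)
u_oracle <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}

# percentile by explicit sort + linear interpolation between order statistics
pct_oracle <- function(v, q) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * q / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# tree diameter (longest tip-to-tip path) by all-pairs search
tree_diameter <- function(tree) {
  max(ape::cophenetic.phylo(tree))
}

# clade-selection oracle: enumerate every clade of the rooted tree, keep the
# maximal ones containing >= 1 reference and 0 outgroups, collect queries
clade_oracle <- function(rooted_annot) {
  tree <- rooted_annot$tree
  roles <- rooted_annot$roles
  ntip <- length(tree$tip.label)
  clades <- c(as.list(seq_len(ntip)),
              lapply(ntip + seq_len(tree$Nnode), function(nd) {
                unlist(phangorn::Descendants(tree, nd, type = "tips"))
              }))
  tipsets <- lapply(clades, function(ix) tree$tip.label[ix])
  ok <- vapply(tipsets, function(tp)
    any(roles[tp] == "reference") && !any(roles[tp] == "outgroup"),
    logical(1))
  keep <- which(ok)
  maximal <- keep[vapply(keep, function(i) {
    !any(vapply(keep, function(j)
      j != i && all(tipsets[[i]] %in% tipsets[[j]]), logical(1)))
  }, logical(1))]
  sort(unique(unlist(lapply(maximal, function(i) {
    tp <- tipsets[[i]]
    tp[roles[tp] == "query"]
  }))))
}

# small expression matrix: sexual stage-S samples then vegetative controls
make_expr <- function(counts, species = "sp1", n_sex = NULL, lengths = NULL) {
  ns <- ncol(counts)
  if (is.null(n_sex)) n_sex <- ceiling(ns / 2)
  meta <- data.frame(
    sample_id = colnames(counts), species = species,
    condition_class = rep(c("sexual", "vegetative_control"),
                          c(n_sex, ns - n_sex)),
    stage = rep(c("S", "none"), c(n_sex, ns - n_sex)),
    condition_label = rep(c("sex_S", "veg"), c(n_sex, ns - n_sex)),
    replicate = seq_len(ns), stringsAsFactors = FALSE)
  expression_matrix(counts, meta, lengths)
}

# minimal stage-wise result carrying only what downstream consumers read
fake_stagewise <- function(stages_df) {
  structure(list(genes = NULL, stages = stages_df), class = "stagewise_de")
}

# a MAG expression long table with given per-gene counts for one cell
make_cell_expr <- function(mag_id, sample_id, counts, lengths = NULL) {
  ng <- length(counts)
  if (is.null(lengths)) lengths <- rep(1000, ng)
  data.frame(mag_id = mag_id, sample_id = sample_id,
             gene_id = sprintf("%s_g%04d", mag_id, seq_len(ng)),
             count = counts, length = lengths, stringsAsFactors = FALSE)
}
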