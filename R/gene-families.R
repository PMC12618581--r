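#' Homologous gene family table
#'
#' The cross-species bridge: maps genes to homologous gene families and
#' records, per family and species, the copy number, together with a
#' diatom-specificity flag per family (families whose taxonomic profile is
#' restricted to diatoms).
#'
#' @param genes data.frame with columns `gene_id`, `family_id`, `species`.
#'   Every gene maps to at most one family.
#' @param families data.frame with columns `family_id`, `species`,
#'   `copy_count` (one row per family x species where the family occurs) and
#'   `diatom_specific` (logical, constant within a family).
#'
#' @return an object of class `gene_family_table`.
#' @export
gene_family_table <- function(genes, families) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  families <- as.data.frame(families, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "family_id", "species") %in% names(genes)),
            all(c("family_id", "species", "copy_count", "diatom_specific")
                %in% names(families)))
  if (anyDuplicated(genes$gene_id))
    stop("a gene must map to at most one family")
  if (any(families$copy_count < 0)) stop("copy counts must be >= 0")
  # copy counts must be consistent with gene membership where genes are listed
  memb <- stats::aggregate(gene_id ~ family_id + species, genes, length)
  key <- paste(families$family_id, families$species)
  mk <- match(paste(memb$family_id, memb$species), key)
  if (anyNA(mk) ||
      any(memb$gene_id != families$copy_count[mk]))
    stop("copy counts inconsistent with gene membership")
  structure(list(genes = genes, families = families),
            class = "gene_family_table")
}

#' @export
print.gene_family_table <- function(x, ...) {
  cat(sprintf("Gene family table: %d genes, %d families (%d diatom-specific)\n",
              nrow(x$genes), length(unique(x$families$family_id)),
              sum(tapply(x$families$diatom_specific, x$families$family_id,
                         any))))
  invisible(x)
}

#' Family membership of genes
#'
#' @param ft a `gene_family_table`.
#' @param gene_ids character vector.
#' @return character vector of family ids (NA for unmapped genes).
#' @export
family_of <- function(ft, gene_ids) {
  ft$genes$family_id[match(gene_ids, ft$genes$gene_id)]
}

#' Member genes of a family
#'
#' @param ft a `gene_family_table`.
#' @param family_id a single family id.
#' @param species optional species restriction.
#' @return character vector of gene ids.
#' @export
genes_of <- function(ft, family_id, species = NULL) {
  g <- ft$genes[ft$genes$family_id == family_id, , drop = FALSE]
  if (!is.null(species)) g <- g[g$species %in% species, , drop = FALSE]
  g$gene_id
}

#' Per-family attribute helpers
#'
#' `family_ids()` lists all families; `is_diatom_specific()` returns the
#' specificity flag per family; `copy_counts()` returns the family x species
#' copy-number matrix (0 where absent).
#'
#' @param ft a `gene_family_table`.
#' @return see description.
#' @export
family_ids <- function(ft) sort(unique(ft$families$family_id))

#' @rdname family_ids
#' @export
is_diatom_specific <- function(ft) {
  spec <- tapply(ft$families$diatom_specific, ft$families$family_id, any)
  c(spec[family_ids(ft)])
}

#' @rdname family_ids
#' @export
copy_counts <- function(ft) {
  fams <- family_ids(ft)
  sps <- sort(unique(ft$families$species))
  m <- matrix(0, length(fams), length(sps), dimnames = list(fams, sps))
  idx <- cbind(match(ft$families$family_id, fams),
               match(ft$families$species, sps))
  m[idx] <- ft$families$copy_count
  m
}

#' Read a gene family table from TSV files
#'
#' @param genes_file TSV with columns gene_id, family_id, species.
#' @param families_file TSV with columns family_id, species, copy_count,
#'   diatom_specific.
#' @return a `gene_family_table`.
#' @export
read_family_tsv <- function(genes_file, families_file) {
  g <- utils::read.delim(genes_file, stringsAsFactors = FALSE)
  f <- utils::read.delim(families_file, stringsAsFactors = FALSE)
  f$diatom_specific <- as.logical(f$diatom_specific)
  gene_family_table(g, f)
}
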