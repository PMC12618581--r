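#' Expression matrix with sample metadata
#'
#' Container for a gene x sample read-count matrix together with per-sample
#' metadata (species, condition class, mating stage, condition label,
#' replicate) and optional per-gene transcript lengths (required for TPM).
#' Mating stages follow the S/P/GZ/A scheme: sex pheromone signalling (S),
#' gametangia (P), gametes/zygotes (GZ) and auxospores (A); vegetative and
#' atlas samples carry stage "none".
#'
#' @param counts numeric matrix, genes in rows, samples in columns; row and
#'   column names are the gene and sample identifiers. Counts may be
#'   fractional (expectation-based quantification upstream) but not negative.
#' @param sample_meta data.frame with columns `sample_id`, `species`,
#'   `condition_class` (one of "sexual", "vegetative_control", "atlas"),
#'   `stage` (one of "S", "P", "GZ", "A", "none"), `condition_label`,
#'   `replicate`. One row per column of `counts`, matched by `sample_id`.
#' @param gene_lengths optional named numeric vector of transcript lengths in
#'   bases, covering all genes.
#'
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(counts, sample_meta, gene_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  req <- c("sample_id", "species", "condition_class", "stage",
           "condition_label", "replicate")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss))
    stop("sample_meta lacks column(s): ", paste(miss, collapse = ", "))
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  if (!setequal(sample_meta$sample_id, colnames(counts)))
    stop("sample_meta$sample_id must match the columns of counts")
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  if (any(is.na(sample_meta[req])))
    stop("every sample must have complete metadata")
  ok_class <- c("sexual", "vegetative_control", "atlas")
  if (!all(sample_meta$condition_class %in% ok_class))
    stop("condition_class must be one of: ", paste(ok_class, collapse = ", "))
  ok_stage <- c("S", "P", "GZ", "A", "none")
  if (!all(sample_meta$stage %in% ok_stage))
    stop("stage must be one of: ", paste(ok_stage, collapse = ", "))
  sexual <- sample_meta$condition_class == "sexual"
  if (any(sexual & sample_meta$stage == "none") ||
      any(!sexual & sample_meta$stage != "none"))
    stop("stage must be set exactly for sexual samples (none otherwise)")
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths)) ||
        !all(rownames(counts) %in% names(gene_lengths)))
      stop("gene_lengths must be named and cover all genes")
    gene_lengths <- gene_lengths[rownames(counts)]
    if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  }
  structure(list(counts = counts, samples = sample_meta,
                 gene_lengths = gene_lengths),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$species, x$samples$condition_class)
  print(tab)
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' Subset an expression matrix by samples
#'
#' @param x an `expr_matrix`.
#' @param samples character vector of sample ids, or a logical/integer index
#'   into the columns.
#' @return an `expr_matrix` restricted to those samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.character(samples)) samples <- match(samples, colnames(x$counts))
  expression_matrix(x$counts[, samples, drop = FALSE],
                    x$samples[samples, , drop = FALSE],
                    x$gene_lengths)
}

#' Read an expression matrix from TSV files
#'
#' The counts file has a header row, gene ids in the first column and one
#' column per sample. The metadata file has columns sample_id, species,
#' condition_class, stage, condition_label, replicate.
#'
#' @param counts_file,meta_file paths to the two TSV files.
#' @param lengths_file optional TSV with columns gene_id, length.
#' @return an `expr_matrix`.
#' @export
read_expression_tsv <- function(counts_file, meta_file, lengths_file = NULL) {
  cnt <- utils::read.delim(counts_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  mat <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(mat) <- cnt[[1]]
  meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
  lens <- NULL
  if (!is.null(lengths_file)) {
    lt <- utils::read.delim(lengths_file, stringsAsFactors = FALSE)
    lens <- stats::setNames(lt$length, lt$gene_id)
  }
  expression_matrix(mat, meta, lens)
}

#' Write an expression matrix to TSV files
#'
#' @param x an `expr_matrix`.
#' @param counts_file,meta_file output paths.
#' @export
write_expression_tsv <- function(x, counts_file, meta_file) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, meta_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
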