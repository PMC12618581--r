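#' Read externally produced DE records
#'
#' Drop-in ingestion for per-gene per-stage DE summaries produced by an
#' external engine (e.g. a negative-binomial GLM fit): a TSV with columns
#' gene_id, species, stage, log2fc, se, p_raw. The result feeds
#' [stagewise_adjust()] and everything downstream exactly like the built-in
#' test.
#'
#' @param path TSV path.
#' @return data.frame of DE records.
#' @export
read_de_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "species", "stage", "log2fc", "se", "p_raw")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("DE record table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(d$p_raw < 0 | d$p_raw > 1)) stop("p_raw must lie in [0, 1]")
  if (any(d$se <= 0)) stop("se must be positive")
  d
}

#' Write a result table as TSV
#'
#' Plain tab-separated serialization for any of the pipeline's tabular
#' results (DE records, stage-wise tables, candidate rankings, threshold
#' tables, event calls, summaries).
#'
#' @param x a data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read a MAG metatranscriptome dataset from TSV files
#'
#' @param expr_file TSV: mag_id, sample_id, gene_id, count, length.
#' @param mags_file TSV: mag_id, clade, genus.
#' @param samples_file TSV: sample_id, station, depth, size_fraction and
#'   optionally season.
#' @return a `mag_dataset`.
#' @export
read_mag_tsv <- function(expr_file, mags_file, samples_file) {
  mag_dataset(utils::read.delim(expr_file, stringsAsFactors = FALSE),
              utils::read.delim(mags_file, stringsAsFactors = FALSE),
              utils::read.delim(samples_file, stringsAsFactors = FALSE))
}
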