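#' Read and write tab-separated pipeline tables
#'
#' All tabular interchange in the pipeline uses plain TSV with a header row.
#' Methylation matrices are stored with a leading `bin_id` column
#' (`chrom:start-end`, 0-based half-open) and one column per sample visit.
#'
#' @param path file path.
#' @param x object to write.
#' @return `read_methylation()` returns a numeric matrix with bin ids as row
#'   names and sample-visit ids as column names; `read_samples()` /
#'   `read_table_tsv()` return data frames.
#' @name twinmeth-io
NULL

#' @rdname twinmeth-io
#' @export
write_methylation <- function(x, path) {
  stopifnot(is.matrix(x))
  df <- data.frame(bin_id = rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname twinmeth-io
#' @export
read_methylation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' @rdname twinmeth-io
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname twinmeth-io
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @rdname twinmeth-io
#' @export
write_samples <- function(x, path) write_table_tsv(x, path)

#' @rdname twinmeth-io
#' @export
read_samples <- function(path) read_table_tsv(path)

#' Read a BED annotation track
#'
#' Reads labelled genomic intervals from BED (0-based half-open). UCSC text
#' dumps occasionally use 1-based inclusive coordinates; set
#' `dialect = "one_based"` to convert on read.
#'
#' @param path BED file path (3+ columns: chrom, start, end, optional name).
#' @param dialect `"bed"` (default, 0-based half-open) or `"one_based"`
#'   (1-based inclusive, converted to BED on read).
#' @return data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path, dialect = c("bed", "one_based")) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  names(df)[1:3] <- c("chrom", "start", "end")
  df$name <- if (ncol(df) >= 4) as.character(df[[4]]) else "."
  if (dialect == "one_based") {
    df$start <- df$start - 1L
  }
  if (any(df$start >= df$end)) stop("BED intervals must satisfy start < end")
  df[order(df$chrom, df$start), c("chrom", "start", "end", "name")]
}

#' Write intervals as BED
#'
#' @param df data frame with `chrom`, `start`, `end` and optionally `name`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  out <- df[, c("chrom", "start", "end")]
  if (!is.null(df$name)) out$name <- df$name
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
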