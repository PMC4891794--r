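#' Build the overlapping genomic bin grid
#'
#' Tiles each chromosome with 500-bp bins on a 250-bp step (so interior
#' positions are covered by exactly two bins). The terminal bin is truncated
#' at the chromosome end rather than dropped, giving full genome coverage.
#' Coordinates are 0-based half-open throughout.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param width,step bin width and step in bp.
#' @return data frame of class `bin_grid` with columns `chrom`, `start`,
#'   `end`, `bin_id`, sorted by chromosome then start.
#' @examples
#' make_bin_grid(c(chr1 = 1000))
#' @export
make_bin_grid <- function(chrom_lengths, width = 500L, step = 250L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("`chrom_lengths` must be a named vector")
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (width <= 0 || step <= 0) stop("`width` and `step` must be positive")
  out <- lapply(names(chrom_lengths), function(chrom) {
    len <- as.integer(chrom_lengths[[chrom]])
    starts <- seq.int(0L, len - 1L, by = step)
    ends <- pmin(starts + as.integer(width), len)
    data.frame(chrom = chrom, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, out)
  grid <- grid[order(grid$chrom, grid$start), , drop = FALSE]
  grid$bin_id <- bin_id(grid$chrom, grid$start, grid$end)
  rownames(grid) <- NULL
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' Extend mapped reads to the average MeDIP fragment size
#'
#' Single-end reads only tag the fragment 5' end; each read is extended to
#' the average immunoprecipitated fragment length (350 bp) in its strand
#' direction before bin counting. Plus-strand reads become
#' `[start, start + extension)`; minus-strand reads become
#' `[start + read_length - extension, start + read_length)`. Intervals are
#' clipped at position 0 and, when `chrom_lengths` is supplied, at the
#' chromosome end.
#'
#' @param reads data frame with columns `chrom`, `start` (0-based), `strand`
#'   (`"+"`/`"-"`), and optionally `read_length` (default 50).
#' @param extension fragment extension length in bp (must be positive).
#' @param read_length default read length used when the table lacks a
#'   `read_length` column.
#' @param chrom_lengths optional named vector for right-clipping.
#' @return data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open extended fragments).
#' @export
extend_reads <- function(reads, extension = 350L, read_length = 50L,
                         chrom_lengths = NULL) {
  if (extension <= 0) stop("`extension` must be positive")
  stopifnot(all(c("chrom", "start", "strand") %in% names(reads)))
  if (any(reads$start < 0)) stop("read starts must be >= 0")
  if (!all(reads$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  rl <- reads$read_length %||% rep_len(as.integer(read_length), nrow(reads))
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$start, reads$start + rl - extension)
  end <- ifelse(plus, reads$start + extension, reads$start + rl)
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[reads$chrom]
    if (any(is.na(lim))) stop("reads on chromosomes absent from `chrom_lengths`")
    end <- pmin(end, lim)
  }
  data.frame(chrom = reads$chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' Quantify normalized methylation signal per bin for one sample
#'
#' Counts extended reads overlapping each bin by at least 1 bp (a fragment
#' spanning k bins contributes to all k) and normalizes by library size:
#' `value = count / (total_uniquely_mapped / 1e6)`, i.e. reads per bin per
#' million uniquely mapped reads.
#'
#' @param reads read-position table (see [extend_reads()]); raw reads are
#'   extended internally unless `already_extended = TRUE`.
#' @param grid a [make_bin_grid()] result.
#' @param total_uniquely_mapped library size used for normalization (> 0).
#' @param extension,read_length passed to [extend_reads()].
#' @param already_extended set `TRUE` if `reads` already holds fragment
#'   intervals (`chrom`, `start`, `end`).
#' @return numeric vector of normalized signal, one element per grid bin,
#'   named by `bin_id`.
#' @export
quantify_sample <- function(reads, grid, total_uniquely_mapped,
                            extension = 350L, read_length = 50L,
                            already_extended = FALSE) {
  stopifnot(inherits(grid, "bin_grid") || all(c("chrom", "start", "end") %in% names(grid)))
  if (length(total_uniquely_mapped) != 1L || total_uniquely_mapped <= 0) {
    stop("`total_uniquely_mapped` must be a positive count")
  }
  frags <- if (already_extended) reads else {
    extend_reads(reads, extension = extension, read_length = read_length)
  }
  counts <- if (nrow(frags) == 0L) {
    integer(nrow(grid))
  } else {
    GenomicRanges::countOverlaps(
      intervals_to_granges(grid),
      intervals_to_granges(frags),
      minoverlap = 1L
    )
  }
  stats::setNames(counts / (total_uniquely_mapped / 1e6), grid$bin_id)
}

#' Quantify several samples into a methylation matrix
#'
#' @param read_sets named list of read tables, one per sample.
#' @param grid bin grid.
#' @param totals named numeric vector of uniquely mapped read totals; when
#'   missing, each sample's read count is used.
#' @inheritParams quantify_sample
#' @return methylation matrix (bins x samples).
#' @export
quantify_samples <- function(read_sets, grid, totals = NULL,
                             extension = 350L, read_length = 50L) {
  stopifnot(is.list(read_sets), !is.null(names(read_sets)))
  cols <- vapply(names(read_sets), function(s) {
    tot <- if (!is.null(totals)) totals[[s]] else nrow(read_sets[[s]])
    quantify_sample(read_sets[[s]], grid, tot,
                    extension = extension, read_length = read_length)
  }, numeric(nrow(grid)))
  m <- matrix(cols, nrow = nrow(grid),
              dimnames = list(grid$bin_id, names(read_sets)))
  m
}

#' Read a tab-separated read-position table
#'
#' Expected columns: `chrom`, `start` (0-based), `strand`, and optionally
#' `read_length`.
#'
#' @param path TSV path.
#' @return data frame of reads.
#' @export
read_reads <- function(path) {
  df <- read_table_tsv(path)
  stopifnot(all(c("chrom", "start", "strand") %in% names(df)))
  df
}
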