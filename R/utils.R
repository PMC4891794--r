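`%||%` <- function(a, b) if (is.null(a)) b else a

#' Row-wise Pearson correlation
#'
#' Computes, for each row, the Pearson correlation between the corresponding
#' rows of two matrices of equal dimension. Used for per-bin screening
#' statistics where one correlation per genomic bin is needed and a loop over
#' `cor()` would be prohibitive.
#'
#' @param x,y numeric matrices, bins in rows, paired observations in columns.
#' @return numeric vector of correlations; `NA` where either row has zero
#'   variance (degenerate, flagged downstream).
#' @keywords internal
row_pearson <- function(x, y) {
  stopifnot(identical(dim(x), dim(y)))
  mx <- rowMeans(x)
  my <- rowMeans(y)
  xc <- x - mx
  yc <- y - my
  sxy <- rowSums(xc * yc)
  sxx <- rowSums(xc * xc)
  syy <- rowSums(yc * yc)
  denom <- sqrt(sxx * syy)
  r <- ifelse(sxx <= 0 | syy <= 0, NA_real_, sxy / denom)
  pmin(pmax(r, -1), 1)
}

# Row-wise double-entry Pearson: each column pair contributes both orderings,
# making the estimate invariant to which twin is labelled first. This is the
# standard order-invariant intraclass estimator for twin data.
row_pearson_double_entry <- function(x, y) {
  stopifnot(identical(dim(x), dim(y)))
  n <- ncol(x)
  m <- (rowSums(x) + rowSums(y)) / (2 * n)
  xc <- x - m
  yc <- y - m
  sxy <- rowSums(xc * yc)
  sxx <- rowSums(xc * xc)
  syy <- rowSums(yc * yc)
  r <- ifelse(sxx + syy <= 0, NA_real_, 2 * sxy / (sxx + syy))
  pmin(pmax(r, -1), 1)
}

# Two-sided p value for a Pearson correlation via the exact t transform with
# n - 2 degrees of freedom.
pearson_p <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n > 2
  t <- r[ok] * sqrt((n - 2) / pmax(1 - r[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(-abs(t), df = n - 2)
  p
}

bin_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

parse_bin_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)-([0-9]+)$", id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed bin id(s): ", paste(utils::head(id[bad]), collapse = ", "))
  data.frame(
    bin_id = id,
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

# BED-style 0-based half-open intervals -> GRanges (1-based closed).
intervals_to_granges <- function(df, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  if (!is.null(seqlengths)) {
    GenomicRanges::seqlengths(gr) <- seqlengths[GenomicRanges::seqlevels(gr)]
  }
  gr
}

granges_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

check_proportion <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop("invalid configuration: `", field, "` must be a proportion in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, field, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop("invalid configuration: `", field, "` must be an integer >= ", min)
  }
  invisible(as.integer(x))
}
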