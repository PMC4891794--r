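#' Construct CpG-island shores
#'
#' Shores are the 2-kb regions immediately up- and downstream of each CpG
#' island boundary, clipped at position 0 (and at the chromosome end when
#' lengths are given), with island territory subtracted so that island bases
#' are never shore - including where one island's shore would overlap a
#' neighbouring island.
#'
#' @param cgi_track CpG-island intervals: data frame `chrom`, `start`,
#'   `end` (BED, 0-based half-open).
#' @param chrom_lengths optional named vector for right-clipping.
#' @param flank shore width in bp (default 2000).
#' @return data frame of shore intervals (`chrom`, `start`, `end`, `name`),
#'   merged and sorted.
#' @export
build_shores <- function(cgi_track, chrom_lengths = NULL, flank = 2000L) {
  if (nrow(cgi_track) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stringsAsFactors = FALSE))
  }
  islands <- GenomicRanges::reduce(intervals_to_granges(cgi_track))
  up <- GenomicRanges::flank(islands, flank, start = TRUE)
  down <- GenomicRanges::flank(islands, flank, start = FALSE)
  shores <- GenomicRanges::reduce(c(up, down))
  shores <- GenomicRanges::setdiff(shores, islands)
  # clip at chromosome bounds
  GenomicRanges::start(shores) <- pmax(GenomicRanges::start(shores), 1L)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[as.character(GenomicRanges::seqnames(shores))]
    GenomicRanges::end(shores) <- pmin(GenomicRanges::end(shores), lim)
  }
  shores <- shores[GenomicRanges::width(shores) > 0]
  out <- granges_to_intervals(shores)
  out$name <- "shore"
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Classify bins by CpG context and chromatin state
#'
#' Assigns every bin exactly one CpG class (`island` > `shore` > `open_sea`
#' by >= 1 bp overlap precedence) and one chromatin-state class
#' (`promoter` > `enhancer` > `other`). Promoter states are the active,
#' weak and poised promoter ChromHMM states; enhancer states are strong and
#' weak enhancers; all remaining states fall in `other`. State intervals are
#' matched by their `name` column against `promoter_pattern` /
#' `enhancer_pattern`.
#'
#' @param grid bin grid (or any data frame with `chrom`, `start`, `end`,
#'   `bin_id`).
#' @param cgi_track CpG-island intervals.
#' @param chromatin_track ChromHMM-style intervals with state names in
#'   `name`.
#' @param shores optional precomputed shore track (defaults to
#'   [build_shores()] of `cgi_track`).
#' @param promoter_pattern,enhancer_pattern regular expressions matched
#'   case-insensitively against state names.
#' @return data frame: `bin_id`, `cpg_class`, `state_class`.
#' @export
classify_bins <- function(grid, cgi_track, chromatin_track,
                          shores = NULL,
                          promoter_pattern = "promoter",
                          enhancer_pattern = "enhancer") {
  track_chroms <- unique(c(cgi_track$chrom, chromatin_track$chrom))
  unmatched <- setdiff(unique(grid$chrom), track_chroms)
  if (length(unmatched)) {
    stop("grid chromosomes absent from the annotation tracks: ",
         paste(unmatched, collapse = ", "))
  }
  bins_gr <- intervals_to_granges(grid)
  overlaps_any <- function(track) {
    if (is.null(track) || nrow(track) == 0L) return(rep(FALSE, nrow(grid)))
    GenomicRanges::countOverlaps(bins_gr, intervals_to_granges(track),
                                 minoverlap = 1L) > 0
  }
  if (is.null(shores)) shores <- build_shores(cgi_track)
  in_island <- overlaps_any(cgi_track)
  in_shore <- overlaps_any(shores)
  cpg_class <- ifelse(in_island, "island", ifelse(in_shore, "shore", "open_sea"))

  is_prom <- grepl(promoter_pattern, chromatin_track$name, ignore.case = TRUE)
  is_enh <- grepl(enhancer_pattern, chromatin_track$name, ignore.case = TRUE)
  in_prom <- overlaps_any(chromatin_track[is_prom, , drop = FALSE])
  in_enh <- overlaps_any(chromatin_track[is_enh, , drop = FALSE])
  state_class <- ifelse(in_prom, "promoter", ifelse(in_enh, "enhancer", "other"))

  data.frame(bin_id = grid$bin_id, cpg_class = cpg_class,
             state_class = state_class, stringsAsFactors = FALSE)
}

#' Class-proportion enrichment of lsBINs
#'
#' Compares, per annotation class, the proportion of lsBINs falling in the
#' class against the proportion among all bins (two-proportion Z test), plus
#' an overall chi-square test of the class distribution between the two
#' sets.
#'
#' @param classification per-bin classification from [classify_bins()].
#' @param lsbins lsBIN id set (must be a subset of the classified bins).
#' @param class_col which classification axis to use (`"cpg_class"` or
#'   `"state_class"`).
#' @return list with `per_class` (class, counts, proportions, `z`, `p_z`)
#'   and `chisq` (statistic, df, p).
#' @export
proportion_enrichment <- function(classification, lsbins,
                                  class_col = c("cpg_class", "state_class")) {
  class_col <- match.arg(class_col)
  if (nrow(classification) == 0L || length(lsbins) == 0L) {
    stop("empty classification or lsBIN set")
  }
  if (!all(lsbins %in% classification$bin_id)) {
    stop("lsBIN set contains unclassified bins")
  }
  cls <- classification[[class_col]]
  levels_ <- sort(unique(cls))
  is_ls <- classification$bin_id %in% lsbins
  n_all <- length(cls)
  n_ls <- sum(is_ls)
  per_class <- do.call(rbind, lapply(levels_, function(lv) {
    x_all <- sum(cls == lv)
    x_ls <- sum(cls[is_ls] == lv)
    p_all <- x_all / n_all
    p_ls <- x_ls / n_ls
    pool <- (x_all + x_ls) / (n_all + n_ls)
    se <- sqrt(pool * (1 - pool) * (1 / n_all + 1 / n_ls))
    z <- if (se > 0) (p_ls - p_all) / se else 0
    data.frame(class = lv, n_total = x_all, prop_total = p_all,
               n_lsbin = x_ls, prop_lsbin = p_ls,
               z = z, p_z = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  }))
  counts <- rbind(lsbin = table(factor(cls[is_ls], levels = levels_)),
                  total = table(factor(cls, levels = levels_)))
  chisq <- suppressWarnings(stats::chisq.test(counts))
  list(per_class = per_class,
       chisq = list(statistic = unname(chisq$statistic),
                    df = unname(chisq$parameter),
                    p_value = chisq$p.value))
}

#' Stability by annotation class
#'
#' Per-class mean and standard error of a per-bin statistic (longitudinal
#' stability by default, optionally the MZ twin correlation), with Welch t
#' tests for every pair of classes. Classes with fewer than 3 bins are
#' skipped with a warning.
#'
#' @param stability per-bin table containing `bin_id` and the statistic.
#' @param classification per-bin classification.
#' @param stat name of the statistic column (default `"r_repeated"`).
#' @param class_col classification axis.
#' @return list with `summary` (class, n, mean, sem) and `pairwise` (Welch t
#'   and p per class pair).
#' @export
stability_by_region <- function(stability, classification,
                                stat = "r_repeated",
                                class_col = c("cpg_class", "state_class")) {
  class_col <- match.arg(class_col)
  m <- merge(stability, classification, by = "bin_id")
  m <- m[is.finite(m[[stat]]), , drop = FALSE]
  groups <- split(m[[stat]], m[[class_col]])
  small <- names(groups)[vapply(groups, length, 1L) < 3L]
  if (length(small)) {
    warning("skipping classes with fewer than 3 bins: ",
            paste(small, collapse = ", "))
    groups <- groups[setdiff(names(groups), small)]
  }
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(class = g, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)), stringsAsFactors = FALSE)
  }))
  combos <- if (length(groups) >= 2) utils::combn(names(groups), 2) else
    base::matrix(character(), 2, 0)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    tt <- stats::t.test(groups[[a]], groups[[b]])
    data.frame(class_1 = a, class_2 = b, t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairwise)) {
    pairwise <- data.frame(class_1 = character(), class_2 = character(),
                           t = numeric(), df = numeric(), p_value = numeric(),
                           stringsAsFactors = FALSE)
  }
  list(summary = summary, pairwise = pairwise)
}

#' Stability-threshold trend table
#'
#' For an ascending series of stability thresholds (the first row meaning
#' "no filtering"), counts the bins with `R_repeated` above each threshold
#' and the percentage of those falling in each annotation class, and
#' summarizes the trend per class by the Spearman rank correlation between
#' threshold rank and percentage. Degenerate (constant) percentage series
#' get `rho = 0`, `p = 1`.
#'
#' @param stability per-bin stability table (`bin_id`, `r_repeated`).
#' @param classification per-bin classification.
#' @param thresholds ascending numeric thresholds; use `-Inf` for the
#'   unfiltered row (default `c(-Inf, 0.11, 0.2, ..., 0.7)`).
#' @param class_cols classification axes to tabulate.
#' @return list with `table` (one row per threshold: `n_bins`, and per class
#'   `n_<class>` / `pct_<class>`) and `trend` (class, Spearman `rho`, `p`).
#' @export
threshold_trend <- function(stability, classification,
                            thresholds = c(-Inf, 0.11, 0.2, 0.3, 0.4, 0.5,
                                           0.6, 0.7),
                            class_cols = c("cpg_class", "state_class")) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be strictly ascending")
  }
  m <- merge(stability, classification, by = "bin_id")
  classes <- unlist(lapply(class_cols, function(cc) sort(unique(m[[cc]]))))
  rows <- lapply(thresholds, function(thr) {
    sel <- if (is.infinite(thr) && thr < 0) rep(TRUE, nrow(m)) else
      is.finite(m$r_repeated) & m$r_repeated > thr
    n <- sum(sel)
    row <- data.frame(threshold = thr, n_bins = n)
    for (cc in class_cols) {
      for (lv in sort(unique(m[[cc]]))) {
        cnt <- sum(m[[cc]][sel] == lv)
        row[[paste0("n_", lv)]] <- cnt
        row[[paste0("pct_", lv)]] <- if (n > 0) 100 * cnt / n else NA_real_
      }
    }
    row
  })
  tab <- do.call(rbind, rows)
  trend <- do.call(rbind, lapply(classes, function(lv) {
    pct <- tab[[paste0("pct_", lv)]]
    ok <- is.finite(pct)
    if (sum(ok) < 3L || stats::sd(pct[ok]) == 0) {
      return(data.frame(class = lv, rho = 0, p_value = 1,
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(seq_along(pct)[ok], pct[ok], method = "spearman"))
    data.frame(class = lv, rho = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  list(table = tab, trend = trend)
}
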