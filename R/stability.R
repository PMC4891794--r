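#' Exclude bins with excess zero methylation
#'
#' A bin is retained iff the fraction of individuals whose value is exactly
#' zero is at most `max_zero_frac` (the exact boundary is retained;
#' strictly-greater fractions are excluded). With repeat visits, each
#' individual is represented by their first visit.
#'
#' @param matrix methylation matrix (bins x sample visits).
#' @param individuals character vector mapping columns to individual ids;
#'   defaults to treating every column as a distinct individual.
#' @param max_zero_frac maximum tolerated zero fraction (default 0.20).
#' @return character vector of retained bin ids.
#' @export
zero_filter <- function(matrix, individuals = colnames(matrix),
                        max_zero_frac = 0.20) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0L || ncol(matrix) == 0L) {
    stop("`matrix` must be a nonempty methylation matrix")
  }
  individuals <- individuals %||% as.character(seq_len(ncol(matrix)))
  first_col <- !duplicated(individuals)
  sub <- matrix[, first_col, drop = FALSE]
  zero_frac <- rowMeans(sub == 0)
  rownames(matrix)[zero_frac <= max_zero_frac]
}

#' Build sequential visit pairings for stability screening
#'
#' Pairs consecutive visits within each individual (visits sorted by age at
#' visit), requiring the two measurements to come from the same processing
#' batch and to be at least `min_years_gap` years apart. Individuals with
#' four or more eligible visits contribute each disjoint consecutive pair
#' (visits 1-2, 3-4, ...), so a pair of measurements is the unit of analysis.
#'
#' @param samples sample table (see [simulate_cohort()]).
#' @param min_years_gap minimum years between paired visits (default 3).
#' @param same_batch require the paired visits to share a batch.
#' @return data frame with columns `individual_id`, `sample_1`, `sample_2`,
#'   `batch`, `years_apart`.
#' @export
make_visit_pairings <- function(samples, min_years_gap = 3, same_batch = TRUE) {
  out <- lapply(split(samples, samples$individual_id), function(s) {
    s <- s[order(s$age), , drop = FALSE]
    pairs <- list()
    i <- 1L
    while (i < nrow(s)) {
      gap <- s$age[i + 1L] - s$age[i]
      ok <- gap >= min_years_gap && (!same_batch || s$batch[i] == s$batch[i + 1L])
      if (ok) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          individual_id = s$individual_id[1L],
          sample_1 = s$sample_id[i], sample_2 = s$sample_id[i + 1L],
          batch = s$batch[i], years_apart = gap, stringsAsFactors = FALSE)
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
    if (length(pairs)) do.call(rbind, pairs) else NULL
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(individual_id = character(), sample_1 = character(),
                      sample_2 = character(), batch = character(),
                      years_apart = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Per-bin longitudinal stability
#'
#' For each bin, the Pearson correlation (`R_repeated`) across visit
#' pairings between the earlier and later measurement, with a two-sided p
#' value from the exact t transform with `n - 2` degrees of freedom. Bins
#' with zero variance in either vector have undefined correlation and are
#' flagged (`defined = FALSE`); they are excluded from lsBIN selection and
#' summaries.
#'
#' @param matrix methylation matrix.
#' @param pairings visit pairings from [make_visit_pairings()].
#' @param bins optional bin id subset (default all rows).
#' @return data frame: `bin_id`, `r_repeated`, `p_value`, `n_pairs`,
#'   `defined`.
#' @export
longitudinal_stability <- function(matrix, pairings, bins = rownames(matrix)) {
  if (nrow(pairings) < 3L) stop("need at least 3 visit pairings")
  miss <- setdiff(c(pairings$sample_1, pairings$sample_2), colnames(matrix))
  if (length(miss)) stop("pairing samples absent from matrix: ",
                         paste(utils::head(miss), collapse = ", "))
  x <- matrix[bins, pairings$sample_1, drop = FALSE]
  y <- matrix[bins, pairings$sample_2, drop = FALSE]
  r <- row_pearson(x, y)
  n <- nrow(pairings)
  data.frame(bin_id = bins, r_repeated = r, p_value = pearson_p(r, n),
             n_pairs = n, defined = !is.na(r), stringsAsFactors = FALSE)
}

#' Select longitudinally stable bins (lsBINs)
#'
#' A bin qualifies iff its stability correlation is positive and nominally
#' significant: `p < alpha` and `R_repeated > 0`. Undefined bins never
#' qualify.
#'
#' @param stability output of [longitudinal_stability()].
#' @param alpha nominal significance level (default 0.05).
#' @return character vector of lsBIN ids.
#' @export
select_lsbins <- function(stability, alpha = 0.05) {
  ok <- stability$defined & !is.na(stability$p_value) &
    stability$p_value < alpha & stability$r_repeated > 0
  stability$bin_id[ok]
}

#' Build co-twin measurement pairs
#'
#' Pairs co-twin measurements taken at the same visit (same measurement
#' date) and processing batch, separately for MZ and DZ families. Families
#' with repeat visits contribute one measurement pair per visit.
#'
#' @param samples sample table.
#' @return data frame: `family_id`, `zygosity`, `visit`, `sample_1`,
#'   `sample_2`.
#' @export
make_twin_pairs <- function(samples) {
  tw <- samples[samples$zygosity %in% c("MZ", "DZ"), , drop = FALSE]
  out <- lapply(split(tw, list(tw$family_id, tw$visit), drop = TRUE), function(s) {
    if (nrow(s) != 2L || length(unique(s$batch)) != 1L) return(NULL)
    s <- s[order(s$twin), , drop = FALSE]
    data.frame(family_id = s$family_id[1L], zygosity = s$zygosity[1L],
               visit = s$visit[1L], sample_1 = s$sample_id[1L],
               sample_2 = s$sample_id[2L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(family_id = character(), zygosity = character(),
                      visit = integer(), sample_1 = character(),
                      sample_2 = character(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$zygosity, out$family_id, out$visit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-bin intrapair twin correlations
#'
#' Computes, for every bin, the correlation between co-twin methylation
#' values for MZ and DZ pairs. The default estimator is double-entry Pearson
#' (each pair contributes both orderings), which is invariant to co-twin
#' labelling; plain single-ordering Pearson is available via
#' `method = "single"`.
#'
#' @param matrix methylation matrix.
#' @param twin_pairs pairs from [make_twin_pairs()].
#' @param bins optional bin subset.
#' @param method `"double_entry"` (default) or `"single"`.
#' @return data frame: `bin_id`, `r_mz`, `r_dz`, `n_mz_pairs`, `n_dz_pairs`.
#' @export
twin_pair_correlation <- function(matrix, twin_pairs, bins = rownames(matrix),
                                  method = c("double_entry", "single")) {
  method <- match.arg(method)
  res <- data.frame(bin_id = bins, stringsAsFactors = FALSE)
  for (z in c("MZ", "DZ")) {
    p <- twin_pairs[twin_pairs$zygosity == z, , drop = FALSE]
    if (nrow(p) == 0L) {
      res[[if (z == "MZ") "r_mz" else "r_dz"]] <- NA_real_
      res[[if (z == "MZ") "n_mz_pairs" else "n_dz_pairs"]] <- 0L
      next
    }
    if (nrow(p) < 3L) stop("need at least 3 ", z, " pairs")
    x <- matrix[bins, p$sample_1, drop = FALSE]
    y <- matrix[bins, p$sample_2, drop = FALSE]
    r <- if (method == "double_entry") {
      row_pearson_double_entry(x, y)
    } else {
      row_pearson(x, y)
    }
    res[[if (z == "MZ") "r_mz" else "r_dz"]] <- r
    res[[if (z == "MZ") "n_mz_pairs" else "n_dz_pairs"]] <- nrow(p)
  }
  res
}

#' Stability / twin-correlation meta-summary
#'
#' Per chromosome and genome-wide, summarizes how bin-level twin
#' correlations track longitudinal stability: `correl_1 = cor(R_repeated,
#' R_MZ)`, `correl_2 = cor(R_repeated, R_DZ)`, `correl_3 = cor(R_MZ, R_DZ)`,
#' together with bin counts (`n_ini` from the full grid when supplied,
#' `n_filtered` bins summarized, `n_sign` with `p < alpha`, `n_posit`
#' additionally requiring `R_repeated > 0`) and extreme values. The ratio
#' analysis correlates `R_MZ / R_DZ` with `R_repeated` over bins whose DZ
#' correlation is positive and nominally significant.
#'
#' @param stability per-bin stability table.
#' @param twincorr per-bin twin correlation table.
#' @param n_ini optional named vector of initial bin counts per chromosome.
#' @param alpha significance level used for the count columns and the ratio
#'   bin filter.
#' @return list with `per_chromosome` (data frame, one row per chromosome
#'   plus `ALL`) and `ratio_series` (per-bin ratio table used for the trend).
#' @export
stability_twin_summary <- function(stability, twincorr, n_ini = NULL,
                                   alpha = 0.05) {
  common <- merge(stability[stability$defined, , drop = FALSE], twincorr,
                  by = "bin_id")
  if (nrow(common) < 3L) stop("need at least 3 bins common to both tables")
  common <- cbind(common, parse_bin_id(common$bin_id)[, c("chrom"), drop = FALSE])
  dz_p <- pearson_p(common$r_dz, common$n_dz_pairs)
  ratio_ok <- !is.na(common$r_dz) & common$r_dz > 0 & !is.na(dz_p) & dz_p < alpha
  ratio_series <- data.frame(bin_id = common$bin_id[ratio_ok],
                             r_repeated = common$r_repeated[ratio_ok],
                             ratio_mz_dz = common$r_mz[ratio_ok] / common$r_dz[ratio_ok],
                             stringsAsFactors = FALSE)
  summarize <- function(d, label) {
    data.frame(
      chrom = label,
      n_ini = if (!is.null(n_ini)) {
        if (label == "ALL") sum(n_ini) else unname(n_ini[label])
      } else NA_integer_,
      n_filtered = nrow(d),
      n_sign = sum(d$p_value < alpha, na.rm = TRUE),
      n_posit = sum(d$p_value < alpha & d$r_repeated > 0, na.rm = TRUE),
      max_r_repeated = max(d$r_repeated),
      min_r_repeated = min(d$r_repeated),
      correl_1 = if (nrow(d) >= 3) stats::cor(d$r_repeated, d$r_mz) else NA_real_,
      correl_2 = if (nrow(d) >= 3) stats::cor(d$r_repeated, d$r_dz) else NA_real_,
      correl_3 = if (nrow(d) >= 3) stats::cor(d$r_mz, d$r_dz) else NA_real_,
      max_r_mz = max(d$r_mz, na.rm = TRUE),
      max_r_dz = max(d$r_dz, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }
  per_chrom <- do.call(rbind, lapply(split(common, common$chrom),
                                     function(d) summarize(d, d$chrom[1L])))
  per_chrom <- rbind(per_chrom, summarize(common, "ALL"))
  rownames(per_chrom) <- NULL
  list(per_chromosome = per_chrom, ratio_series = ratio_series)
}
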