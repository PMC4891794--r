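#' Relative SMM discordance between co-twins
#'
#' `(smm_1 - smm_2) / (0.5 * (smm_1 + smm_2))`: the within-pair difference
#' relative to the pair mean. Antisymmetric under swapping the twins and
#' invariant to rescaling both values by a positive constant.
#'
#' @param smm_1,smm_2 co-twin trait values (kg); vectors recycle.
#' @return signed relative difference.
#' @export
discordance_score <- function(smm_1, smm_2) {
  mean_ <- 0.5 * (smm_1 + smm_2)
  if (any(mean_ <= 0)) stop("pair mean SMM must be positive")
  (smm_1 - smm_2) / mean_
}

#' Tabulate MZ pair discordance
#'
#' Builds one row per complete MZ pair with both twins' SMM and the signed
#' discordance score, restricted to pairs whose trait assessment and
#' methylation measurement are at most `max_gap_months` apart.
#'
#' @param samples sample table (one row per visit; SMM constant within
#'   individual).
#' @param max_gap_months eligibility window between DXA and methylation
#'   assessment, months; the `assessment_gap_months` column is used when
#'   present, otherwise the gap is taken as 0.
#' @return data frame: `family_id`, `twin_1`, `twin_2`, `sample_1`,
#'   `sample_2`, `smm_1`, `smm_2`, `d_smm`.
#' @export
make_discordance_table <- function(samples, max_gap_months = 12) {
  mz <- samples[samples$zygosity == "MZ" & samples$visit == 1, , drop = FALSE]
  gap <- mz$assessment_gap_months %||% rep(0, nrow(mz))
  mz <- mz[gap <= max_gap_months, , drop = FALSE]
  out <- lapply(split(mz, mz$family_id), function(s) {
    if (nrow(s) != 2L) return(NULL)
    s <- s[order(s$twin), , drop = FALSE]
    data.frame(family_id = s$family_id[1L],
               twin_1 = s$individual_id[1L], twin_2 = s$individual_id[2L],
               sample_1 = s$sample_id[1L], sample_2 = s$sample_id[2L],
               smm_1 = s$smm[1L], smm_2 = s$smm[2L],
               d_smm = discordance_score(s$smm[1L], s$smm[2L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) stop("no complete MZ pairs within the assessment window")
  rownames(out) <- NULL
  out
}

#' Select the most SMM-discordant MZ pairs
#'
#' Ranks pairs by absolute discordance and returns the top `k`. Ties at the
#' k-th rank are broken deterministically by family id order. Within each
#' selected pair the twin orientation is fixed so the discordance is
#' positive (higher-SMM twin first), making downstream within-pair
#' methylation differences interpretable.
#'
#' @param pairs discordance table from [make_discordance_table()].
#' @param k number of pairs to select (default 50).
#' @return the selected rows, reoriented, with `d_smm > 0`, ordered by
#'   decreasing `|d_smm|`.
#' @export
select_discordant_pairs <- function(pairs, k = 50L) {
  if (nrow(pairs) < k) {
    stop("need ", k, " eligible MZ pairs but only ", nrow(pairs),
         " available (shortfall ", k - nrow(pairs), ")")
  }
  ord <- order(-abs(pairs$d_smm), pairs$family_id)
  sel <- pairs[ord[seq_len(k)], , drop = FALSE]
  flip <- sel$d_smm < 0
  if (any(flip)) {
    sel[flip, c("twin_1", "twin_2")] <- sel[flip, c("twin_2", "twin_1")]
    sel[flip, c("sample_1", "sample_2")] <- sel[flip, c("sample_2", "sample_1")]
    sel[flip, c("smm_1", "smm_2")] <- sel[flip, c("smm_2", "smm_1")]
    sel$d_smm[flip] <- -sel$d_smm[flip]
  }
  rownames(sel) <- NULL
  sel
}

#' Paired t test per bin across discordant MZ pairs
#'
#' For each bin, within-pair methylation differences
#' `d_i = M_twin1 - M_twin2` (twin 1 = higher-SMM twin) are tested against
#' zero: `t = mean(d) / (sd(d) / sqrt(n))`, two-sided p with `n - 1` df.
#' Bins with zero difference variance are flagged undefined.
#'
#' @param matrix methylation matrix.
#' @param selected_pairs oriented pairs from [select_discordant_pairs()].
#' @param bins bin ids to test (typically the lsBIN set).
#' @return data frame: `bin_id`, `mean_dmtl`, `t_statistic`, `p_value`,
#'   `n_pairs`, `defined`.
#' @export
paired_t_per_bin <- function(matrix, selected_pairs, bins = rownames(matrix)) {
  if (nrow(selected_pairs) < 2L) stop("need at least 2 pairs")
  d <- matrix[bins, selected_pairs$sample_1, drop = FALSE] -
    matrix[bins, selected_pairs$sample_2, drop = FALSE]
  n <- ncol(d)
  md <- rowMeans(d)
  sdd <- sqrt(rowSums((d - md)^2) / (n - 1))
  t <- ifelse(sdd > 0, md / (sdd / sqrt(n)), NA_real_)
  p <- ifelse(is.na(t), NA_real_, 2 * stats::pt(-abs(t), df = n - 1))
  data.frame(bin_id = bins, mean_dmtl = md, t_statistic = t, p_value = p,
             n_pairs = n, defined = !is.na(t), stringsAsFactors = FALSE)
}

#' Filter discovery hits into replication candidates
#'
#' Retains bins with discovery `p < p_thresh` and stability
#' `R_repeated > r_thresh`, ordered by discovery p ascending. No
#' multiple-testing correction is applied at this stage; error control is
#' deferred to replication.
#'
#' @param discovery per-bin results from [paired_t_per_bin()].
#' @param stability per-bin stability table.
#' @param p_thresh discovery p threshold (default 0.01).
#' @param r_thresh stability threshold (default 0.4).
#' @return data frame of candidate bins (discovery columns plus
#'   `r_repeated`), ordered by `p_value`.
#' @export
candidate_filter <- function(discovery, stability, p_thresh = 0.01,
                             r_thresh = 0.4) {
  m <- merge(discovery, stability[, c("bin_id", "r_repeated")], by = "bin_id")
  keep <- m$defined & !is.na(m$p_value) & m$p_value < p_thresh &
    !is.na(m$r_repeated) & m$r_repeated > r_thresh
  out <- m[keep, , drop = FALSE]
  out <- out[order(out$p_value, out$bin_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
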