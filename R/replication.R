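#' Unadjusted correlation of candidate-bin methylation with SMM
#'
#' Pearson correlation, per candidate bin, between methylation (one value
#' per individual: the first eligible visit) and SMM, with two-sided p from
#' the t transform.
#'
#' @param matrix methylation matrix.
#' @param samples sample table restricted to the replication individuals.
#' @param bins candidate bin ids.
#' @return data frame: `bin_id`, `r`, `p_r`, `n_corr`, `defined`.
#' @export
correlate_smm <- function(matrix, samples, bins) {
  if (length(bins) == 0L) stop("no candidate bins supplied")
  first <- samples[!duplicated(samples$individual_id), , drop = FALSE]
  x <- matrix[bins, first$sample_id, drop = FALSE]
  smm <- first$smm
  n <- length(smm)
  y <- base::matrix(smm, nrow = length(bins), ncol = n, byrow = TRUE)
  r <- row_pearson(x, y)
  data.frame(bin_id = bins, r = r, p_r = pearson_p(r, n), n_corr = n,
             defined = !is.na(r), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up over a fixed family of m tests
#'
#' Applies the BH step-up procedure at level `q` to a candidate p-value list
#' that may be shorter than the full family size `m` (untested candidates
#' are conservatively assigned p = 1): the largest `k` with
#' `p_(k) <= k * q / m` is found and all tests at rank `<= k` are declared
#' significant. The output is always a prefix of the p-sorted list.
#'
#' @param p_values numeric p values in (0, 1].
#' @param m total number of tests in the family (defaults to
#'   `length(p_values)`; must be at least that).
#' @param q FDR level in (0, 1), default 0.1.
#' @return integer indices into `p_values` declared significant.
#' @examples
#' bh_fdr(c(0.0003, 0.0004, 0.0015, 0.0015, 0.0025, 0.0032, 0.0037), m = 134)
#' @export
bh_fdr <- function(p_values, m = length(p_values), q = 0.1) {
  if (q <= 0 || q >= 1) stop("`q` must lie in (0, 1)")
  if (m < length(p_values)) stop("`m` must be at least length(p_values)")
  if (length(p_values) == 0L) return(integer())
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p values must lie in (0, 1]")
  }
  ord <- order(p_values)
  ps <- p_values[ord]
  k <- which(ps <= seq_along(ps) * q / m)
  if (length(k) == 0L) return(integer())
  sort(ord[seq_len(max(k))])
}

#' Covariate-adjusted replication regression per bin
#'
#' Ordinary least squares of z-scored SMM on z-scored methylation, age and
#' smoking score, over complete cases, giving standardized coefficients with
#' two-sided t-based p values per covariate.
#'
#' @param matrix methylation matrix.
#' @param samples replication sample table (first visit per individual is
#'   used); smoking may contain `NA` (those individuals drop out).
#' @param bins candidate bin ids.
#' @param smoking_coding `"score"` uses the numeric smoking column as is
#'   (e.g. never = 0 / ex = 1 / current = 2); `"ever"` dichotomizes at > 0.
#' @return data frame: `bin_id`, `beta_mtl`, `p_mtl`, `beta_age`, `p_age`,
#'   `beta_psmk`, `p_psmk`, `n_regress`.
#' @export
regression_model <- function(matrix, samples, bins,
                             smoking_coding = c("score", "ever")) {
  smoking_coding <- match.arg(smoking_coding)
  first <- samples[!duplicated(samples$individual_id), , drop = FALSE]
  smk <- first$smoking
  if (smoking_coding == "ever") smk <- as.integer(smk > 0)
  cc <- stats::complete.cases(first$smm, first$age, smk)
  first <- first[cc, , drop = FALSE]
  smk <- smk[cc]
  zs <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("collinear design: constant column among covariates")
    (v - mean(v)) / s
  }
  smm_z <- zs(first$smm)
  age_z <- zs(first$age)
  smk_z <- zs(smk)
  out <- lapply(bins, function(b) {
    mtl <- matrix[b, first$sample_id]
    if (stats::sd(mtl) == 0) {
      return(data.frame(bin_id = b, beta_mtl = NA_real_, p_mtl = NA_real_,
                        beta_age = NA_real_, p_age = NA_real_,
                        beta_psmk = NA_real_, p_psmk = NA_real_,
                        n_regress = nrow(first), stringsAsFactors = FALSE))
    }
    X <- cbind(mtl = zs(mtl), age = age_z, psmk = smk_z)
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1L) {
      bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X) + 1L)] - 1L]
      stop("collinear design: ", paste(bad, collapse = ", "))
    }
    fit <- stats::lm(smm_z ~ X)
    sm <- summary(fit)$coefficients
    data.frame(bin_id = b,
               beta_mtl = sm["Xmtl", 1], p_mtl = sm["Xmtl", 4],
               beta_age = sm["Xage", 1], p_age = sm["Xage", 4],
               beta_psmk = sm["Xpsmk", 1], p_psmk = sm["Xpsmk", 4],
               n_regress = nrow(first), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Replicate candidate bins in an independent sample
#'
#' Convenience wrapper combining the unadjusted correlation screen, BH FDR
#' over the full candidate family, and the covariate-adjusted regression,
#' producing a table shaped like a replication summary (one row per
#' candidate bin).
#'
#' @inheritParams correlate_smm
#' @param m total test-family size for BH (defaults to `length(bins)`).
#' @param q FDR level.
#' @param smoking_coding see [regression_model()].
#' @return data frame with correlation, regression and `bh_significant`
#'   columns, ordered by `p_r`.
#' @export
replicate_candidates <- function(matrix, samples, bins, m = length(bins),
                                 q = 0.1, smoking_coding = "score") {
  corr <- correlate_smm(matrix, samples, bins)
  sig <- bh_fdr(corr$p_r, m = m, q = q)
  corr$bh_significant <- seq_len(nrow(corr)) %in% sig
  reg <- regression_model(matrix, samples, bins, smoking_coding = smoking_coding)
  out <- merge(corr, reg, by = "bin_id", sort = FALSE)
  out <- out[order(out$p_r), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Blood-cell composition check at hit bins
#'
#' Correlates methylation at each replicated bin with the proportions of the
#' available white-blood-cell subtypes; a bin is flagged as potentially
#' cell-composition confounded iff any cell type reaches `p < alpha`.
#'
#' @param matrix methylation matrix.
#' @param samples sample table containing cell-proportion columns.
#' @param bins hit bin ids.
#' @param cell_types columns to test (default the FACS panel
#'   neutrophils/eosinophils/monocytes/lymphocytes; pass a panel including
#'   basophils if available).
#' @param alpha nominal level for the flag.
#' @return data frame, one row per bin x cell type (`r`, `p`), plus a
#'   per-bin `confounded` flag in the `summary` attribute; also returned as
#'   list element for convenience.
#' @export
wbc_check <- function(matrix, samples, bins,
                      cell_types = c("neutrophils", "eosinophils",
                                     "monocytes", "lymphocytes"),
                      alpha = 0.05) {
  first <- samples[!duplicated(samples$individual_id), , drop = FALSE]
  missing_ct <- setdiff(cell_types, names(first))
  if (length(missing_ct)) stop("cell types absent from samples: ",
                               paste(missing_ct, collapse = ", "))
  if (nrow(first) < 4L) stop("WBC subset too small")
  rows <- list()
  for (b in bins) {
    mtl <- matrix[b, first$sample_id]
    for (ct in cell_types) {
      ct_vals <- first[[ct]]
      if (stats::sd(mtl) == 0 || stats::sd(ct_vals) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        htest <- stats::cor.test(mtl, ct_vals)
        r <- unname(htest$estimate); p <- htest$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(bin_id = b, cell_type = ct,
                                              r = r, p = p,
                                              stringsAsFactors = FALSE)
    }
  }
  detail <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(detail, detail$bin_id), function(d) {
    data.frame(bin_id = d$bin_id[1L],
               confounded = any(!is.na(d$p) & d$p < alpha),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(detail = detail, summary = summary)
}
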