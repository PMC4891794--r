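#' Simulate a twin cohort with binned methylation and an SMM phenotype
#'
#' Generates a complete synthetic dataset with the statistical structure the
#' downstream analysis assumes. For each bin `b` and individual `j` a stable
#' biological methylation level is drawn as
#' `B_jb = mu_b + sigma_b * (sqrt(a2)*A + sqrt(c2)*C + sqrt(e2_stable)*U)`,
#' where the additive-genetic factor `A` is shared identically by MZ co-twins
#' and with correlation 0.5 by DZ co-twins (`A2 = 0.5*A1 + sqrt(0.75)*A'`),
#' the common-environment factor `C` is shared within a family, and `U` is
#' individual. Each visit observes `B_jb` plus fresh visit noise scaled by
#' `sqrt(e2_visit)`; with probability `zero_inflation_rate` an observation is
#' replaced by exact zero (independently per observation). SMM combines a
#' standardized age effect, the genetic (or stable-environmental, per
#' `assoc_route`) components of the associated bins, a polygenic background,
#' and a unique residual, scaled so the additive-genetic fraction of
#' age-adjusted SMM variance equals `smm_h2`.
#'
#' @param config a [cohort_config()].
#' @return an object of class `twin_cohort`: a list with elements
#'   \describe{
#'     \item{samples}{data frame, one row per sample visit: `sample_id`,
#'       `individual_id`, `family_id`, `zygosity` (MZ/DZ/SG), `twin`,
#'       `visit`, `age`, `batch`, `smm` (kg), `smoking` (0 = never,
#'       1 = ever), and FACS-style blood-cell proportions `neutrophils`,
#'       `eosinophils`, `monocytes`, `lymphocytes`.}
#'     \item{methylation}{numeric matrix, bins x sample visits, nonnegative
#'       normalized signal (reads per bin per million mapped reads scale).}
#'     \item{truth}{ground-truth record: `associated_bins`, signed
#'       `assoc_effects`, `per_bin_vc`, `smm_h2`, `assoc_route`.}
#'     \item{grid}{the bin grid (see [make_bin_grid()]) on the synthetic
#'       chromosome `chrS`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_mz_pairs = 5, n_dz_pairs = 3,
#'                                         n_bins = 50, seed = 7))
#' dim(cohort$methylation)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_mz <- cfg$n_mz_pairs
  n_dz <- cfg$n_dz_pairs
  n_sg <- cfg$n_singletons
  n_fam <- n_mz + n_dz + n_sg
  n_ind <- 2L * n_mz + 2L * n_dz + n_sg
  n_bins <- cfg$n_bins
  n_vis <- cfg$n_visits_per_individual

  grid <- if (n_bins > 0) {
    make_bin_grid(c(chrS = 250L * n_bins))
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               bin_id = character(), stringsAsFactors = FALSE)
  }

  # Family / individual bookkeeping. Twins within a family share an age;
  # processing batch is assigned per family so co-twin and repeat-visit
  # measurements satisfy the same-batch pairing rules.
  zyg_fam <- rep(c("MZ", "DZ", "SG"), times = c(n_mz, n_dz, n_sg))
  fam_id <- sprintf("F%04d", seq_len(n_fam))
  members <- ifelse(zyg_fam == "SG", 1L, 2L)
  ind_fam_idx <- rep(seq_len(n_fam), times = members)
  twin_no <- unlist(lapply(members, seq_len), use.names = FALSE)
  ind_id <- sprintf("%s_T%d", fam_id[ind_fam_idx], twin_no)
  zyg_ind <- zyg_fam[ind_fam_idx]

  if (n_ind == 0L || n_bins == 0L) {
    return(empty_cohort(cfg, grid))
  }

  age_fam <- stats::runif(n_fam, cfg$age_range[1], cfg$age_range[2])
  batch_fam <- sprintf("B%d", 1L + (seq_len(n_fam) - 1L) %% 4L)
  smoking <- stats::rbinom(n_ind, 1L, cfg$smoking_prevalence)

  # Blood-cell proportions: Dirichlet-like draw around typical adult
  # differential counts; independent of methylation (no confounding truth).
  wbc_shape <- c(neutrophils = 55, eosinophils = 3, monocytes = 7, lymphocytes = 33)
  g <- matrix(stats::rgamma(n_ind * 4L, shape = rep(wbc_shape, each = n_ind)),
              nrow = n_ind)
  wbc <- 0.98 * g / rowSums(g)
  colnames(wbc) <- names(wbc_shape)

  vc <- resolve_bin_vc(cfg$bin_vc_model, n_bins)
  mu_b <- stats::runif(n_bins, 5, 50)
  sigma_b <- 0.15 * mu_b

  # Latent standardized components, bins x individuals.
  A_fam <- matrix(stats::rnorm(n_bins * n_fam), n_bins, n_fam)
  C_fam <- matrix(stats::rnorm(n_bins * n_fam), n_bins, n_fam)
  A_ind <- A_fam[, ind_fam_idx, drop = FALSE]
  dz2 <- which(zyg_ind == "DZ" & twin_no == 2L)
  if (length(dz2)) {
    A_ind[, dz2] <- 0.5 * A_ind[, dz2] +
      sqrt(0.75) * matrix(stats::rnorm(n_bins * length(dz2)), n_bins)
  }
  C_ind <- C_fam[, ind_fam_idx, drop = FALSE]
  U_ind <- matrix(stats::rnorm(n_bins * n_ind), n_bins, n_ind)

  stable_std <- sqrt(vc[, "a2"]) * A_ind + sqrt(vc[, "c2"]) * C_ind +
    sqrt(vc[, "e2_stable"]) * U_ind

  # SMM: age effect plus age-adjusted residual of unit variance split into
  # additive-genetic and unique-environment parts.
  n_assoc <- round(cfg$frac_associated_bins * n_bins)
  assoc_idx <- if (n_assoc > 0) sort(sample.int(n_bins, n_assoc)) else integer()
  gamma <- if (n_assoc > 0) {
    cfg$assoc_effect * rep_len(c(1, -1), n_assoc)
  } else {
    numeric()
  }
  comp <- if (cfg$assoc_route == "genetic") A_ind else U_ind
  g_assoc <- if (n_assoc > 0) {
    as.vector(crossprod(comp[assoc_idx, , drop = FALSE], gamma))
  } else {
    rep(0, n_ind)
  }
  var_assoc <- sum(gamma^2)

  A_bg_fam <- stats::rnorm(n_fam)
  A_bg <- A_bg_fam[ind_fam_idx]
  if (length(dz2)) {
    A_bg[dz2] <- 0.5 * A_bg[dz2] + sqrt(0.75) * stats::rnorm(length(dz2))
  }
  E_res <- stats::rnorm(n_ind)

  h2 <- cfg$smm_h2
  if (cfg$assoc_route == "genetic") {
    genetic <- g_assoc + sqrt(max(h2 - var_assoc, 0)) * A_bg
    environ <- sqrt(1 - h2) * E_res
  } else {
    genetic <- sqrt(h2) * A_bg
    environ <- g_assoc + sqrt(max(1 - h2 - var_assoc, 0)) * E_res
  }
  age_ind <- age_fam[ind_fam_idx]
  z_age <- if (stats::sd(age_ind) > 0) {
    (age_ind - mean(age_ind)) / stats::sd(age_ind)
  } else {
    rep(0, n_ind)
  }
  smm_std <- cfg$beta_age_smm * z_age +
    sqrt(1 - cfg$beta_age_smm^2) * (genetic + environ)
  smm <- cfg$smm_mean + cfg$smm_sd * smm_std

  # Observed methylation per visit: stable level plus fresh visit noise,
  # zero-inflated per observation, clamped at zero (signal is nonnegative).
  zir <- rep_len(cfg$zero_inflation_rate, n_bins)
  cols <- vector("list", n_vis)
  for (v in seq_len(n_vis)) {
    eps <- matrix(stats::rnorm(n_bins * n_ind), n_bins, n_ind)
    m <- mu_b + sigma_b * (stable_std + sqrt(vc[, "e2_visit"]) * eps)
    if (any(zir > 0)) {
      drop <- matrix(stats::rbinom(n_bins * n_ind, 1L, zir), n_bins, n_ind)
      m[drop == 1L] <- 0
    }
    m[m < 0] <- 0
    colnames(m) <- sprintf("%s_v%d", ind_id, v)
    cols[[v]] <- m
  }
  meth <- do.call(cbind, cols)
  ord <- order(rep(seq_len(n_ind), n_vis), rep(seq_len(n_vis), each = n_ind))
  meth <- meth[, ord, drop = FALSE]
  rownames(meth) <- grid$bin_id

  samples <- data.frame(
    sample_id = colnames(meth),
    individual_id = rep(ind_id, each = n_vis),
    family_id = rep(fam_id[ind_fam_idx], each = n_vis),
    zygosity = rep(zyg_ind, each = n_vis),
    twin = rep(twin_no, each = n_vis),
    visit = rep(seq_len(n_vis), times = n_ind),
    age = rep(age_ind, each = n_vis) +
      (rep(seq_len(n_vis), times = n_ind) - 1L) * cfg$visit_gap_years,
    batch = rep(batch_fam[ind_fam_idx], each = n_vis),
    smm = rep(smm, each = n_vis),
    smoking = rep(smoking, each = n_vis),
    stringsAsFactors = FALSE
  )
  samples <- cbind(samples, wbc[rep(seq_len(n_ind), each = n_vis), , drop = FALSE])
  rownames(samples) <- NULL

  truth <- list(
    associated_bins = grid$bin_id[assoc_idx],
    assoc_effects = stats::setNames(gamma, grid$bin_id[assoc_idx]),
    per_bin_vc = data.frame(bin_id = grid$bin_id, vc, stringsAsFactors = FALSE),
    smm_h2 = h2,
    assoc_route = cfg$assoc_route
  )

  structure(list(samples = samples, methylation = meth, truth = truth,
                 grid = grid, config = cfg),
            class = "twin_cohort")
}

empty_cohort <- function(cfg, grid) {
  samples <- data.frame(
    sample_id = character(), individual_id = character(),
    family_id = character(), zygosity = character(), twin = integer(),
    visit = integer(), age = numeric(), batch = character(),
    smm = numeric(), smoking = integer(),
    neutrophils = numeric(), eosinophils = numeric(),
    monocytes = numeric(), lymphocytes = numeric(),
    stringsAsFactors = FALSE
  )
  meth <- matrix(numeric(), nrow = nrow(grid), ncol = 0,
                 dimnames = list(grid$bin_id, NULL))
  truth <- list(associated_bins = character(),
                assoc_effects = stats::setNames(numeric(), character()),
                per_bin_vc = data.frame(bin_id = character(),
                                        a2 = numeric(), c2 = numeric(),
                                        e2_stable = numeric(),
                                        e2_visit = numeric(),
                                        stringsAsFactors = FALSE),
                smm_h2 = cfg$smm_h2, assoc_route = cfg$assoc_route)
  structure(list(samples = samples, methylation = meth, truth = truth,
                 grid = grid, config = cfg),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("Synthetic twin cohort: %d bins x %d sample visits (%d individuals)\n",
              nrow(x$methylation), ncol(x$methylation),
              length(unique(x$samples$individual_id))))
  cat(sprintf("  %d truly associated bin(s); SMM h2 = %.3f (%s route)\n",
              length(x$truth$associated_bins), x$truth$smm_h2,
              x$truth$assoc_route))
  invisible(x)
}

#' Write a simulated cohort to a directory
#'
#' Writes `samples.tsv`, `methylation.tsv`, `grid.bed`, the ground-truth
#' sidecars `truth_bins.tsv` / `truth_vc.tsv`, and a machine-readable
#' configuration echo `config.yaml`.
#'
#' @param cohort a `twin_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "twin_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_samples(cohort$samples, file.path(dir, "samples.tsv"))
  write_methylation(cohort$methylation, file.path(dir, "methylation.tsv"))
  write_bed(data.frame(chrom = cohort$grid$chrom, start = cohort$grid$start,
                       end = cohort$grid$end, name = cohort$grid$bin_id),
            file.path(dir, "grid.bed"))
  tb <- data.frame(bin_id = cohort$truth$associated_bins,
                   effect = as.numeric(cohort$truth$assoc_effects),
                   stringsAsFactors = FALSE)
  write_table_tsv(tb, file.path(dir, "truth_bins.tsv"))
  write_table_tsv(cohort$truth$per_bin_vc, file.path(dir, "truth_vc.tsv"))
  cfg <- cohort$config
  cfg_out <- cfg[setdiff(names(cfg), "bin_vc_model")]
  cfg_out$bin_vc_model <- if (is.character(cfg$bin_vc_model)) {
    cfg$bin_vc_model
  } else {
    "custom"
  }
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Simulate twin pair traits from the biometrical AE model
#'
#' Lightweight trait-level generator (no methylome) used for parameter
#' recovery of the variance-decomposition estimators: draws one or two traits
#' per twin under the classical AE model, with MZ co-twins sharing the
#' additive-genetic factor entirely and DZ co-twins with correlation 0.5.
#' When a second trait is requested, its genetic and unique-environment
#' factors are correlated with the first trait's at `r_g` and `r_e`,
#' producing the standard bivariate twin covariance structure.
#'
#' @param n_mz_pairs,n_dz_pairs pair counts.
#' @param h2_x heritability of trait `x`.
#' @param h2_y heritability of trait `y`, or `NULL` for univariate output.
#' @param r_g,r_e genetic and environmental correlations between `x` and `y`.
#' @param seed integer seed.
#' @return data frame with `family_id`, `zygosity`, `twin`, `x` and
#'   optionally `y` (standardized scale).
#' @export
simulate_twin_traits <- function(n_mz_pairs, n_dz_pairs, h2_x,
                                 h2_y = NULL, r_g = 0, r_e = 0, seed = 1L) {
  check_proportion(h2_x, "h2_x")
  if (!is.null(h2_y)) check_proportion(h2_y, "h2_y")
  if (abs(r_g) > 1 || abs(r_e) > 1) stop("`r_g` and `r_e` must lie in [-1, 1]")
  withr::with_seed(seed, {
    n_fam <- n_mz_pairs + n_dz_pairs
    zyg <- rep(c("MZ", "DZ"), times = c(n_mz_pairs, n_dz_pairs))
    fam <- sprintf("F%04d", seq_len(n_fam))
    twin_structured <- function() {
      g_fam <- stats::rnorm(n_fam)
      g <- cbind(g_fam, g_fam)
      dz <- zyg == "DZ"
      g[dz, 2] <- 0.5 * g[dz, 2] + sqrt(0.75) * stats::rnorm(sum(dz))
      g
    }
    gx <- twin_structured()
    ex <- matrix(stats::rnorm(2 * n_fam), n_fam, 2)
    x <- sqrt(h2_x) * gx + sqrt(1 - h2_x) * ex
    out <- data.frame(
      family_id = rep(fam, each = 2),
      zygosity = rep(zyg, each = 2),
      twin = rep(1:2, times = n_fam),
      x = as.vector(t(x)),
      stringsAsFactors = FALSE
    )
    if (!is.null(h2_y)) {
      gy <- r_g * gx + sqrt(1 - r_g^2) * twin_structured()
      ey <- r_e * ex + sqrt(1 - r_e^2) * matrix(stats::rnorm(2 * n_fam), n_fam, 2)
      y <- sqrt(h2_y) * gy + sqrt(1 - h2_y) * ey
      out$y <- as.vector(t(y))
    }
    out
  })
}

#' Synthetic CpG-island and chromatin-state tracks
#'
#' Generates annotation tracks on the same synthetic chromosome as a
#' simulated cohort's bin grid so the annotation-enrichment stage can run
#' without external UCSC files: sparse CpG islands (about 1% of the
#' chromosome) and a ChromHMM-style segmentation alternating promoter,
#' enhancer and other states.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param seed integer seed.
#' @return list with elements `cgi` and `chromatin`, each a BED-style data
#'   frame (`chrom`, `start`, `end`, `name`).
#' @export
make_synthetic_tracks <- function(chrom_lengths, seed = 1L) {
  withr::with_seed(seed, {
    cgi <- list()
    chrom_states <- list()
    states <- c("Active_Promoter", "Weak_Promoter", "Poised_Promoter",
                "Strong_Enhancer", "Weak_Enhancer", "Txn_Elongation",
                "Weak_Txn", "Insulator", "Heterochrom_lo")
    state_w <- c(2, 2, 1, 3, 4, 10, 12, 3, 40)
    for (chrom in names(chrom_lengths)) {
      len <- chrom_lengths[[chrom]]
      n_cgi <- max(1L, round(0.01 * len / 1000))
      starts <- sort(sample.int(max(len - 2000L, 1L), n_cgi))
      widths <- sample(500:2000, n_cgi, replace = TRUE)
      ends <- pmin(starts + widths, len)
      keep <- c(TRUE, diff(starts) > 4000)[seq_len(n_cgi)]
      cgi[[chrom]] <- data.frame(chrom = chrom, start = starts[keep],
                                 end = ends[keep], name = "CpG_island",
                                 stringsAsFactors = FALSE)
      pos <- 0L
      seg <- list()
      while (pos < len) {
        w <- sample(500:5000, 1L)
        s <- sample(states, 1L, prob = state_w)
        seg[[length(seg) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = min(pos + w, len), name = s,
          stringsAsFactors = FALSE)
        pos <- pos + w
      }
      chrom_states[[chrom]] <- do.call(rbind, seg)
    }
    list(cgi = do.call(rbind, cgi), chromatin = do.call(rbind, chrom_states))
  })
}
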