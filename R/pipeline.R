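#' Pipeline configuration
#'
#' Assembles the configuration for an end-to-end run: the synthetic-cohort
#' block, the sample partition, and per-stage parameters. Defaults scale the
#' original three-subsample design (stability individuals with repeat
#' visits, 50 discordant MZ discovery pairs, the remainder as replication
#' individuals) down to desk size while keeping the proportions.
#'
#' @param cohort a [cohort_config()] (or list of its arguments).
#' @param n_stability_individuals target size of the stability subsample.
#' @param n_discovery_pairs number of discordant MZ pairs for discovery.
#' @param screen list: `alpha`, `max_zero_frac`, `min_years_gap`.
#' @param discover list: `p_thresh`, `r_thresh`, `max_gap_months`.
#' @param replicate list: `q`, `m` (`NULL` = number of candidates),
#'   `smoking_coding`.
#' @param heritability list: `model` (`"AE"` or `"ACE"`), `max_bivariate`
#'   (cap on per-bin bivariate fits).
#' @param annotate list: `thresholds` for the trend table, `tracks_seed`.
#' @param assignments optional explicit partition: list with
#'   `stability` (individual ids), `discovery_families` (family ids),
#'   `replication` (individual ids); validated for disjointness.
#' @param seed seed for partitioning (the cohort block carries its own).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(n_mz_pairs = 130,
                                                   n_dz_pairs = 70,
                                                   n_singletons = 20,
                                                   n_bins = 1500),
                            n_stability_individuals = 60L,
                            n_discovery_pairs = 50L,
                            screen = list(),
                            discover = list(),
                            replicate = list(),
                            heritability = list(),
                            annotate = list(),
                            assignments = NULL,
                            seed = 1L) {
  if (!inherits(cohort, "cohort_config")) cohort <- do.call(cohort_config, cohort)
  cfg <- list(
    cohort = cohort,
    n_stability_individuals = check_count(n_stability_individuals,
                                          "n_stability_individuals"),
    n_discovery_pairs = check_count(n_discovery_pairs, "n_discovery_pairs"),
    screen = utils::modifyList(
      list(alpha = 0.05, max_zero_frac = 0.20, min_years_gap = 3), screen),
    discover = utils::modifyList(
      list(p_thresh = 0.01, r_thresh = 0.4, max_gap_months = 12), discover),
    replicate = utils::modifyList(
      list(q = 0.1, m = NULL, smoking_coding = "score"), replicate),
    heritability = utils::modifyList(
      list(model = "AE", max_bivariate = 10L), heritability),
    annotate = utils::modifyList(
      list(thresholds = c(-Inf, 0.11, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7),
           tracks_seed = 99L), annotate),
    assignments = assignments,
    seed = check_count(seed, "seed")
  )
  structure(cfg, class = "pipeline_config")
}

partition_cohort <- function(cohort, config) {
  samples <- cohort$samples
  ind <- samples[!duplicated(samples$individual_id),
                 c("individual_id", "family_id", "zygosity")]
  if (!is.null(config$assignments)) {
    a <- config$assignments
    stab <- a$stability %||% character()
    disc_fam <- a$discovery_families %||% character()
    disc <- ind$individual_id[ind$family_id %in% disc_fam]
    repl <- a$replication %||% setdiff(ind$individual_id, c(stab, disc))
    overlap <- c(intersect(stab, disc), intersect(stab, repl),
                 intersect(disc, repl))
    if (length(overlap)) {
      stop("partition error: individual(s) assigned to more than one subsample: ",
           paste(unique(overlap), collapse = ", "))
    }
    return(list(stability = stab, discovery_families = disc_fam,
                replication = repl))
  }
  withr::with_seed(config$seed, {
    fams <- unique(ind$family_id)
    fams <- sample(fams)
    sizes <- table(ind$family_id)[fams]
    cum <- cumsum(as.integer(sizes))
    n_stab_fam <- which(cum >= config$n_stability_individuals)[1]
    if (is.na(n_stab_fam)) stop("not enough individuals for the stability subsample")
    stab_fams <- fams[seq_len(n_stab_fam)]
    stab <- ind$individual_id[ind$family_id %in% stab_fams]
    rest <- ind[!ind$family_id %in% stab_fams, , drop = FALSE]
    mz_fams <- unique(rest$family_id[rest$zygosity == "MZ"])
    mz_fams <- mz_fams[vapply(mz_fams, function(f)
      sum(rest$family_id == f) == 2L, TRUE)]
    smm1 <- samples[match(rest$individual_id, samples$individual_id), "smm"]
    names(smm1) <- rest$individual_id
    dsc <- vapply(mz_fams, function(f) {
      tw <- rest$individual_id[rest$family_id == f]
      abs(discordance_score(smm1[tw[1]], smm1[tw[2]]))
    }, numeric(1))
    if (length(mz_fams) < config$n_discovery_pairs) {
      stop("not enough MZ pairs outside the stability subsample for discovery")
    }
    disc_fams <- mz_fams[order(-dsc, mz_fams)][seq_len(config$n_discovery_pairs)]
    disc <- ind$individual_id[ind$family_id %in% disc_fams]
    repl <- setdiff(ind$individual_id, c(stab, disc))
    list(stability = stab, discovery_families = disc_fams, replication = repl)
  })
}

#' Run the full twin EWAS pipeline
#'
#' Executes simulate -> screen -> discover -> replicate -> heritability ->
#' annotate on three non-overlapping subsamples (stability, discovery,
#' replication); assigning an individual to more than one subsample is an
#' error. All tabular outputs are written as TSV (intervals as BED) under
#' `out_dir`, together with a JSON run manifest carrying parameter echoes,
#' per-stage wall-clock times and MD5 checksums of every output file.
#' Identical configuration (including seeds) reproduces identical checksums.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return the manifest, invisibly (class `run_manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(obj, name, writer = write_table_tsv) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files <<- c(files, path)
    path
  }

  cohort <- stage("simulate", simulate_cohort(config$cohort))
  emit(cohort$samples, "samples.tsv")
  emit(cohort$methylation, "methylation.tsv", write_methylation)
  part <- partition_cohort(cohort, config)
  disc_ind <- unique(cohort$samples$individual_id[
    cohort$samples$family_id %in% part$discovery_families])
  emit(data.frame(
    individual_id = c(part$stability, disc_ind, part$replication),
    subsample = rep(c("stability", "discovery", "replication"),
                    times = c(length(part$stability), length(disc_ind),
                              length(part$replication))),
    stringsAsFactors = FALSE
  ), "partition.tsv")

  samples <- cohort$samples
  meth <- cohort$methylation

  # --- stability screen ---
  scr <- config$screen
  stab_samples <- samples[samples$individual_id %in% part$stability, , drop = FALSE]
  screen_res <- stage("screen", {
    kept <- zero_filter(meth[, stab_samples$sample_id, drop = FALSE],
                        individuals = stab_samples$individual_id,
                        max_zero_frac = scr$max_zero_frac)
    pairings <- make_visit_pairings(stab_samples,
                                    min_years_gap = scr$min_years_gap)
    stability <- longitudinal_stability(meth, pairings, bins = kept)
    lsbins <- select_lsbins(stability, alpha = scr$alpha)
    twin_pairs <- make_twin_pairs(stab_samples)
    twincorr <- twin_pair_correlation(meth, twin_pairs, bins = kept)
    n_ini <- table(parse_bin_id(rownames(meth))$chrom)
    summary <- stability_twin_summary(stability, twincorr,
                                      n_ini = stats::setNames(
                                        as.integer(n_ini), names(n_ini)),
                                      alpha = scr$alpha)
    list(stability = stability, lsbins = lsbins, twincorr = twincorr,
         summary = summary)
  })
  emit(screen_res$stability, "stability.tsv")
  emit(screen_res$twincorr, "twin_correlations.tsv")
  emit(screen_res$summary$per_chromosome, "stability_summary.tsv")
  emit(data.frame(bin_id = screen_res$lsbins), "lsbins.tsv")

  # --- discordant-pair discovery ---
  dsc <- config$discover
  disc_samples <- samples[samples$family_id %in% part$discovery_families &
                            samples$visit == 1, , drop = FALSE]
  discovery_res <- stage("discover", {
    pairs <- make_discordance_table(disc_samples,
                                    max_gap_months = dsc$max_gap_months)
    sel <- select_discordant_pairs(pairs, k = config$n_discovery_pairs)
    disc <- paired_t_per_bin(meth, sel, bins = screen_res$lsbins)
    cand <- candidate_filter(disc, screen_res$stability,
                             p_thresh = dsc$p_thresh, r_thresh = dsc$r_thresh)
    list(pairs = sel, discovery = disc, candidates = cand)
  })
  emit(discovery_res$pairs, "discordant_pairs.tsv")
  emit(discovery_res$discovery, "discovery.tsv")
  emit(discovery_res$candidates, "candidates.tsv")

  # --- replication ---
  rep_cfg <- config$replicate
  repl_samples <- samples[samples$individual_id %in% part$replication &
                            samples$visit == 1, , drop = FALSE]
  replication_res <- stage("replicate", {
    cand_bins <- discovery_res$candidates$bin_id
    if (length(cand_bins) == 0L) {
      NULL
    } else {
      m_tests <- rep_cfg$m %||% length(cand_bins)
      replicate_candidates(meth, repl_samples, cand_bins, m = m_tests,
                           q = rep_cfg$q,
                           smoking_coding = rep_cfg$smoking_coding)
    }
  })
  if (!is.null(replication_res)) emit(replication_res, "replication.tsv")

  # --- heritability / bivariate ---
  her <- config$heritability
  heritability_res <- stage("heritability", {
    first <- repl_samples[!duplicated(repl_samples$individual_id), , drop = FALSE]
    first$smm_adj <- residualize(first$smm, first$age)
    tw <- data.frame(family_id = first$family_id, zygosity = first$zygosity,
                     x = first$smm_adj, stringsAsFactors = FALSE)
    smm_fit <- suppressWarnings(fit_univariate(tw, model = her$model))
    hits <- if (!is.null(replication_res)) {
      replication_res$bin_id[replication_res$bh_significant]
    } else character()
    hits <- utils::head(hits, her$max_bivariate)
    biv <- lapply(hits, function(b) {
      tw2 <- tw
      tw2$y <- as.numeric(meth[b, first$sample_id])
      fit <- suppressWarnings(fit_bivariate(tw2))
      data.frame(bin_id = b, h2_smm = smm_fit$h2, se_h2_smm = smm_fit$se_h2,
                 h2_bin = fit$a2_y, r_g = fit$r_g, r_e = fit$r_e,
                 p_rg = fit$lrt_rg$p_value, p_re = fit$lrt_re$p_value,
                 p_both = fit$lrt_both$p_value, stringsAsFactors = FALSE)
    })
    list(smm_fit = smm_fit,
         bivariate = if (length(biv)) do.call(rbind, biv) else NULL)
  })
  emit(data.frame(trait = "smm_age_adjusted",
                  model = her$model,
                  h2 = heritability_res$smm_fit$h2,
                  se_h2 = heritability_res$smm_fit$se_h2,
                  loglik = heritability_res$smm_fit$loglik),
       "heritability.tsv")
  if (!is.null(heritability_res$bivariate)) {
    emit(heritability_res$bivariate, "bivariate.tsv")
  }

  # --- annotation enrichment ---
  ann <- config$annotate
  annotate_res <- stage("annotate", {
    chrom_lengths <- vapply(split(cohort$grid$end, cohort$grid$chrom), max,
                            numeric(1))
    tracks <- make_synthetic_tracks(chrom_lengths, seed = ann$tracks_seed)
    cls <- classify_bins(cohort$grid, tracks$cgi, tracks$chromatin)
    enrich <- if (length(screen_res$lsbins) > 0) {
      proportion_enrichment(cls[cls$bin_id %in% screen_res$stability$bin_id, ],
                            screen_res$lsbins)
    } else NULL
    trend <- threshold_trend(screen_res$stability, cls,
                             thresholds = ann$thresholds)
    list(tracks = tracks, classification = cls, enrichment = enrich,
         trend = trend)
  })
  emit(annotate_res$tracks$cgi, "cgi.bed", write_bed)
  emit(annotate_res$tracks$chromatin, "chromatin.bed", write_bed)
  emit(annotate_res$classification, "classification.tsv")
  if (!is.null(annotate_res$enrichment)) {
    emit(annotate_res$enrichment$per_class, "enrichment.tsv")
  }
  emit(annotate_res$trend$table, "trend.tsv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("twinmeth")),
    seed = config$seed,
    cohort_seed = config$cohort$seed,
    parameters = list(
      screen = config$screen, discover = config$discover,
      replicate = config$replicate, heritability = config$heritability,
      n_stability_individuals = config$n_stability_individuals,
      n_discovery_pairs = config$n_discovery_pairs
    ),
    partition_sizes = list(stability = length(part$stability),
                           discovery_pairs = length(part$discovery_families),
                           replication = length(part$replication)),
    timings_sec = timings,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(structure(manifest, class = "run_manifest"))
}
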