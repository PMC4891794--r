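# Generator: configuration validation, determinism, and model-implied moments

test_that("invalid configurations fail with the offending field named", {
  expect_error(cohort_config(smm_h2 = 1.2), "smm_h2")
  expect_error(cohort_config(frac_associated_bins = -0.1), "frac_associated_bins")
  expect_error(cohort_config(visit_gap_years = 0), "visit_gap_years")
  expect_error(cohort_config(n_mz_pairs = 2.5), "n_mz_pairs")
  expect_error(cohort_config(n_bins = 100, frac_associated_bins = 0.5,
                             assoc_effect = 0.5), "assoc_effect")
  expect_error(
    simulate_cohort(cohort_config(n_bins = 10,
                                  bin_vc_model = c(0.5, 0.5, 0.5, 0.5))),
    "sum to 1")
})

test_that("an all-zero-count configuration yields empty tables and truth", {
  co <- simulate_cohort(cohort_config(n_mz_pairs = 0, n_dz_pairs = 0,
                                      n_singletons = 0, n_bins = 20))
  expect_equal(nrow(co$samples), 0L)
  expect_equal(ncol(co$methylation), 0L)
  expect_length(co$truth$associated_bins, 0L)
})

test_that("identical configurations reproduce byte-identical cohorts", {
  cfg <- cohort_config(n_mz_pairs = 8, n_dz_pairs = 5, n_singletons = 3,
                       n_bins = 40, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  c2 <- simulate_cohort(cohort_config(n_mz_pairs = 8, n_dz_pairs = 5,
                                      n_singletons = 3, n_bins = 40,
                                      seed = 43))
  expect_false(identical(a$methylation, c2$methylation))
})

test_that("zero visit noise makes repeat visits identical before zero-inflation", {
  co <- simulate_cohort(cohort_config(n_mz_pairs = 4, n_dz_pairs = 0,
                                      n_singletons = 2, n_bins = 30,
                                      n_visits_per_individual = 2,
                                      zero_inflation_rate = 0,
                                      bin_vc_model = c(0.4, 0.1, 0.5, 0),
                                      frac_associated_bins = 0, seed = 2))
  s <- co$samples
  for (ind in unique(s$individual_id)) {
    cols <- s$sample_id[s$individual_id == ind]
    expect_equal(co$methylation[, cols[1]], co$methylation[, cols[2]])
  }
})

test_that("co-twin and repeat-visit correlations match the generative expectations", {
  # observed visit value = stable + visit noise, unit total variance, so
  # cor(MZ co-twins) = a2 + c2, cor(DZ) = a2/2 + c2, and the within-person
  # visit correlation is a2 + c2 + e2_stable
  vc <- c(a2 = 0.8, c2 = 0, e2_stable = 0.1, e2_visit = 0.1)
  co <- simulate_cohort(cohort_config(n_mz_pairs = 500, n_dz_pairs = 500,
                                      n_singletons = 0, n_bins = 200,
                                      n_visits_per_individual = 2,
                                      zero_inflation_rate = 0,
                                      frac_associated_bins = 0,
                                      bin_vc_model = unname(vc), seed = 11))
  tp <- make_twin_pairs(co$samples)
  tp1 <- tp[tp$visit == 1, ]
  tc <- twin_pair_correlation(co$methylation, tp1)
  expect_lt(abs(mean(tc$r_mz) - 0.8), 0.03)
  expect_lt(abs(mean(tc$r_dz) - 0.4), 0.03)
  pr <- make_visit_pairings(co$samples)
  st <- longitudinal_stability(co$methylation, pr)
  expect_lt(abs(mean(st$r_repeated) - 0.9), 0.03)
})

test_that("zero-inflation hits observations independently at the configured rate", {
  rate <- 0.1
  co <- simulate_cohort(cohort_config(n_mz_pairs = 50, n_dz_pairs = 0,
                                      n_singletons = 0, n_bins = 200,
                                      n_visits_per_individual = 1,
                                      zero_inflation_rate = rate,
                                      frac_associated_bins = 0, seed = 9))
  frac0 <- mean(co$methylation == 0)
  expect_lt(abs(frac0 - rate), 0.01)
})

test_that("SMM has the configured mean, spread, and age dependence", {
  co <- simulate_cohort(cohort_config(n_mz_pairs = 400, n_dz_pairs = 200,
                                      n_singletons = 100, n_bins = 10,
                                      frac_associated_bins = 0, seed = 21))
  first <- co$samples[!duplicated(co$samples$individual_id), ]
  expect_lt(abs(mean(first$smm) - 39.9), 0.5)
  expect_lt(abs(sd(first$smm) - 5.4), 0.4)
  r_age <- cor(first$smm, first$age)
  expect_lt(abs(r_age - (-0.097)), 0.06)
  expect_lt(abs(mean(first$smoking) - 0.41), 0.05)
})

test_that("realized SMM heritability is recovered by the twin estimator", {
  co <- simulate_cohort(cohort_config(n_mz_pairs = 400, n_dz_pairs = 400,
                                      n_singletons = 0, n_bins = 10,
                                      frac_associated_bins = 0, seed = 31))
  first <- co$samples[!duplicated(co$samples$individual_id), ]
  tw <- data.frame(family_id = first$family_id, zygosity = first$zygosity,
                   x = residualize(first$smm, first$age))
  fit <- fit_univariate(tw)
  expect_true(fit$convergence)
  expect_lt(abs(fit$h2 - 0.809), 2 * fit$se_h2 + 1e-8)
})

test_that("the environmental association route creates r_E rather than r_G", {
  cfg <- cohort_config(n_mz_pairs = 300, n_dz_pairs = 300, n_singletons = 0,
                       n_bins = 50, frac_associated_bins = 0.04,
                       assoc_effect = 0.2, assoc_route = "environmental",
                       zero_inflation_rate = 0,
                       bin_vc_model = c(0.3, 0, 0.5, 0.2), seed = 41)
  co <- simulate_cohort(cfg)
  first <- co$samples[!duplicated(co$samples$individual_id), ]
  b <- co$truth$associated_bins[1]
  tw <- data.frame(family_id = first$family_id, zygosity = first$zygosity,
                   x = residualize(first$smm, first$age),
                   y = as.numeric(co$methylation[b, first$sample_id]))
  fit <- suppressWarnings(fit_bivariate(tw))
  expect_gt(abs(fit$r_e), abs(fit$r_g) - 0.05)
})

test_that("ground truth is consistent with the generated cohort", {
  cfg <- cohort_config(n_mz_pairs = 20, n_dz_pairs = 10, n_singletons = 5,
                       n_bins = 100, frac_associated_bins = 0.05,
                       assoc_effect = 0.1, seed = 8)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$associated_bins %in% rownames(co$methylation)))
  expect_equal(length(co$truth$associated_bins), 5L)
  expect_equal(nrow(co$truth$per_bin_vc), 100L)
  expect_true(all(abs(rowSums(co$truth$per_bin_vc[, -1]) - 1) < 1e-9))
  expect_equal(unname(abs(co$truth$assoc_effects)), rep(0.1, 5))
})
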