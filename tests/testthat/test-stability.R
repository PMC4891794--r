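# Zero filtering, longitudinal stability, lsBIN selection, twin correlations

make_matrix <- function(values, bins = paste0("chrS:", seq_len(nrow(values)),
                                              "-", seq_len(nrow(values)) + 500),
                        samples = paste0("S", seq_len(ncol(values)))) {
  dimnames(values) <- list(bins, samples)
  values
}

test_that("zero filter retains the exact boundary and excludes above it", {
  m <- make_matrix(rbind(
    c(rep(0, 3), rnorm(7) + 10),   # 30% zeros -> excluded
    c(rep(0, 2), rnorm(8) + 10),   # 20% zeros -> retained (boundary)
    rnorm(10) + 10,                # no zeros  -> retained
    rep(0, 10)                     # all zero  -> excluded
  ))
  kept <- zero_filter(m)
  expect_setequal(kept, rownames(m)[2:3])
  expect_error(zero_filter(m[0, , drop = FALSE]), "nonempty")
  all0 <- make_matrix(matrix(0, 3, 10))
  expect_length(zero_filter(all0), 0L)
})

test_that("zero filter is monotone in the threshold", {
  withr::with_seed(5, {
    m <- make_matrix(matrix(rbinom(50 * 20, 1, 0.7) * abs(rnorm(50 * 20)),
                            50, 20))
    prev <- character()
    for (thr in c(0, 0.1, 0.2, 0.5, 1)) {
      cur <- zero_filter(m, max_zero_frac = thr)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  })
})

test_that("stability correlations match hand-computed Pearson values", {
  m <- make_matrix(rbind(c(1, 2, 3, 4, 5, 1, 2, 3, 5, 4),
                         c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)),
                   samples = c(paste0("A", 1:5, "_v1"), paste0("A", 1:5, "_v2")))
  pr <- data.frame(individual_id = paste0("A", 1:5),
                   sample_1 = paste0("A", 1:5, "_v1"),
                   sample_2 = paste0("A", 1:5, "_v2"),
                   batch = "B1", years_apart = 5)
  st <- longitudinal_stability(m, pr)
  # oracle: slow_pearson((1,2,3,4,5), (1,2,3,5,4)) = 0.9
  expect_equal(st$r_repeated[1], slow_pearson(1:5, c(1, 2, 3, 5, 4)))
  expect_equal(st$r_repeated[1], 0.9)
  expect_equal(st$p_value[1], slow_pearson_p(0.9, 5), tolerance = 1e-12)
  # identical visits -> perfect stability
  expect_equal(st$r_repeated[2], 1)
  expect_error(longitudinal_stability(m, pr[1:2, ]), "at least 3")
})

test_that("degenerate bins are flagged and never become lsBINs", {
  m <- make_matrix(rbind(rep(7, 10), c(1:5, 5:1)),
                   samples = c(paste0("A", 1:5, "_v1"), paste0("A", 1:5, "_v2")))
  pr <- data.frame(individual_id = paste0("A", 1:5),
                   sample_1 = paste0("A", 1:5, "_v1"),
                   sample_2 = paste0("A", 1:5, "_v2"),
                   batch = "B1", years_apart = 5)
  st <- longitudinal_stability(m, pr)
  expect_false(st$defined[1])
  expect_false(rownames(m)[1] %in% select_lsbins(st, alpha = 1))
})

test_that("lsBIN selection requires positive and significant stability", {
  st <- data.frame(bin_id = c("a", "b", "c"),
                   r_repeated = c(0.5, -0.5, 0.1),
                   p_value = c(0.001, 0.001, 0.20),
                   n_pairs = 100, defined = TRUE)
  expect_equal(select_lsbins(st), "a")
  # weakly shrinking in alpha
  st2 <- data.frame(bin_id = letters[1:10], r_repeated = runif(10),
                    p_value = seq(0.005, 0.5, length.out = 10),
                    n_pairs = 50, defined = TRUE)
  prev <- select_lsbins(st2, alpha = 1)
  for (a in c(0.5, 0.1, 0.05, 0.01)) {
    cur <- select_lsbins(st2, alpha = a)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("visit pairings respect gap, batch, and disjoint sequential pairs", {
  s <- data.frame(
    sample_id = paste0("I1_v", 1:4),
    individual_id = "I1", family_id = "F1", zygosity = "SG", twin = 1,
    visit = 1:4, age = c(40, 47, 54, 61), batch = "B1",
    smm = 40, smoking = 0)
  pr <- make_visit_pairings(s)
  expect_equal(nrow(pr), 2L)           # (v1,v2) and (v3,v4), disjoint
  expect_equal(pr$sample_1, c("I1_v1", "I1_v3"))
  # batch mismatch breaks a pairing
  s2 <- s[1:2, ]; s2$batch <- c("B1", "B2")
  expect_equal(nrow(make_visit_pairings(s2)), 0L)
  # too-short gap is skipped
  s3 <- s[1:2, ]; s3$age <- c(40, 41)
  expect_equal(nrow(make_visit_pairings(s3)), 0L)
})

test_that("under the null the stability p values are uniform and lsBINs ~ alpha/2", {
  co <- simulate_cohort(cohort_config(
    n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 150, n_bins = 4000,
    n_visits_per_individual = 2, frac_associated_bins = 0,
    zero_inflation_rate = 0, bin_vc_model = c(0, 0, 0, 1), seed = 77))
  pr <- make_visit_pairings(co$samples)
  st <- longitudinal_stability(co$methylation, pr)
  expect_lt(abs(mean(st$p_value < 0.05) - 0.05), 0.015)
  ls <- select_lsbins(st, alpha = 0.05)
  frac <- length(ls) / nrow(st)
  se3 <- 3 * sqrt(0.025 * 0.975 / 4000)
  expect_lt(abs(frac - 0.025), se3 + 0.005)
})

test_that("double-entry twin correlation is invariant to co-twin labelling", {
  withr::with_seed(13, {
    n <- 30
    m <- make_matrix(matrix(rnorm(20 * 2 * n), 20, 2 * n),
                     samples = c(paste0("T1_", 1:n), paste0("T2_", 1:n)))
    pairs <- data.frame(family_id = paste0("F", 1:n), zygosity = "MZ",
                        visit = 1, sample_1 = paste0("T1_", 1:n),
                        sample_2 = paste0("T2_", 1:n))
    dz_pad <- data.frame(family_id = paste0("G", 1:3), zygosity = "DZ",
                         visit = 1, sample_1 = paste0("T1_", 1:3),
                         sample_2 = paste0("T2_", 1:3))
    tc1 <- twin_pair_correlation(m, rbind(pairs, dz_pad))
    flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
    pairs2 <- pairs
    pairs2[flip, c("sample_1", "sample_2")] <- pairs[flip, c("sample_2", "sample_1")]
    tc2 <- twin_pair_correlation(m, rbind(pairs2, dz_pad))
    expect_equal(tc1$r_mz, tc2$r_mz, tolerance = 1e-12)
    # double-entry matches the brute-force double-entry oracle
    x <- unname(m[1, pairs$sample_1]); y <- unname(m[1, pairs$sample_2])
    expect_equal(tc1$r_mz[1], slow_icc_double_entry(x, y), tolerance = 1e-12)
    # single-ordering option matches plain Pearson
    tcS <- twin_pair_correlation(m, rbind(pairs, dz_pad), method = "single")
    expect_equal(tcS$r_mz[1], slow_pearson(x, y), tolerance = 1e-12)
  })
})

test_that("summary reproduces trivial identities and errors on tiny input", {
  withr::with_seed(3, {
    bins <- sprintf("chr1:%d-%d", 0:19 * 250, 0:19 * 250 + 500)
    st <- data.frame(bin_id = bins, r_repeated = runif(20, 0.1, 0.9),
                     p_value = runif(20, 0, 0.04), n_pairs = 100,
                     defined = TRUE)
    tc <- data.frame(bin_id = bins, r_mz = st$r_repeated,
                     r_dz = runif(20, 0.2, 0.6),
                     n_mz_pairs = 100, n_dz_pairs = 60)
    sm <- stability_twin_summary(st, tc)
    all_row <- sm$per_chromosome[sm$per_chromosome$chrom == "ALL", ]
    expect_equal(all_row$correl_1, 1)           # R_MZ identical to R_repeated
    expect_equal(all_row$n_filtered, 20L)
    expect_equal(all_row$n_posit, sum(st$p_value < 0.05 & st$r_repeated > 0))
    expect_error(stability_twin_summary(st[1:2, ], tc[1:2, ]), "at least 3")
    # ratio series restricted to positive, significant R_DZ
    expect_true(all(sm$ratio_series$bin_id %in% bins))
  })
})

test_that("row-wise Pearson agrees with cor() across many random instances", {
  withr::with_seed(99, {
    for (rep in 1:60) {
      n <- sample(4:12, 1)
      x <- matrix(rnorm(3 * n), 3, n)
      y <- matrix(rnorm(3 * n), 3, n)
      st <- longitudinal_stability(
        make_matrix(cbind(x, y), samples = c(paste0("a", 1:n), paste0("b", 1:n))),
        data.frame(individual_id = paste0("i", 1:n),
                   sample_1 = paste0("a", 1:n), sample_2 = paste0("b", 1:n),
                   batch = "B1", years_apart = 5))
      for (i in 1:3) {
        expect_equal(st$r_repeated[i], slow_pearson(x[i, ], y[i, ]),
                     tolerance = 1e-12)
        ct <- cor.test(x[i, ], y[i, ])
        expect_equal(st$p_value[i], ct$p.value, tolerance = 1e-12)
      }
    }
  })
})
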