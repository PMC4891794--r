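# CpG/chromatin classification, enrichment, and stability trend tables

test_that("shores flank islands by 2 kb with island territory subtracted", {
  cgi <- data.frame(chrom = "chr1", start = 10000, end = 11000, name = "cgi")
  sh <- build_shores(cgi)
  expect_equal(sh$start, c(8000, 11000))
  expect_equal(sh$end, c(10000, 13000))
  # two islands 1 kb apart: the whole gap is shore, island bases never shore
  cgi2 <- data.frame(chrom = "chr1", start = c(10000, 12000),
                     end = c(11000, 13000), name = "cgi")
  sh2 <- build_shores(cgi2)
  expect_equal(sh2$start, c(8000, 11000, 13000))
  expect_equal(sh2$end, c(10000, 12000, 15000))
  # island at chromosome start: left shore empty
  cgi3 <- data.frame(chrom = "chr1", start = 0, end = 500, name = "cgi")
  sh3 <- build_shores(cgi3)
  expect_equal(sh3$start, 500)
  expect_equal(sh3$end, 2500)
})

test_that("bin classification applies island > shore and promoter > enhancer precedence", {
  grid <- make_bin_grid(c(chr1 = 3000))
  cgi <- data.frame(chrom = "chr1", start = 400, end = 600, name = "cgi")
  chrom <- data.frame(chrom = "chr1",
                      start = c(0, 600, 1500),
                      end = c(600, 1500, 3000),
                      name = c("Active_Promoter", "Strong_Enhancer", "Heterochrom"))
  cls <- classify_bins(grid, cgi, chrom)
  # bin [250,750) overlaps the island (and its shore): island wins
  expect_equal(cls$cpg_class[cls$bin_id == "chr1:250-750"], "island")
  # bin [750,1250) is within 2 kb of the island: shore
  expect_equal(cls$cpg_class[cls$bin_id == "chr1:750-1250"], "shore")
  # bin [250,750) overlaps promoter and enhancer states: promoter wins
  expect_equal(cls$state_class[cls$bin_id == "chr1:250-750"], "promoter")
  expect_equal(cls$state_class[cls$bin_id == "chr1:2750-3000"], "other")
  expect_error(classify_bins(make_bin_grid(c(chrX = 1000)), cgi, chrom), "chrX")
})

test_that("classification agrees with the brute-force overlap oracle", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      grid <- make_bin_grid(c(chr1 = 50000))
      starts <- sort(sample.int(48000, 15))
      cgi <- data.frame(chrom = "chr1", start = starts,
                        end = starts + sample(200:1500, 15, replace = TRUE),
                        name = "cgi")
      cls <- classify_bins(grid, cgi,
                           data.frame(chrom = "chr1", start = 0, end = 50000,
                                      name = "Heterochrom"))
      shores <- build_shores(cgi)
      oracle <- slow_classify_cpg(grid, cgi, shores)
      expect_equal(cls$cpg_class, oracle)
    }
  })
})

test_that("proportion enrichment detects class shifts and matches the chi-square oracle", {
  withr::with_seed(33, {
    n <- 3000
    cls <- data.frame(bin_id = paste0("b", 1:n),
                      cpg_class = sample(c("island", "shore", "open_sea"), n,
                                         replace = TRUE, prob = c(.05, .15, .8)),
                      state_class = "other")
    # uniformly drawn lsBINs: no enrichment
    ls_unif <- sample(cls$bin_id, 500)
    enr <- proportion_enrichment(cls, ls_unif)
    expect_true(all(abs(enr$per_class$z) < 3.5))
    # shore-only lsBINs: strong enrichment and depletion
    ls_shore <- cls$bin_id[cls$cpg_class == "shore"][1:100]
    enr2 <- proportion_enrichment(cls, ls_shore)
    shore_row <- enr2$per_class[enr2$per_class$class == "shore", ]
    sea_row <- enr2$per_class[enr2$per_class$class == "open_sea", ]
    expect_gt(shore_row$z, 3)
    expect_lt(sea_row$z, -3)
    expect_lt(enr2$chisq$p_value, 1e-10)
    # chi-square equals the textbook formula on the same counts table
    counts <- rbind(table(factor(cls$cpg_class[cls$bin_id %in% ls_shore],
                                 levels = sort(unique(cls$cpg_class)))),
                    table(factor(cls$cpg_class,
                                 levels = sort(unique(cls$cpg_class)))))
    expect_equal(enr2$chisq$statistic, slow_chisq(counts), tolerance = 1e-10)
    expect_error(proportion_enrichment(cls, character()), "empty")
    expect_error(proportion_enrichment(cls, "nope"), "unclassified")
  })
})

test_that("stability-by-region means and Welch tests match the hand formulas", {
  withr::with_seed(35, {
    st <- data.frame(bin_id = paste0("b", 1:90),
                     r_repeated = c(rnorm(30, 0.20, 0.05),
                                    rnorm(30, 0.16, 0.05),
                                    rnorm(30, 0.16, 0.05)))
    cls <- data.frame(bin_id = paste0("b", 1:90),
                      cpg_class = rep(c("island", "shore", "open_sea"), each = 30),
                      state_class = "other")
    res <- stability_by_region(st, cls)
    isl <- res$summary[res$summary$class == "island", ]
    expect_equal(isl$mean, mean(st$r_repeated[1:30]), tolerance = 1e-12)
    expect_equal(isl$sem, sd(st$r_repeated[1:30]) / sqrt(30), tolerance = 1e-12)
    w <- slow_welch(st$r_repeated[1:30], st$r_repeated[31:60])
    row <- res$pairwise[res$pairwise$class_1 == "island" &
                          res$pairwise$class_2 == "shore", ]
    expect_equal(row$t, w$t, tolerance = 1e-10)
    expect_equal(row$p_value, w$p, tolerance = 1e-10)
    # a class with < 3 bins is skipped with a warning
    cls2 <- cls; cls2$cpg_class[1:29] <- "shore"
    expect_warning(stability_by_region(st, cls2), "island")
  })
})

test_that("threshold trend table counts shrink and Spearman captures the direction", {
  withr::with_seed(37, {
    n <- 4000
    is_enh <- rbinom(n, 1, 0.08) == 1
    # enhancer bins generated with stochastically lower stability
    r <- ifelse(is_enh, rbeta(n, 1.3, 6), rbeta(n, 2, 5))
    st <- data.frame(bin_id = paste0("b", 1:n), r_repeated = r)
    cls <- data.frame(bin_id = paste0("b", 1:n), cpg_class = "open_sea",
                      state_class = ifelse(is_enh, "enhancer", "other"))
    tt <- threshold_trend(st, cls, thresholds = c(-Inf, 0.11, 0.2, 0.3, 0.4,
                                                  0.5, 0.6, 0.7))
    expect_true(all(diff(tt$table$n_bins) <= 0))
    expect_equal(tt$table$n_bins[1], n)
    enh <- tt$trend[tt$trend$class == "enhancer", ]
    expect_lt(enh$rho, 0)
    expect_lt(enh$p_value, 0.05)
    # strictly decreasing series gives rho = -1 with the exact Spearman p
    st2 <- data.frame(bin_id = paste0("b", 1:n), r_repeated = r)
    pct <- tt$table$pct_enhancer
    if (all(diff(pct) < 0)) expect_equal(enh$rho, -1)
    # constant percentages: rho defined as 0
    cls3 <- data.frame(bin_id = paste0("b", 1:n), cpg_class = "open_sea",
                       state_class = "other")
    tt3 <- threshold_trend(st, cls3)
    expect_equal(tt3$trend$rho[tt3$trend$class == "other"], 0)
    expect_error(threshold_trend(st, cls, thresholds = c(0.2, 0.1)),
                 "ascending")
  })
})
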