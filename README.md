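# twinmeth

Twin-based epigenome-wide association analysis of longitudinally stable DNA
methylation, applied to skeletal muscle mass.

## The problem

Appendicular lean mass ("skeletal muscle mass", SMM) is strongly familial,
yet few genetic variants explain its variation, and its decline drives
sarcopenia. One route to regulatory signal is an epigenome-wide association
study (EWAS) of whole-blood DNA methylation profiled by MeDIP-seq, where the
methylome is quantified in ~11 million overlapping 500-bp bins. At that
scale, naive genome-wide testing is hopeless: most of the bin-level signal
fluctuates over time, and multiple-testing burden swamps realistic effect
sizes.

`twinmeth` implements, as reusable and tested R functions, a twin-cohort
design that attacks both problems:

1. **Stability screening.** Using individuals with repeat visits years
   apart, each bin gets a longitudinal correlation `R_repeated`; only bins
   with significant positive `R_repeated` ("lsBINs") move forward. Per-bin
   MZ and DZ co-twin correlations (`R_MZ`, `R_DZ`) quantify how much of that
   stability is genetic.
2. **Discordant-MZ discovery.** The most SMM-discordant monozygotic pairs
   (ranked by the relative difference
   `dSMM = (SMM_1 − SMM_2) / (0.5·(SMM_1 + SMM_2))`) are tested per lsBIN
   with a paired *t* test, removing genetic confounding by design.
3. **Replication with FDR control.** Candidate bins (discovery `P < .01`,
   `R_repeated > 0.4`) are tested in an independent sample by correlation
   with SMM and covariate-adjusted regression (methylation, age, smoking,
   standardized), with Benjamini–Hochberg control at FDR `q = 0.1` over the
   full candidate family, plus a blood-cell-composition check.
4. **Variance decomposition.** Classical biometrical twin models fitted by
   maximum likelihood: univariate AE/ACE heritability (MZ pairs share
   additive genetics fully, DZ pairs half), and a bivariate model giving the
   genetic correlation `r_G` and environmental correlation `r_E` between
   SMM and each replicated bin, with likelihood ratio tests.
5. **Annotation enrichment.** Bins classified by CpG context
   (island > shore > open sea) and ChromHMM chromatin state
   (promoter > enhancer > other), with enrichment tests and
   stability-threshold trend tables.

A synthetic twin-cohort generator (`simulate_cohort()`) with known ground
truth — family structure, per-bin variance components
`(a², c², e²_stable, e²_visit)`, zero-inflated signal, an SMM phenotype with
high heritability and weak negative age dependence — drives every stage, so
the whole pipeline runs and is tested without any external data.

## Worked example

```r
library(twinmeth)

cohort <- simulate_cohort(cohort_config(
  n_mz_pairs = 150, n_dz_pairs = 80, n_singletons = 20,
  n_bins = 2000, frac_associated_bins = 0.005, assoc_effect = 0.1,
  assoc_route = "environmental", seed = 42))

# stability screen on individuals with repeat visits
pairings  <- make_visit_pairings(cohort$samples)
kept      <- zero_filter(cohort$methylation)
stability <- longitudinal_stability(cohort$methylation, pairings, bins = kept)
lsbins    <- select_lsbins(stability)
length(lsbins)
#> [1] 1448

# discordant-MZ discovery on the lsBINs
pairs <- select_discordant_pairs(make_discordance_table(cohort$samples), k = 50)
disc  <- paired_t_per_bin(cohort$methylation, pairs, bins = lsbins)
cand  <- candidate_filter(disc, stability, p_thresh = 0.01, r_thresh = 0.4)

# heritability of age-adjusted SMM
first <- cohort$samples[!duplicated(cohort$samples$individual_id), ]
fit <- fit_univariate(data.frame(family_id = first$family_id,
                                 zygosity = first$zygosity,
                                 x = residualize(first$smm, first$age)))
fit
#> AE twin model fit for 'x' (150 MZ, 80 DZ pairs, 20 singletons)
#>   h2 = 0.766 +/- 0.032  (a2 = 0.766, c2 = 0.000, e2 = 0.234)
#>   loglik = -615.315
```

1448 of 2000 bins qualify as lsBINs here (every simulated individual has a
repeat visit, so the screen is generous at this scale), and the AE estimator
recovers the generator's SMM heritability (0.809) within 1.5 standard errors
on a cohort of this size. At the default weak effect size the discovery
filter typically yields few or no candidates from only 50 pairs — power
comes at the replication stage; `fit_bivariate()` on a replicated bin
returns `r_G`/`r_E` with likelihood-ratio p values.

`run_pipeline(pipeline_config(), "out/")` executes all stages end to end on
three disjoint subsamples (stability / discovery / replication, enforced),
writing TSV tables, BED tracks, and a JSON manifest with parameter echoes
and per-file MD5 checksums; identical configurations reproduce identical
checksums. A command-line wrapper with `simulate | quantify | screen |
discover | replicate | heritability | annotate | run` subcommands is
installed at `inst/scripts/twinmeth.R`.

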