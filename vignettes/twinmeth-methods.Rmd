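---
title: "Methods: twin-based EWAS of longitudinally stable methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-based EWAS of longitudinally stable methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the assumptions behind the synthetic-data generator, and the
numerical and design choices made where the design was genuinely open. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. Quantification model

MeDIP-seq reads are single-end tags of immunoprecipitated methylated
fragments. `make_bin_grid()` tiles each chromosome with 500-bp bins on a
250-bp step (0-based half-open coordinates), so every interior position is
covered by exactly two bins; the terminal bin is truncated at the chromosome
end rather than dropped, keeping coverage complete. `extend_reads()` extends
each read to 350 bp — the average fragment size — in its strand direction,
clipping at the chromosome bounds. `quantify_sample()` counts extended
fragments overlapping each bin by at least 1 bp (a fragment spanning k bins
counts in all k) and normalizes to reads per bin per million uniquely
mapped reads:

$$\mathrm{signal}(b) = \frac{\#\{\text{extended reads overlapping } b\}}
{\text{total uniquely mapped} / 10^6}.$$

Two deliberate conventions: the normalization contains no per-kilobase
factor (bin width is fixed at 500 bp, so a kb factor would be a constant
rescaling), and the overlap rule is the simplest one (≥ 1 bp), matched
exactly by the brute-force oracle used in the tests. Read input is a plain
TSV of (chrom, start, strand, read length); alignment-container parsing is
out of scope.

## 2. The generative model behind the synthetic cohort

`simulate_cohort()` draws, for each bin $b$ and individual $j$, a stable
biological methylation level

$$B_{jb} = \mu_b + \sigma_b\left(\sqrt{a^2_b}\,A + \sqrt{c^2_b}\,C +
\sqrt{e^2_{\mathrm{st},b}}\,U\right),$$

where $A$ is the additive-genetic factor (shared identically by MZ
co-twins; for DZ co-twins $A_2 = 0.5A_1 + \sqrt{0.75}\,A'$, the standard
biometrical construction giving correlation exactly 0.5), $C$ is shared by
the whole family, and $U$ is individual. Each visit observes
$B_{jb} + \sigma_b\sqrt{e^2_{\mathrm{vis},b}}\,\varepsilon$ with fresh
noise, and with probability `zero_inflation_rate` an observation is
replaced by exact zero — independently per observation, so the >20 %-zeros
filter has a binomially predictable pass rate. Values are clamped at zero
(signal is nonnegative); with the default signal scale
($\mu_b \sim U(5, 50)$ in RPM units, $\sigma_b = 0.15\,\mu_b$, i.e. a
constant 15 % biological coefficient of variation) the clamp is a > 6-sigma
event and statistically negligible.

Model-implied moments used as test oracles (all on the unit-variance
latent scale, before zero-inflation):

* co-twin correlation of observed values: $a^2 + c^2$ (MZ),
  $a^2/2 + c^2$ (DZ);
* within-individual visit correlation:
  $a^2 + c^2 + e^2_{\mathrm{st}}$ (equivalently
  $(a^2+c^2+e^2_{\mathrm{st}})/(a^2+c^2+e^2_{\mathrm{st}}+e^2_{\mathrm{vis}})$,
  the components summing to 1).

**Per-bin variance components.** The default sampler (`default_bin_vc()`)
draws $a^2 \sim \mathrm{Beta}(0.5, 2.5)$ (mean 0.17 with a long right
tail: a heritable minority of bins), $c^2 = (1-a^2)\,\mathrm{Beta}(1, 24)$
(small shared environment), $e^2_{\mathrm{st}} = (1-a^2-c^2)\,
\mathrm{Beta}(1, 6)$, and the remainder as visit-level noise. Visit noise
therefore dominates most bins, and both longitudinal stability and twin
correlation are driven upward by the same per-bin $a^2$ — the feature that
makes the stability/heritability meta-correlations (Correl.1 > Correl.2 > 0
and the rising $R_{MZ}/R_{DZ}$ ratio) emerge rather than being built in
directly. These shapes were fixed once as a plausible rendering of binned
MeDIP-seq behaviour; they are parameters of the study conditions, not
tuning knobs.

**SMM phenotype.** Age-adjusted SMM has unit variance split into an
additive-genetic part of fraction $h^2$ (default 0.809) and a unique
residual; the observed trait adds a standardized age effect (default
−0.097, ages uniform on 17–82 and shared within pair) and is scaled to
39.9 ± 5.4 kg. Smoking is a two-level never/ever score at prevalence 0.41
with no true SMM effect. Blood-cell proportions are Dirichlet-like draws
around a typical adult differential count and independent of methylation.

**Association routes.** The published design does not determine whether
trait-associated bins act through shared genetic factors or through stable
environment. The generator exposes both: `assoc_route = "genetic"` feeds
the bins' $A$ components into SMM's genetic part (creating $r_G$), and
`assoc_route = "environmental"` feeds the $U$ components into the residual
(creating $r_E$). Signed effects alternate in sign and their summed squares
must fit inside the corresponding variance budget ($h^2$ or $1-h^2$),
enforced at configuration time. Note that under the genetic route MZ
co-twins share the bin effect entirely, so discordant-pair discovery has
power only for the environmental route — which is precisely the design
logic of the discordant-MZ stage.

**What the generator does not emulate:** spatial autocorrelation of
methylation along the genome (bins are independent), CpG-density-dependent
signal, batch effects on the measurement scale, and cell-composition
confounding (WBC proportions are independent of methylation by
construction, making the WBC check's null calibration testable). Passing
tests therefore demonstrate correctness of the estimators under the stated
model, not robustness to those real-data features.

## 3. Screening statistics

The zero filter retains a bin iff the fraction of individuals (first visit
each) with exact-zero signal is at most 0.20 — the boundary is retained,
matching "more than 20 % excluded". Longitudinal stability is the Pearson
correlation across visit pairings (consecutive disjoint visit pairs per
individual, same processing batch, ≥ 3 years apart by default; an
individual with four eligible visits contributes two pairs). P values use
the exact t transform with $n-2$ df. lsBINs are bins with $p < 0.05$ and
$R_{\mathrm{repeated}} > 0$; both the $p<.05$ count and the positive subset
are reported. Bins with zero variance in either vector are flagged
undefined, excluded from lsBINs and summaries.

Twin correlations default to **double-entry Pearson** (each pair enters in
both orientations), the order-invariant intraclass estimator for twin data;
single-ordering Pearson is available, since the published tables do not say
which was used. The ratio analysis $R_{MZ}/R_{DZ}$ is restricted to bins
with positive, nominally significant $R_{DZ}$ (otherwise the ratio is
unstable or sign-flipped).

## 4. Discovery and replication

Discordance is the symmetric relative difference
$(s_1-s_2)/\tfrac12(s_1+s_2)$ — the printed formula in the source contains
an obvious typo (it subtracts a term from itself); the relative co-twin
difference is the only reading that yields a ranking statistic. Pairs are
ranked by $|dSMM|$ (ranking by the signed value would discard half the
discordant pairs for no reason), ties at the cut broken by family id, and
each selected pair is oriented so the higher-SMM twin is first, making the
sign of the within-pair methylation difference interpretable. The per-bin
paired t uses $n-1$ df. No multiple-testing correction is applied at
discovery — error control is deferred to replication, mirroring the
original two-stage logic.

Replication computes per-candidate Pearson correlation with SMM (one value
per individual, first eligible visit) and a standardized OLS of SMM on
methylation, age and smoking score (z-scored throughout, so coefficients
are comparable across covariates on different natural scales). The BH
step-up runs over the **full candidate family** `m` (134 in the original
design), with untested candidates conservatively carrying $p = 1$; the
significant set is always a prefix of the p-sorted list and monotone in
`q`. Smoking coding defaults to an ordinal score (never/ex/current) with an
ever/never option. The WBC panel is configurable because the source lists
two slightly different four-type panels (monocytes vs basophils) in
different places; the FACS panel
(neutrophils/eosinophils/monocytes/lymphocytes) is the default. Twins in
the replication sample are treated as independent observations, as in the
original analysis.

## 5. Twin variance decomposition

The likelihood is the classical biometrical twin model: pair values are
bivariate normal with common mean, within-pair covariance $a^2 + c^2$ (MZ)
or $a^2/2 + c^2$ (DZ); singletons contribute marginal terms. AE is the
default (the published analysis reports only $h^2$); ACE is optional.
Numerical choices:

* Traits are standardized before fitting; components are parameterized by
  square roots, so nonnegativity is structural and the reported fractions
  sum to one. Means are estimated inside the likelihood.
* Each likelihood evaluation is O(1) via per-zygosity sufficient statistics
  (counts, first and second moments), so the 100-replicate recovery suites
  run in minutes.
* Optimization is Nelder-Mead followed by BFGS polish; the observed
  information (numerical Hessian) gives delta-method standard errors for
  $h^2$, with a profile-likelihood curvature fallback (central second
  difference at ±0.02 on the $h^2$ axis). Boundary solutions
  ($a^2 \approx 0$, etc.) are flagged.
* The bivariate AE model parameterizes $r_G = \tanh z_G$,
  $r_E = \tanh z_E$ (open interval, smooth); the 4×4 pair covariance uses
  within-person cross-trait covariance $r_G a_x a_y + r_E e_x e_y$ and
  cross-twin cross-trait covariance $r_G a_x a_y$ scaled by 1 (MZ) or 1/2
  (DZ). LRTs refit with $r_G = 0$, $r_E = 0$, and both (df 1, 1, 2).
* LRT p values use the naive chi-square df by default. For a variance-type
  parameter on its boundary this is conservative; a 50:50 point-mass
  mixture correction is available via `lrt(boundary = TRUE)`. Correlations
  tested at interior values are unaffected.
* A constrained fit beating the full fit beyond
  $10^{-5}(1+|\ell|)$ raises a refit-failure error rather than reporting a
  negative chi-square.

The double-entry intraclass correlation uses the number of pairs as the
effective sample size for its t-transform p value — conservative relative
to counting double-entered rows.

## 6. Annotation

Shores are the 2-kb flanks of CpG islands with island territory subtracted
(so island bases are never shore, even between adjacent islands); clipping
at position 0 and optional chromosome ends. Classification precedence is
island > shore > open sea and promoter > enhancer > other, by ≥ 1-bp
overlap — the source states no rule; precedence makes each axis a
partition, which the tests rely on. ChromHMM states are grouped by name
pattern: promoter = active/weak/poised promoter, enhancer = strong/weak
enhancer, everything else `other`. Tracks are consumed as BED (0-based
half-open) with a `one_based` dialect flag for 1-based inclusive dumps.
Enrichment uses a two-proportion Z per class (lsBIN set vs all bins) and an
overall chi-square; group comparisons use Welch t tests; threshold trends
use Spearman rank correlation between threshold rank and class percentage,
with a constant series defined as $\rho = 0$. The trend thresholds
(no filter, 0.11, 0.2, …, 0.7) are free parameters: the equivalence between
"$p < .05$" and "$R > 0.11$" depends on the pairing count and is not
asserted.

## 7. Pipeline and problem sizes

`run_pipeline()` enforces the three-subsample discipline: stability
individuals, discovery pairs and replication individuals are disjoint
(explicit assignments are validated, and a violation is an error). The
default desk-scale configuration uses 130 MZ + 70 DZ pairs + 20 singletons,
1500 bins, a 60-individual stability subsample and 50 discovery pairs —
the original proportions (292 stability individuals, 50 pairs, 1196
replication individuals, 11.5 M bins) scaled to sizes where the full run
takes seconds. The test suite uses: 10,000 bins × 50 MZ pairs for the
discovery type-I calibration; 500 + 500 pairs × 100 replicates for
univariate ($h^2 \in \{0.2, 0.5, 0.8\}$) and bivariate
($h^2_x = 0.8$, $h^2_y = 0.5$, $r_G = 0.5$, $r_E = 0.1$ — an SMM-like and
a bin-like trait) recovery, asserting 2-SE coverage of at least 90 % per
parameter; 3000 bins × (100 MZ + 70 DZ pairs) for the
stability/heritability meta-correlations; and 50 seeded end-to-end runs
(600 bins, 180 MZ + 60 DZ pairs, 10 environmental-route associated bins at
effect 0.2 with $h^2_{SMM} = 0.4$ so the injected effects fit the variance
budget and the replication stage has nontrivial power) for the
false-discovery-proportion check, asserting mean FDP ≤ 0.15 at $q = 0.1$.

For the discovery-calibration runs the generator is configured with
`zero_inflation_rate = 0`: the discovery stage operates on lsBINs, which
have passed the zero filter and represent the stable high-signal fraction
of the methylome where exact zeros are essentially absent, and with clean
signal the paired t is exactly calibrated — matching the design's own 5 %
expectation.

## 8. Known limitations

* Bins are generated independently; nothing here validates methods against
  spatially correlated methylation.
* The AE/ACE family excludes dominance (ADE) and gene–environment
  interaction; extended pedigrees beyond twin pairs + singletons are out of
  scope.
* The bivariate model assumes multivariate normality; zero-inflated bins
  violate it mildly, and heavily zero-inflated bins should be filtered
  before fitting (as the pipeline does).
* The replication stage ignores family clustering, as in the original
  design; an optional family-cluster bootstrap would tighten inference but
  is not implemented.
* Annotation enrichment on synthetic tracks demonstrates machinery, not
  biology: the synthetic CGI/chromatin tracks are random and carry no
  relationship to the simulated variance components unless one is injected.
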