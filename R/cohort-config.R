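#' Configuration for the synthetic twin-cohort generator
#'
#' Bundles and validates all parameters of the generative model used by
#' [simulate_cohort()]. Defaults emulate a female adult twin registry:
#' appendicular lean mass ("skeletal muscle mass", SMM) of 39.9 +/- 5.4 kg
#' with heritability 0.809, a weak negative age effect (standardized
#' -0.097 over ages 17-82), an ever-smoking prevalence of 0.41 with no true
#' SMM effect, and repeat methylation visits 7 years apart.
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons family structure counts.
#' @param n_bins number of genomic bins on the synthetic chromosome
#'   (500 bp wide, 250 bp step; see [make_bin_grid()]).
#' @param n_visits_per_individual number of methylation visits per individual
#'   (>= 2 is required for longitudinal stability screening to be testable).
#' @param visit_gap_years years between consecutive visits.
#' @param frac_associated_bins fraction of bins truly associated with SMM.
#' @param assoc_effect standardized SMM effect size per associated bin
#'   (signs alternate across associated bins).
#' @param assoc_route `"genetic"` routes the association through the bin's
#'   additive-genetic component (creates a genetic correlation with SMM);
#'   `"environmental"` routes it through the stable unique-environment
#'   component (creates an environmental correlation).
#' @param bin_vc_model per-bin variance-component model: `"default"` for the
#'   built-in sampler ([default_bin_vc()]), a numeric length-4 vector
#'   `c(a2, c2, e2_stable, e2_visit)` applied to every bin, an
#'   `n_bins` x 4 matrix, or a `function(n_bins)` returning such a matrix.
#'   Rows must sum to 1.
#' @param zero_inflation_rate per-observation probability that a methylation
#'   value is replaced by exact zero (scalar, or vector of length `n_bins`).
#' @param smm_mean,smm_sd SMM mean and standard deviation in kg.
#' @param smm_h2 narrow-sense heritability of age-adjusted SMM.
#' @param age_range length-2 numeric, years; ages are uniform over the range
#'   and shared within a twin pair.
#' @param beta_age_smm standardized age effect on SMM.
#' @param smoking_prevalence probability an individual is an ever-smoker
#'   (two-level score 0/1, no true SMM effect).
#' @param seed integer RNG seed; identical configurations produce
#'   byte-identical cohorts.
#' @return an object of class `cohort_config` (validated list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_mz_pairs = 100L,
                          n_dz_pairs = 60L,
                          n_singletons = 20L,
                          n_bins = 2000L,
                          n_visits_per_individual = 2L,
                          visit_gap_years = 7,
                          frac_associated_bins = 0.005,
                          assoc_effect = 0.1,
                          assoc_route = c("genetic", "environmental"),
                          bin_vc_model = "default",
                          zero_inflation_rate = 0.02,
                          smm_mean = 39.9,
                          smm_sd = 5.4,
                          smm_h2 = 0.809,
                          age_range = c(17, 82),
                          beta_age_smm = -0.097,
                          smoking_prevalence = 0.41,
                          seed = 1L) {
  cfg <- list(
    n_mz_pairs = check_count(n_mz_pairs, "n_mz_pairs"),
    n_dz_pairs = check_count(n_dz_pairs, "n_dz_pairs"),
    n_singletons = check_count(n_singletons, "n_singletons"),
    n_bins = check_count(n_bins, "n_bins"),
    n_visits_per_individual = check_count(n_visits_per_individual,
                                          "n_visits_per_individual", min = 1),
    visit_gap_years = visit_gap_years,
    frac_associated_bins = frac_associated_bins,
    assoc_effect = assoc_effect,
    assoc_route = match.arg(assoc_route),
    bin_vc_model = bin_vc_model,
    zero_inflation_rate = zero_inflation_rate,
    smm_mean = smm_mean,
    smm_sd = smm_sd,
    smm_h2 = smm_h2,
    age_range = age_range,
    beta_age_smm = beta_age_smm,
    smoking_prevalence = smoking_prevalence,
    seed = check_count(seed, "seed")
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  check_proportion(cfg$frac_associated_bins, "frac_associated_bins")
  check_proportion(cfg$smm_h2, "smm_h2")
  check_proportion(cfg$smoking_prevalence, "smoking_prevalence")
  check_proportion(cfg$zero_inflation_rate, "zero_inflation_rate")
  if (!is.numeric(cfg$visit_gap_years) || cfg$visit_gap_years <= 0) {
    stop("invalid configuration: `visit_gap_years` must be a positive real")
  }
  if (!is.numeric(cfg$smm_sd) || cfg$smm_sd <= 0) {
    stop("invalid configuration: `smm_sd` must be positive")
  }
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) <= 0) {
    stop("invalid configuration: `age_range` must be an increasing length-2 range")
  }
  if (abs(cfg$beta_age_smm) >= 1) {
    stop("invalid configuration: `beta_age_smm` must be a standardized effect in (-1, 1)")
  }
  if (!(length(cfg$zero_inflation_rate) %in% c(1L, cfg$n_bins))) {
    stop("invalid configuration: `zero_inflation_rate` must be scalar or length n_bins")
  }
  n_assoc <- round(cfg$frac_associated_bins * cfg$n_bins)
  budget <- if (cfg$assoc_route == "genetic") cfg$smm_h2 else 1 - cfg$smm_h2
  if (n_assoc * cfg$assoc_effect^2 > budget + 1e-12) {
    stop("invalid configuration: `assoc_effect` too large - summed squared effects (",
         signif(n_assoc * cfg$assoc_effect^2, 3),
         ") exceed the available SMM variance fraction (", signif(budget, 3), ")")
  }
  invisible(cfg)
}

#' Default per-bin variance-component sampler
#'
#' Draws per-bin fractions of additive-genetic (`a2`), shared-environment
#' (`c2`), stable unique-environment (`e2_stable`) and visit-level noise
#' (`e2_visit`) variance, summing to 1. The sampler concentrates heritability
#' in a minority of bins with a long right tail, keeps shared environment
#' small, and lets visit-level noise dominate most bins, mirroring the
#' behaviour of binned MeDIP-seq signal where only a modest fraction of the
#' methylome is longitudinally stable or strongly heritable.
#'
#' @param n_bins number of bins.
#' @return `n_bins` x 4 matrix with columns `a2`, `c2`, `e2_stable`,
#'   `e2_visit`; rows sum to 1.
#' @export
default_bin_vc <- function(n_bins) {
  a2 <- stats::rbeta(n_bins, 0.5, 2.5)
  c2 <- (1 - a2) * stats::rbeta(n_bins, 1, 24)
  rem <- 1 - a2 - c2
  e2_stable <- rem * stats::rbeta(n_bins, 1, 6)
  e2_visit <- rem - e2_stable
  cbind(a2 = a2, c2 = c2, e2_stable = e2_stable, e2_visit = e2_visit)
}

resolve_bin_vc <- function(model, n_bins) {
  vc <- if (is.character(model) && identical(model, "default")) {
    default_bin_vc(n_bins)
  } else if (is.function(model)) {
    model(n_bins)
  } else if (is.numeric(model) && is.null(dim(model)) && length(model) == 4L) {
    matrix(model, nrow = n_bins, ncol = 4, byrow = TRUE,
           dimnames = list(NULL, c("a2", "c2", "e2_stable", "e2_visit")))
  } else if (is.matrix(model) || is.data.frame(model)) {
    as.matrix(model)
  } else {
    stop("invalid configuration: `bin_vc_model` not understood")
  }
  if (n_bins > 0) {
    if (nrow(vc) != n_bins || ncol(vc) != 4L) {
      stop("invalid configuration: `bin_vc_model` must yield an n_bins x 4 matrix")
    }
    if (any(vc < 0) || any(abs(rowSums(vc) - 1) > 1e-9)) {
      stop("invalid configuration: `bin_vc_model` rows must be nonnegative and sum to 1")
    }
  }
  colnames(vc) <- c("a2", "c2", "e2_stable", "e2_visit")
  vc
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic twin cohort configuration\n")
  cat(sprintf("  families: %d MZ pairs, %d DZ pairs, %d singletons\n",
              x$n_mz_pairs, x$n_dz_pairs, x$n_singletons))
  cat(sprintf("  methylome: %d bins, %d visit(s) %.1f years apart\n",
              x$n_bins, x$n_visits_per_individual, x$visit_gap_years))
  cat(sprintf("  SMM: %.1f +/- %.1f kg, h2 = %.3f, beta_age = %.3f\n",
              x$smm_mean, x$smm_sd, x$smm_h2, x$beta_age_smm))
  cat(sprintf("  associated bins: %d (effect %.3g, %s route)\n",
              round(x$frac_associated_bins * x$n_bins), x$assoc_effect,
              x$assoc_route))
  invisible(x)
}
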