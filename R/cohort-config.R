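#' Define one locus of the genotype panel
#'
#' A locus is described by its rsID, a gene label, a variant-allele frequency
#' used for Hardy-Weinberg genotype sampling, and the additive log-scale
#' effects of the heterozygous and homozygous-variant categories on the
#' dose-standardized AUC (ng.hr/ml per mg/day). Wild-type is the reference
#' category with effect 0.
#'
#' @param rsid rsID string, unique within a panel.
#' @param gene_label gene / allele label (e.g. `"UGT1A7"`).
#' @param variant_allele_frequency variant-allele frequency in `[0, 1]`.
#' @param effect_hetero,effect_variant additive effects of the heterozygous and
#'   homozygous-variant categories on `log(standard AUC)` (dimensionless).
#' @return A `locus_definition` list.
#' @export
locus_definition <- function(rsid, gene_label, variant_allele_frequency,
                             effect_hetero = 0, effect_variant = 0) {
  if (!is.numeric(variant_allele_frequency) ||
      variant_allele_frequency < 0 || variant_allele_frequency > 1) {
    stopf("variant_allele_frequency for %s must be in [0, 1]", rsid)
  }
  structure(
    list(rsid = as.character(rsid), gene_label = as.character(gene_label),
         variant_allele_frequency = variant_allele_frequency,
         effect_hetero = effect_hetero, effect_variant = effect_variant),
    class = "locus_definition")
}

#' Default six-locus axitinib pharmacogenetic panel
#'
#' The six loci implicated in axitinib absorption, metabolism and efflux:
#' UGT1A7 387T>G (rs17868323), UGT1A9*1b -118T9>T10 (rs3832043, an indel
#' treated identically to SNVs at the category level), ABCG2 421C>A
#' (rs2231142), ABCB1 2677G>T/A (rs2032582, triallelic), ABCB1 3435C>T
#' (rs1045642) and OR2B11 23delT (rs35305980).
#'
#' Allele frequencies and effect sizes are simulation parameters of this
#' package, not published estimates: frequencies are set in the 0.2-0.4 range
#' typical of these polymorphisms in East Asian populations, and effects span
#' the 1.3-2.2-fold exposure shifts reported for reduced-function transporter
#' and UGT variants with tyrosine-kinase inhibitors. The synonymous ABCB1
#' 3435C>T locus is planted as a null (both effects 0), giving seven non-zero
#' indicator columns among the twelve.
#'
#' @return List of six [locus_definition()] objects.
#' @export
default_panel <- function() {
  list(
    locus_definition("rs17868323", "UGT1A7",    0.35, 0.30, 0.65),
    locus_definition("rs3832043",  "UGT1A9*1b", 0.30, 0.00, 0.45),
    locus_definition("rs2231142",  "ABCG2",     0.30, 0.30, 0.75),
    locus_definition("rs2032582",  "ABCB1",     0.40, 0.00, 0.40),
    locus_definition("rs1045642",  "ABCB1",     0.40, 0.00, 0.00),
    locus_definition("rs35305980", "OR2B11",    0.25, 0.00, 0.55)
  )
}

#' Logistic links from log exposure to clinical outcomes
#'
#' Each AUC-linked outcome (responder, grade >= 2 hand-foot syndrome, grade 2
#' hypothyroidism) is drawn from a logistic model in `log(actual AUC)`;
#' hypertension is drawn independently of exposure. Default intercepts are
#' anchored so that, at the cohort's typical exposure (AUC around 150
#' ng.hr/ml), marginal event rates approximate the tabulated phase II rates
#' (ORR ~27%, hand-foot syndrome grade >= 2 ~20%, hypothyroidism ~75%,
#' hypertension grade >= 2 ~70%).
#'
#' @param responder,hand_foot_syndrome,hypothyroidism numeric
#'   `c(intercept, slope)` on the logit scale; the linear predictor is
#'   `intercept + slope * log(actual AUC)`.
#' @param hypertension scalar probability of a grade >= 2 event (no covariate).
#' @return Named list of link parameters.
#' @export
outcome_links <- function(responder = c(-7.0, 1.2),
                          hand_foot_syndrome = c(-6.4, 1.0),
                          hypothyroidism = c(-2.9, 0.8),
                          hypertension = 0.705) {
  list(responder = responder, hand_foot_syndrome = hand_foot_syndrome,
       hypothyroidism = hypothyroidism, hypertension = hypertension)
}

#' Configure a synthetic sparse-sampling PK cohort
#'
#' Bundles every tunable of the generator: split sizes, the genotype panel,
#' the planted log-linear exposure model, the dosing policy, the day-8
#' steady-state sampling grid, measurement noise, per-patient kinetic
#' parameter ranges, and outcome links.
#'
#' @param n_train,n_validation patients in the training / validation splits
#'   (defaults 44 and 16, the study-design counts).
#' @param loci list of [locus_definition()]; default [default_panel()].
#' @param intercept_b0 intercept of `log(standard AUC)`; default `log(15)`
#'   (standard AUC ~15 ng.hr/ml per mg/day, i.e. AUC ~150 at 10 mg/day).
#' @param effect_dose additive effect of daily dose (per mg/day) on
#'   `log(standard AUC)`; default 0 (standard AUC is already dose-normalized).
#' @param residual_sd residual SD of `log(standard AUC)`; default 0.3.
#' @param dose_policy named numeric vector of probabilities over daily doses in
#'   mg/day; names are doses in `[2, 20]`. Default: point mass at 10 mg/day
#'   (5 mg twice daily).
#' @param sampling_times sampling grid in hours after the day-8 dose; default
#'   `c(0, 1, 2, 3, 4, 8, 12)`.
#' @param measurement_cv multiplicative assay-noise coefficient of variation;
#'   default 0.1.
#' @param ka_range,ke_range per-patient absorption / elimination rate-constant
#'   ranges (1/hr), sampled uniformly; defaults `[0.3, 2]` and `[0.05, 0.5]`.
#' @param outcome_links list from [outcome_links()].
#' @param seed master integer seed; sub-streams per generator stage are derived
#'   deterministically from it.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_train = 44L, n_validation = 16L,
                          loci = default_panel(),
                          intercept_b0 = log(15),
                          effect_dose = 0,
                          residual_sd = 0.3,
                          dose_policy = c("10" = 1),
                          sampling_times = c(0, 1, 2, 3, 4, 8, 12),
                          measurement_cv = 0.1,
                          ka_range = c(0.3, 2), ke_range = c(0.05, 0.5),
                          outcome_links = pgxauc::outcome_links(),
                          seed = 1L) {
  if (n_train < 1 || n_validation < 1) stopf("split sizes must be positive")
  if (residual_sd < 0) stopf("residual_sd must be non-negative")
  if (measurement_cv < 0) stopf("measurement_cv must be non-negative")
  rsids <- vapply(loci, `[[`, character(1), "rsid")
  if (anyDuplicated(rsids)) stopf("duplicate rsid in panel")
  doses <- as.numeric(names(dose_policy))
  if (anyNA(doses) || any(doses < 2) || any(doses > 20)) {
    stopf("dose_policy doses must lie in [2, 20] mg/day")
  }
  if (any(dose_policy < 0) || sum(dose_policy) <= 0) {
    stopf("dose_policy probabilities must be non-negative and sum > 0")
  }
  if (any(sampling_times < 0) || is.unsorted(sampling_times, strictly = TRUE)) {
    stopf("sampling_times must be non-negative and strictly increasing")
  }
  if (diff(ka_range) < 0 || diff(ke_range) < 0 ||
      min(ka_range, ke_range) <= 0) {
    stopf("ka_range and ke_range must be positive, ordered intervals")
  }
  structure(
    list(n_train = as.integer(n_train), n_validation = as.integer(n_validation),
         loci = loci, intercept_b0 = intercept_b0, effect_dose = effect_dose,
         residual_sd = residual_sd,
         dose_policy = dose_policy / sum(dose_policy),
         sampling_times = sampling_times, measurement_cv = measurement_cv,
         ka_range = ka_range, ke_range = ke_range,
         outcome_links = outcome_links, seed = as.integer(seed)),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  patients: %d training + %d validation\n",
              x$n_train, x$n_validation))
  cat(sprintf("  panel: %d loci (%s)\n", length(x$loci),
              paste(vapply(x$loci, `[[`, character(1), "rsid"),
                    collapse = ", ")))
  cat(sprintf("  log standard AUC: b0 = %.3f, residual sd = %.2f\n",
              x$intercept_b0, x$residual_sd))
  cat(sprintf("  sampling (hr): %s; measurement CV = %.2f\n",
              paste(x$sampling_times, collapse = ", "), x$measurement_cv))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
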