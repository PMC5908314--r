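GENOTYPE_LEVELS <- c("wild", "hetero", "variant")

#' Draw panel genotypes under Hardy-Weinberg proportions
#'
#' For each locus with variant-allele frequency `q`, genotype categories are
#' drawn independently per patient with probabilities `((1-q)^2, 2q(1-q), q^2)`
#' for (wild, hetero, variant).
#'
#' @param config a [cohort_config()].
#' @return Long data frame with columns `patient_id`, `rsid`, `category`.
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_train + config$n_validation
  ids <- sprintf("P%03d", seq_len(n))
  set.seed(sub_seed(config$seed, "genotypes"))
  out <- lapply(config$loci, function(locus) {
    q <- locus$variant_allele_frequency
    cat_draw <- sample(GENOTYPE_LEVELS, n, replace = TRUE,
                       prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    data.frame(patient_id = ids, rsid = locus$rsid, category = cat_draw,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Per-patient sums of planted locus effects given long genotype calls.
locus_effect_sum <- function(genotypes, loci) {
  eff <- vapply(split(genotypes, genotypes$patient_id), function(g) {
    s <- 0
    for (locus in loci) {
      cat_i <- g$category[g$rsid == locus$rsid]
      s <- s + switch(cat_i, wild = 0,
                      hetero = locus$effect_hetero,
                      variant = locus$effect_variant)
    }
    s
  }, numeric(1))
  eff[unique(genotypes$patient_id)]
}

#' Generate per-patient true pharmacokinetic parameters
#'
#' Inverts the exposure model that the analysis later estimates:
#' `log(standard AUC) = b0 + sum(locus effects) + effect_dose * dose + eps`,
#' `eps ~ Normal(0, residual_sd)`. Actual AUC is standard AUC times daily dose;
#' true clearance uses the per-interval dose (daily / 2) over the 12-hr
#' interval AUC with mg -> ng and ml -> L unit conversion. Absorption and
#' elimination rate constants are drawn uniformly from the configured ranges,
#' resampling while `|ka - ke| < 0.01` so the steady-state curve is
#' non-degenerate.
#'
#' @param genotypes long genotype table from [generate_genotypes()].
#' @param config a [cohort_config()].
#' @return Data frame with one row per patient: `patient_id`, `dose_mg_per_day`,
#'   `true_standard_auc`, `true_auc`, `true_clearance`, `ka`, `ke`, `split`.
#' @export
generate_pk_truth <- function(genotypes, config) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- unique(genotypes$patient_id)
  n <- length(ids)
  set.seed(sub_seed(config$seed, "pk_truth"))
  dose <- as.numeric(sample(names(config$dose_policy), n, replace = TRUE,
                            prob = config$dose_policy))
  eps <- stats::rnorm(n, 0, config$residual_sd)
  ka <- stats::runif(n, config$ka_range[1], config$ka_range[2])
  ke <- stats::runif(n, config$ke_range[1], config$ke_range[2])
  bad <- abs(ka - ke) < 0.01
  while (any(bad)) {
    ka[bad] <- stats::runif(sum(bad), config$ka_range[1], config$ka_range[2])
    ke[bad] <- stats::runif(sum(bad), config$ke_range[1], config$ke_range[2])
    bad <- abs(ka - ke) < 0.01
  }
  log_std <- config$intercept_b0 + locus_effect_sum(genotypes, config$loci) +
    config$effect_dose * dose + eps
  std_auc <- exp(log_std)
  auc <- std_auc * dose
  data.frame(
    patient_id = ids, dose_mg_per_day = dose,
    true_standard_auc = unname(std_auc), true_auc = unname(auc),
    true_clearance = (dose / 2) * 1000 / unname(auc),  # L/hr, interval dose
    ka = ka, ke = ke,
    split = rep(c("training", "validation"),
                c(config$n_train, config$n_validation))[seq_len(n)],
    stringsAsFactors = FALSE)
}

# Steady-state one-compartment oral-absorption curve over a 12-hr interval,
# superposed over all prior doses and scaled so the exact interval integral
# equals `auc`. Symmetric in (ka, ke), so flip-flop kinetics need no special
# case. Returns a vectorized function of time.
steady_state_curve <- function(ka, ke, auc, tau = 12) {
  k1 <- min(ka, ke); k2 <- max(ka, ke)
  if (abs(ka - ke) < 1e-8) stopf("degenerate kinetics: ka = ke")
  amp <- auc / (1 / k1 - 1 / k2)
  e1 <- 1 - exp(-k1 * tau); e2 <- 1 - exp(-k2 * tau)
  function(t) amp * (exp(-k1 * t) / e1 - exp(-k2 * t) / e2)
}

#' Simulate one patient's concentration-time profile
#'
#' Samples the patient's steady-state curve (see [steady_state_curve]
#' internals: one-compartment first-order absorption, superposed over a 12-hr
#' twice-daily interval, amplitude-calibrated so the exact integral over
#' `[0, 12]` equals `true_auc`) at the configured times, then applies
#' independent multiplicative lognormal measurement noise with the configured
#' CV (mean 1, `sdlog = sqrt(log(1 + cv^2))`).
#'
#' @param truth one row of [generate_pk_truth()] output (data frame or list).
#' @param config a [cohort_config()].
#' @param noise_seed optional integer; defaults to a sub-stream of the config
#'   seed keyed by patient id.
#' @return A `concentration_profile`: list with `patient_id`, `times` (hr),
#'   `concentrations` (ng/ml), `dose_mg_per_day`.
#' @export
simulate_concentration_profile <- function(truth, config, noise_seed = NULL) {
  curve <- steady_state_curve(truth$ka, truth$ke, truth$true_auc)
  conc <- curve(config$sampling_times)
  cv <- config$measurement_cv
  if (cv > 0) {
    if (is.null(noise_seed)) {
      noise_seed <- sub_seed(config$seed, paste0("profile_", truth$patient_id))
    }
    set.seed(noise_seed)
    sdlog <- sqrt(log(1 + cv^2))
    conc <- conc * stats::rlnorm(length(conc), -sdlog^2 / 2, sdlog)
  }
  concentration_profile(truth$patient_id, config$sampling_times, conc,
                        truth$dose_mg_per_day)
}

#' Generate clinical outcome records linked to exposure
#'
#' Responder status (CR or PR), grade >= 2 hand-foot syndrome and grade 2
#' hypothyroidism are Bernoulli draws from logistic models in
#' `log(actual AUC)`; grade >= 2 hypertension is drawn independently of
#' exposure. Responders split CR:PR 1:11 and non-responders split SD:PD:NE
#' 25:3:4 (the tabulated phase II proportions); hand-foot syndrome events are
#' grade 3 with probability 3/9, hypertension events with probability 21/31,
#' hypothyroidism events are always grade 2.
#'
#' @param truths data frame from [generate_pk_truth()].
#' @param config a [cohort_config()].
#' @return Long data frame: `patient_id`, `best_response` (one of CR, PR, SD,
#'   PD, NE, repeated down the patient's AE rows), `ae`, `grade` (0, 2 or 3).
#' @export
generate_outcomes <- function(truths, config) {
  links <- config$outcome_links
  set.seed(sub_seed(config$seed, "outcomes"))
  n <- nrow(truths)
  lauc <- log(truths$true_auc)
  p_resp <- stats::plogis(links$responder[1] + links$responder[2] * lauc)
  responder <- stats::runif(n) < p_resp
  best <- character(n)
  best[responder] <- sample(c("CR", "PR"), sum(responder), replace = TRUE,
                            prob = c(1, 11) / 12)
  best[!responder] <- sample(c("SD", "PD", "NE"), sum(!responder),
                             replace = TRUE, prob = c(25, 3, 4) / 32)
  p_hfs <- stats::plogis(links$hand_foot_syndrome[1] +
                           links$hand_foot_syndrome[2] * lauc)
  hfs_event <- stats::runif(n) < p_hfs
  hfs_grade <- ifelse(hfs_event,
                      ifelse(stats::runif(n) < 3 / 9, 3L, 2L), 0L)
  p_thy <- stats::plogis(links$hypothyroidism[1] +
                           links$hypothyroidism[2] * lauc)
  thy_grade <- ifelse(stats::runif(n) < p_thy, 2L, 0L)
  htn_event <- stats::runif(n) < links$hypertension
  htn_grade <- ifelse(htn_event,
                      ifelse(stats::runif(n) < 21 / 31, 3L, 2L), 0L)
  data.frame(
    patient_id = rep(truths$patient_id, each = 3),
    best_response = rep(best, each = 3),
    ae = rep(c("hand_foot_syndrome", "hypothyroidism", "hypertension"), n),
    grade = as.integer(rbind(hfs_grade, thy_grade, htn_grade)),
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generator: Hardy-Weinberg genotypes, planted PK truth,
#' per-patient sparse concentration profiles, and exposure-linked outcomes.
#' The first `n_train` patients form the training split; the remainder the
#' validation split. All randomness derives from the single master seed in the
#' config, so identical configs give bit-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return A `synthetic_cohort`: list with `config`, `genotypes`, `truth`,
#'   `profiles` (list of `concentration_profile`), `outcomes`.
#' @export
generate_cohort <- function(config) {
  genotypes <- generate_genotypes(config)
  truth <- generate_pk_truth(genotypes, config)
  profiles <- lapply(seq_len(nrow(truth)), function(i) {
    simulate_concentration_profile(truth[i, ], config)
  })
  names(profiles) <- truth$patient_id
  outcomes <- generate_outcomes(truth, config)
  structure(list(config = config, genotypes = genotypes, truth = truth,
                 profiles = profiles, outcomes = outcomes),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic PK cohort: %d patients (%d training, %d validation), %d loci\n",
    nrow(x$truth), sum(x$truth$split == "training"),
    sum(x$truth$split == "validation"), length(x$config$loci)))
  cat(sprintf("  %d samples/patient at hr %s\n",
              length(x$config$sampling_times),
              paste(x$config$sampling_times, collapse = ", ")))
  cat(sprintf("  actual AUC range: %.1f - %.1f ng.hr/ml\n",
              min(x$truth$true_auc), max(x$truth$true_auc)))
  invisible(x)
}

#' Write a cohort to its CSV interchange layout
#'
#' Writes `concentrations.csv` (patient_id, time_hr, conc_ng_ml),
#' `genotypes.csv` (patient_id, rsid, category), `doses.csv`
#' (patient_id, dose_mg_per_day), `outcomes.csv` (patient_id, best_response,
#' ae, grade) and `truth.csv` (generator ground truth; kept out of pipeline
#' inputs, for tests only).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  conc <- do.call(rbind, lapply(cohort$profiles, function(p) {
    data.frame(patient_id = p$patient_id, time_hr = p$times,
               conc_ng_ml = p$concentrations, stringsAsFactors = FALSE)
  }))
  wr <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                        row.names = FALSE, quote = FALSE)
  wr(conc, "concentrations.csv")
  wr(cohort$genotypes, "genotypes.csv")
  wr(cohort$truth[, c("patient_id", "dose_mg_per_day")], "doses.csv")
  wr(cohort$outcomes, "outcomes.csv")
  wr(cohort$truth, "truth.csv")
  invisible(dir)
}

#' Read concentration profiles from the CSV interchange layout
#'
#' @param conc_path path to `concentrations.csv`.
#' @param doses_path path to `doses.csv`.
#' @return Named list of `concentration_profile` objects.
#' @export
read_profiles <- function(conc_path, doses_path) {
  conc <- utils::read.csv(conc_path, stringsAsFactors = FALSE)
  doses <- utils::read.csv(doses_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_hr", "conc_ng_ml")
  if (!all(need %in% names(conc))) {
    stopf("concentrations file must have columns %s", paste(need, collapse = ", "))
  }
  dose_of <- stats::setNames(doses$dose_mg_per_day, doses$patient_id)
  ids <- unique(conc$patient_id)
  profiles <- lapply(ids, function(id) {
    rows <- conc[conc$patient_id == id, ]
    rows <- rows[order(rows$time_hr), ]
    concentration_profile(id, rows$time_hr, rows$conc_ng_ml,
                          unname(dose_of[[as.character(id)]]))
  })
  stats::setNames(profiles, ids)
}
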