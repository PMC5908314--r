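test_that("degenerate allele frequencies give all-wild or all-variant calls", {
  loci0 <- lapply(default_panel(), function(l) {
    l$variant_allele_frequency <- 0; l
  })
  g0 <- generate_genotypes(cohort_config(loci = loci0, seed = 3))
  expect_true(all(g0$category == "wild"))
  loci1 <- lapply(default_panel(), function(l) {
    l$variant_allele_frequency <- 1; l
  })
  g1 <- generate_genotypes(cohort_config(loci = loci1, seed = 3))
  expect_true(all(g1$category == "variant"))
})

test_that("genotype frequencies follow Hardy-Weinberg sampling proportions", {
  loci <- list(locus_definition("rsX", "GENE", 0.3))
  cfg <- cohort_config(n_train = 9000, n_validation = 1000, loci = loci,
                       seed = 41)
  g <- generate_genotypes(cfg)
  n <- 10000
  exp_p <- c(wild = 0.49, hetero = 0.42, variant = 0.09)
  obs <- table(factor(g$category, names(exp_p))) / n
  se <- sqrt(exp_p * (1 - exp_p) / n)
  expect_true(all(abs(obs - exp_p) < 3 * se))
})

test_that("Hardy-Weinberg goodness of fit holds across seeds and loci", {
  # 20 seeds x 6 loci = 120 correct-null chi-square tests at alpha = 0.001;
  # allow <= 2 rejections (expected count 0.12) so the check is not itself a
  # coin flip on sampling noise.
  rejections <- 0L
  for (seed in 1:20) {
    cfg <- cohort_config(n_train = 9000, n_validation = 1000, seed = seed)
    g <- generate_genotypes(cfg)
    for (locus in cfg$loci) {
      q <- locus$variant_allele_frequency
      obs <- table(factor(g$category[g$rsid == locus$rsid], c("wild", "hetero", "variant")))
      pval <- stats::chisq.test(
        obs, p = c((1 - q)^2, 2 * q * (1 - q), q^2))$p.value
      if (pval < 0.001) rejections <- rejections + 1L
    }
  }
  expect_lte(rejections, 2L)
})

test_that("noiseless PK truth follows the planted closed form", {
  loci <- lapply(default_panel(), function(l) {
    l$effect_hetero <- 0; l$effect_variant <- 0; l
  })
  cfg <- cohort_config(loci = loci, residual_sd = 0, intercept_b0 = log(15),
                       seed = 5)
  truth <- generate_pk_truth(generate_genotypes(cfg), cfg)
  expect_equal(truth$true_standard_auc, rep(15, 60), tolerance = 1e-12)
  expect_equal(truth$true_auc, rep(150, 60), tolerance = 1e-12)
  expect_equal(truth$true_auc, truth$true_standard_auc * truth$dose_mg_per_day)
})

test_that("a single planted variant effect scales AUC by exp(effect)", {
  loci <- list(locus_definition("rsX", "GENE", 0.5, effect_hetero = 0,
                                effect_variant = log(2)))
  cfg <- cohort_config(n_train = 200, n_validation = 16, loci = loci,
                       residual_sd = 0, seed = 2)
  g <- generate_genotypes(cfg)
  truth <- generate_pk_truth(g, cfg)
  cat_of <- g$category[match(truth$patient_id, g$patient_id)]
  expect_true(any(cat_of == "variant") && any(cat_of == "wild"))
  ratio <- truth$true_auc[cat_of == "variant"][1] /
    truth$true_auc[cat_of == "wild"][1]
  expect_equal(ratio, 2, tolerance = 1e-12)
})

test_that("mean log standard AUC matches its analytic expectation", {
  cfg <- cohort_config(n_train = 450, n_validation = 50, seed = 13)
  g <- generate_genotypes(cfg)
  truth <- generate_pk_truth(g, cfg)
  # E[sum effects] under HWE category probabilities, plus b0
  e_eff <- sum(vapply(cfg$loci, function(l) {
    q <- l$variant_allele_frequency
    2 * q * (1 - q) * l$effect_hetero + q^2 * l$effect_variant
  }, numeric(1)))
  mu <- cfg$intercept_b0 + e_eff
  # SE of the mean: genotype-effect variance + residual variance
  v_eff <- sum(vapply(cfg$loci, function(l) {
    q <- l$variant_allele_frequency
    p2 <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    e <- c(0, l$effect_hetero, l$effect_variant)
    sum(p2 * e^2) - sum(p2 * e)^2
  }, numeric(1)))
  se <- sqrt((v_eff + cfg$residual_sd^2) / 500)
  expect_lt(abs(mean(log(truth$true_standard_auc)) - mu), 3 * se)
})

test_that("noiseless steady-state curves integrate exactly to true AUC", {
  cfg <- cohort_config(measurement_cv = 0, seed = 17)
  truth <- generate_pk_truth(generate_genotypes(cfg), cfg)
  for (i in c(1, 7, 25, 60)) {
    curve <- pgxauc:::steady_state_curve(truth$ka[i], truth$ke[i],
                                         truth$true_auc[i])
    int <- stats::integrate(curve, 0, 12, rel.tol = 1e-12)$value
    expect_equal(int, truth$true_auc[i], tolerance = 1e-9)
    expect_true(all(curve(seq(0, 12, by = 0.05)) >= 0))
  }
})

test_that("sparse 7-point trapezoid bias stays within the documented envelope", {
  # ka x ke grid spanning the configured ranges; relative bias of the sparse
  # trapezoid vs the exact interval integral bounded by 15%.
  for (ka in c(0.3, 0.8, 1.4, 2)) {
    for (ke in c(0.05, 0.2, 0.35, 0.5)) {
      if (abs(ka - ke) < 0.01) next
      curve <- pgxauc:::steady_state_curve(ka, ke, 150)
      times <- c(0, 1, 2, 3, 4, 8, 12)
      p <- concentration_profile("x", times, curve(times), 10)
      expect_lt(abs(compute_auc_trapezoid(p) - 150) / 150, 0.15)
    }
  }
})

test_that("profiles are reproducible under a fixed seed and noisy under CV > 0", {
  cfg <- cohort_config(seed = 23)
  truth <- generate_pk_truth(generate_genotypes(cfg), cfg)
  p1 <- simulate_concentration_profile(truth[1, ], cfg)
  p2 <- simulate_concentration_profile(truth[1, ], cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$concentrations >= 0))
  cfg0 <- cohort_config(seed = 23, measurement_cv = 0)
  p0 <- simulate_concentration_profile(truth[1, ], cfg0)
  expect_false(isTRUE(all.equal(p0$concentrations, p1$concentrations)))
})

test_that("zero outcome slopes give the intercept's inverse-logit event rate", {
  links <- outcome_links(responder = c(stats::qlogis(0.3), 0))
  cfg <- cohort_config(n_train = 1900, n_validation = 100,
                       outcome_links = links, seed = 29)
  truth <- generate_pk_truth(generate_genotypes(cfg), cfg)
  oc <- generate_outcomes(truth, cfg)
  resp <- unique(oc[, c("patient_id", "best_response")])
  frac <- mean(resp$best_response %in% c("CR", "PR"))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("a near-infinite responder slope thresholds at the logistic midpoint", {
  mid <- log(150)
  links <- outcome_links(responder = c(-1e6 * mid, 1e6))
  cfg <- cohort_config(outcome_links = links, seed = 31)
  truth <- generate_pk_truth(generate_genotypes(cfg), cfg)
  oc <- generate_outcomes(truth, cfg)
  resp <- unique(oc[, c("patient_id", "best_response")])
  is_resp <- resp$best_response[match(truth$patient_id, resp$patient_id)] %in%
    c("CR", "PR")
  expect_identical(is_resp, truth$true_auc > 150)
})

test_that("hypertension is generated independently of exposure", {
  cfg <- cohort_config(n_train = 1900, n_validation = 100, seed = 37)
  truth <- generate_pk_truth(generate_genotypes(cfg), cfg)
  oc <- generate_outcomes(truth, cfg)
  htn <- oc[oc$ae == "hypertension", ]
  hi <- htn$grade[match(truth$patient_id, htn$patient_id)] >= 2
  res <- mann_whitney_u(log(truth$true_auc[hi]), log(truth$true_auc[!hi]))
  expect_gt(res$p_value, 0.05)
})

test_that("default cohort has the study-design split sizes and sampling grid", {
  ch <- generate_cohort(cohort_config(seed = 43))
  expect_equal(sum(ch$truth$split == "training"), 44)
  expect_equal(sum(ch$truth$split == "validation"), 16)
  expect_length(ch$profiles, 60)
  expect_true(all(vapply(ch$profiles, function(p) length(p$times),
                         integer(1)) == 7))
  # different seeds: same schema, different concentrations
  ch2 <- generate_cohort(cohort_config(seed = 44))
  expect_identical(names(ch2$profiles), names(ch$profiles))
  expect_false(identical(ch$profiles[[1]]$concentrations,
                         ch2$profiles[[1]]$concentrations))
})

test_that("a minimal cohort round-trips through the CSV writers unchanged", {
  cfg <- cohort_config(n_train = 1, n_validation = 1, seed = 47)
  ch <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  profs <- read_profiles(file.path(dir, "concentrations.csv"),
                         file.path(dir, "doses.csv"))
  expect_equal(length(profs), 2)
  expect_equal(profs[[1]]$times, ch$profiles[[1]]$times)
  expect_equal(profs[[1]]$concentrations, ch$profiles[[1]]$concentrations,
               tolerance = 1e-12)
  expect_equal(profs[[1]]$dose_mg_per_day, ch$profiles[[1]]$dose_mg_per_day)
})
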