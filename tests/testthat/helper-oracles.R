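# Independent oracles used across tests. These are deliberately naive
# implementations (enumeration, permutation, dense numerical integration) kept
# separate from the package's own code paths.

# Piecewise-linear integral by dense midpoint evaluation of approx(); checks
# the trapezoid independently of the closed-form sum.
oracle_piecewise_linear_auc <- function(times, conc, n_grid = 2e5) {
  f <- stats::approxfun(times, conc)
  h <- (max(times) - min(times)) / n_grid
  mid <- min(times) + (seq_len(n_grid) - 0.5) * h
  sum(f(mid)) * h
}

# Kruskal-Wallis H from the textbook rank-sum formula (with tie correction),
# written independently of kruskal.test.
oracle_kw_h <- function(groups) {
  values <- unlist(groups)
  r <- rank(values)
  n <- length(values)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Permutation mid-p for any statistic computed on a grouped sample. Mid-p
# (half weight on permutations tying the observed statistic) is the quantity
# a continuous large-sample approximation estimates for a discrete
# permutation distribution.
oracle_perm_p <- function(values, idx, stat_fn, n_perm, seed) {
  set.seed(seed)
  obs <- stat_fn(values, idx)
  gt <- 0; eq <- 0
  for (i in seq_len(n_perm)) {
    s <- stat_fn(values, sample(idx))
    if (s > obs + 1e-9) gt <- gt + 1 else if (s > obs - 1e-9) eq <- eq + 1
  }
  (gt + 0.5 * eq) / n_perm
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tiny samples only).
oracle_mwu_exact_p <- function(a, b) {
  values <- c(a, b)
  n <- length(values); na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_stat(a, b)
  mu <- na * length(b) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(ix) u_stat(values[ix], values[-ix]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Cochran-Armitage permutation mid-p: permute case/control labels over
# individual patients reconstructed from the 2 x 3 table. |cor| is a
# permutation-equivalent statistic to |Z| (both monotone in |U|).
oracle_ca_perm_p <- function(counts, n_perm, seed) {
  genos <- rep(c(0, 1, 2), colSums(counts))
  is_case <- rep(rep(c(TRUE, FALSE), 3), as.vector(counts))
  # as.vector(counts) is column-major: (case,ctrl) per genotype column
  stat <- function(case_lab) abs(stats::cor(genos, as.numeric(case_lab)))
  set.seed(seed)
  obs <- stat(is_case)
  gt <- 0; eq <- 0
  for (i in seq_len(n_perm)) {
    s <- stat(sample(is_case))
    if (s > obs + 1e-9) gt <- gt + 1 else if (s > obs - 1e-9) eq <- eq + 1
  }
  (gt + 0.5 * eq) / n_perm
}

# Dense-grid config used where exact NCA is needed.
dense_config <- function(...) {
  cohort_config(sampling_times = seq(0, 12, by = 0.002), measurement_cv = 0,
                residual_sd = 0, ...)
}

# Planted non-zero effects of the default panel, keyed by covariate label.
planted_effects <- function(effect_dose = 0) {
  eff <- c(UGT1A7_rs17868323_het = 0.30, UGT1A7_rs17868323_var = 0.65,
           UGT1A91b_rs3832043_var = 0.45, ABCG2_rs2231142_het = 0.30,
           ABCG2_rs2231142_var = 0.75, ABCB1_rs2032582_var = 0.40,
           OR2B11_rs35305980_var = 0.55)
  if (effect_dose != 0) eff <- c(eff, dose_mg_per_day = effect_dose)
  eff
}

# Fit the exposure model through the full simulate -> NCA -> design -> fit
# path for a given config; returns model plus cohort pieces.
fit_through_pipeline <- function(config, k = 8,
                                 selection_method = "forward_loo") {
  ch <- generate_cohort(config)
  pk <- compute_pk_table(ch$profiles)
  design <- build_design_matrix(
    ch$genotypes, ch$truth[, c("patient_id", "dose_mg_per_day")], config$loci)
  tr <- ch$truth$split == "training"
  std <- pk$auc_0_12[tr] / ch$truth$dose_mg_per_day[tr]
  list(model = fit_exponential_model(design[tr, , drop = FALSE], std, k = k,
                                     selection_method = selection_method),
       cohort = ch, pk = pk, design = design, training = tr)
}
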