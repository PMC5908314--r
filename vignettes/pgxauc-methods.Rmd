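---
title: "Pharmacogenetics-based prediction of axitinib exposure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacogenetics-based prediction of axitinib exposure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxauc)
```

## The problem

Axitinib, a VEGFR tyrosine-kinase inhibitor used in advanced renal cell
carcinoma, shows extreme between-patient variability in plasma exposure —
interval AUCs spanning roughly two orders of magnitude at comparable doses.
Exposure tracks both efficacy (objective response) and the on-target
toxicities (hand-foot syndrome, hypothyroidism), but measuring it requires a
day of serial blood sampling at steady state, which is impractical in the
clinic. Because much of the variability is attributable to polymorphisms in
the genes handling absorption, glucuronidation and efflux (*ABCB1*, *ABCG2*,
*UGT1A*) plus one locus flagged by exome-wide association (*OR2B11*), a
regression of exposure on genotype offers a pre-treatment estimate of each
patient's AUC, and with it a rational initial dose.

`pgxauc` implements that workflow end to end: non-compartmental analysis
(NCA) of sparse concentration profiles, genotype encoding, the exponential
exposure regression with variable selection, quartile-based dose advice, the
supporting association statistics, and a fully seeded synthetic-cohort
generator so every stage is testable without patient-level data (none are
publicly deposited for this design).

## The exposure model

The response is the *standard AUC* $y$ — the interval AUC divided by daily
dose (ng·hr/ml per mg/day). With six loci each dummy-coded into two
indicators $(x_i, x_{i+1})$ — wild-type $(0,0)$, heterozygous $(1,0)$,
homozygous variant $(0,1)$ — plus daily dose $x_j$ in mg/day, there are 13
candidate covariates, of which $k = 8$ are selected:

$$ y = \exp\Big(b_0 + \sum_i b_i x_i\Big), $$

with coefficients estimated by ordinary least squares of $\log y$ on the
selected covariates. The exponential link guarantees positive predictions
and makes genotype effects multiplicative on exposure, which matches how
reduced-function transporter and UGT variants act (fold-changes, not
additive shifts). *Calculated AUC* is the predicted standard AUC times the
daily dose; dose enters untransformed as a covariate because no transform is
implied by the design.

### Variable selection

Eight of the thirteen candidates are used. The default search is forward
selection minimizing the leave-one-out (PRESS) squared error on the log
scale, with ties broken toward the lower column index; an exhaustive
best-subset search over all $\binom{13}{8} = 1287$ subsets under the same
criterion is available and is cheap at these sizes
(`selection_method = "best_subset"`), as is a fully manual specification
(`"none"` with `force_labels`). Two numerical points matter:

* PRESS is computed from the hat matrix, $\sum_i (e_i/(1-h_{ii}))^2$. An
  observation with leverage $h_{ii} \to 1$ — e.g. the only homozygous
  carrier at a rare locus in a 44-patient cohort — makes the criterion
  infinite for every subset containing that indicator. That is the correct
  behavior for a cross-validation criterion (a coefficient supported by one
  patient cannot be validated), but it means LOO-based selection can
  deliberately exclude a truly causal but singleton-supported column.
* Greedy forward selection carries no optimality guarantee: even on
  noiseless data it can commit early to a correlated column and then be
  unable to reach the exactly-fitting subset with $k$ fixed. The exhaustive
  search does not have this failure mode, which is why the package's
  noiseless-recovery validation uses it.

Rank-deficient candidate sets score as infinitely bad rather than erroring,
so a constant column (e.g. dose under a one-dose policy) is simply never
selected.

### Quartile-based dose advice

The 25th and 75th percentiles of the *training* cohort's calculated AUC are
frozen into the model (type-7 linear interpolation between order statistics,
R's default quantile convention). At prediction time a calculated AUC at or
below the 25th percentile is categorized `low` (consider a higher initial
dose — exposure tracks response), at or above the 75th `high` (consider a
lower dose — exposure tracks on-target toxicity), otherwise `mid`
(maintain). Boundaries are inclusive on both sides by the rule's "and less /
and more" phrasing. Quartiles are never refit at prediction time, matching
prospective use, and the advice is categorical only — no mg mapping is
prescribed.

## Non-compartmental analysis

Profiles are sampled at 0, 1, 2, 3, 4, 8 and 12 hr after the day-8 morning
dose (steady state under 12-hourly dosing). The interval AUC is the linear
trapezoid over consecutive samples; C-max is the maximum observed
concentration, C-0hr the pre-dose sample, trough the 12-hr sample. Total
clearance is dose over AUC with mg→ng and ml→L conversion,
$CL\,(\mathrm{L/hr}) = 10^3 \cdot d_{mg} / \mathrm{AUC}$, where the dose
basis $d_{mg}$ defaults to the per-interval dose (daily/2) since the AUC
spans one of the two daily intervals; the full daily dose is available as a
configuration because the original tabulations do not state which basis was
used, and neither basis can be reconstructed from published medians (a
median of ratios is not a ratio of medians).

Choices on the edges: the linear (not log-linear) trapezoid is used
throughout, matching the named method; profiles with fewer than 3 samples or
no time-0 sample are marked non-evaluable rather than erroring; a zero AUC
leaves clearance undefined (flagged, not thrown); negative concentrations
are an input error and never clipped.

## Association statistics

* **Kruskal–Wallis** (exposure across genotype or exposure-category groups):
  tie-corrected $H$ with a $\chi^2_{g-1}$ reference; the fully degenerate
  all-equal case is defined as $H = 0$, $p = 1$.
* **Mann–Whitney U** (exposure by binary outcome): $U$ counts pairs
  $(a, b)$ with $a < b$ plus half-ties, so the mirrored statistic is
  $n_a n_b - U$; the p-value is exact for tie-free samples up to $n = 50$
  per arm and a tie- and continuity-corrected normal approximation
  otherwise. Two-sided throughout.
* **Simple linear regression** (calibration of actual on calculated AUC):
  OLS slope with its two-sided t-test; $R^2$ is the squared Pearson
  correlation.
* **Cochran–Armitage trend** (variant-allele dose vs. exposure-high/low
  status): score test with weights $(0, 1, 2)$,
  $Z = U/\sqrt{\bar p(1-\bar p)\,(\sum n_i w_i^2 - (\sum n_i w_i)^2/N)}$
  with $U = \sum w_i r_i - \bar p \sum w_i n_i$, referred two-sided to the
  standard normal. Degenerate tables (zero trend variance) return $Z = 0$,
  $p = 1$; a zero column is permitted.

The exome-style scan (`trend_scan`) dichotomizes patients at a configurable
AUC quantile (default the median, so "exposure-high" vs "exposure-low"
halves), applies the trend test per variant, and ranks by raw p-value with a
Bonferroni column for reference; no adjustment is applied by default because
the scan is a ranking device, not a formal discovery procedure.

A note on validating asymptotic p-values: the test suite compares them to
*mid-p* permutation oracles (half weight on permutations tying the observed
statistic), because a continuous approximation estimates the mid-p of a
discrete permutation lattice. For 2×3 trend tables the lattice atoms near
the null are ~0.05 wide at cell counts of 10–20, so agreement is asserted on
tables with cell counts around 60, where the lattice is fine enough for a
0.03 absolute tolerance to be meaningful.

## The synthetic cohort generator

The generator inverts the analysis model so that the planted regression is
the single source of truth:

1. **Genotypes.** Per locus, categories are drawn under Hardy–Weinberg
   proportions $((1-q)^2,\, 2q(1-q),\, q^2)$. Default variant-allele
   frequencies are 0.25–0.40 per locus — typical of these polymorphisms in
   East Asian populations; the source study reports none.
2. **Exposure truth.** $\log y = b_0 + \sum \text{effects} +
   \beta_d \cdot \text{dose} + \varepsilon$, $\varepsilon \sim N(0,
   \sigma)$, with $b_0 = \log 15$ (AUC ≈ 150 ng·hr/ml at 10 mg/day, the
   tabulated median scale), $\sigma = 0.3$, and seven non-zero indicator
   effects of 0.30–0.75 log units (1.3–2.1-fold), the synonymous ABCB1
   3435C>T planted as a null. The dose effect $\beta_d$ defaults to 0
   (standard AUC is already dose-normalized). Together with measurement
   noise this yields the order-of-magnitude-scale exposure spread the
   assay data showed.
3. **Profiles.** Each patient gets a steady-state one-compartment
   first-order-absorption curve, superposed over the 12-hr interval, with
   $k_a \sim U(0.3, 2)$ and $k_e \sim U(0.05, 0.5)\ \mathrm{hr}^{-1}$
   (resampled while $|k_a - k_e| < 0.01$). The curve's amplitude is scaled
   so its *exact* interval integral equals the planted AUC — calibrating to
   the regression truth rather than drawing V and CL independently — and
   observed concentrations multiply it by independent lognormal noise with
   CV 0.1 (mean 1). Because the steady-state interval is periodic,
   $C(0) = C(12)$ exactly on the noiseless curve; the observed C-0hr/trough
   discrepancy is a noise phenomenon.
4. **Outcomes.** Responder status, grade ≥2 hand-foot syndrome and grade 2
   hypothyroidism are Bernoulli in $\log \mathrm{AUC}$ with intercepts
   anchored to the tabulated marginal rates (ORR ≈ 27%, HFS ≈ 20%,
   hypothyroidism ≈ 75%); hypertension (≈ 70% grade ≥2) is drawn
   independently of exposure, reproducing its observed non-association.
   Within responders CR:PR is 1:11 and within non-responders SD:PD:NE is
   25:3:4, the tabulated proportions, so the reporting stage reproduces the
   published table arithmetic on synthetic data.

Cohorts default to 44 training + 16 validation patients, one master seed,
and deterministic per-stage sub-streams, so identical configurations are
byte-identical.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: assay error is i.i.d. lognormal (no LLOQ
censoring, no carryover), kinetics are strictly one-compartment and exactly
at steady state (no accumulation drift, vomited doses, or adherence gaps),
genotype effects are exactly additive on the log scale with no
gene–gene or gene–drug interactions, and covariates the study discusses but
never models (age, body weight, smoking, co-medication) do not exist in the
simulation. Recovery results therefore validate the *software* against its
own assumptions, not the biological model.

## Numerical and validation choices

* The 7-point trapezoid under-integrates a convex exponential decline; over
  the configured $(k_a, k_e)$ ranges the relative bias of the sparse grid
  against the exact interval integral stays within 15%, and the suite pins
  that envelope. Exact-recovery checks replace the sampling grid with a
  0.002-hr grid, where the trapezoid's $O(h^2)$ error (~$10^{-7}$ relative)
  is far below the 10^-6 recovery tolerance; a 0.1-hr grid would bottom out
  near $10^{-4}$ and cannot support that tolerance.
* Validation problem sizes: coefficient recovery uses 50 stochastic cohorts
  at the study conditions; type-I-error checks use 5,000 null replicates per
  test (three groups of 25 for Kruskal–Wallis, 20 per arm for Mann–Whitney,
  $n = 20$ for regression, $n = 100$ for the trend test); scan power uses a
  large-effect locus among 500 nulls at $n = 44$ over 100 replicates, and
  null calibration compares the minimum p over 500 null variants to its
  uniform order-statistic law across 1,000 replicates at $n = 120$, where
  the normal approximation holds in the far tail.
* Percentages in reporting tables are rounded half-up to one decimal
  (11/44 → 25.0); banker's rounding would differ on exact halves, and
  percentages always recompute from counts.
* Reported coefficient standard errors are the classical OLS ones on the
  selected set; they do not account for selection, which is why the
  stochastic-recovery suite checks coverage empirically (and why
  selection-conditioned bias on the weakest planted effects is expected).

## Limitations

The model consumes only the three-way genotype category — no phasing,
star-allele calling beyond the two named alleles, or imputation. The scan
implements only the downstream trend statistic, not read-level variant
calling or annotation. No extrapolation to AUC$_{0-\infty}$, compartmental
fitting, or survival modelling is attempted. The dose advice is a
categorical flag derived from training quartiles; translating it into mg
adjustments is a clinical decision outside the package's scope.
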