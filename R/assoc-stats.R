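test_result <- function(method, statistic, p_value, ...) {
  structure(c(list(method = method, statistic = unname(statistic),
                   p_value = unname(p_value)), list(...)),
            class = "pgx_test_result")
}

#' @export
print.pgx_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square reference on `g - 1` degrees of
#' freedom. The fully degenerate case (every value identical) is defined as
#' `H = 0, p = 1`.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return A test result: `statistic` (H), `p_value`, `df`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))  # H = 7.2
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) stopf("empty group")
  values <- unlist(groups)
  if (length(values) < 3) stopf("need total n >= 3")
  if (length(unique(values)) == 1) {
    return(test_result("Kruskal-Wallis", 0, 1, df = length(groups) - 1L))
  }
  kt <- stats::kruskal.test(values,
                            g = factor(rep(seq_along(groups),
                                           lengths(groups))))
  test_result("Kruskal-Wallis", kt$statistic, kt$p.value,
              df = unname(kt$parameter))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The statistic follows the convention
#' `U = #{(a, b) pairs with a < b} + (1/2) #{ties}`, so for
#' `a = {1,2,3}, b = {4,5,6}` the statistic is 9 (the mirrored statistic is
#' `n_a * n_b - U = 0`). The p-value is exact when both samples have at most
#' 50 observations and no ties occur, otherwise a tie-corrected,
#' continuity-corrected normal approximation is used.
#'
#' @param a,b non-empty numeric vectors.
#' @return A test result: `statistic` (U), `p_value`, `n_a`, `n_b`, `exact`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stopf("empty sample")
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  # wilcox.test's W counts pairs with a > b (+ half ties); mirror it.
  u <- length(a) * length(b) - unname(wt$statistic)
  exact <- length(a) <= 50 && length(b) <= 50 &&
    !any(duplicated(c(a, b)))
  test_result("Mann-Whitney U", u, wt$p.value,
              n_a = length(a), n_b = length(b), exact = exact)
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` with the two-sided t-test for the
#' slope; `r_squared` is the squared Pearson correlation.
#'
#' @param x,y paired numeric vectors, `n >= 3`, `x` not constant.
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
simple_linear_regression <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch")
  if (length(x) < 3) stopf("need n >= 3")
  if (stats::var(x) == 0) stopf("x is constant")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = unname(s$coefficients[2, 4]),
       n = length(x))
}

#' Cochran-Armitage trend test on a 2 x 3 genotype table
#'
#' Score test for a linear trend in case proportion across genotype columns
#' ordered by variant-allele dose. With case counts `r_i`, column totals
#' `n_i`, scores `w_i` (default 0, 1, 2), `R` cases of `N` total:
#' `U = sum(w_i r_i) - (R/N) sum(w_i n_i)` and
#' `Var(U) = (R/N)(1 - R/N) * (sum(n_i w_i^2) - (sum(n_i w_i))^2 / N)`;
#' `Z = U / sqrt(Var)` is referred to the standard normal, two-sided.
#' Identical genotype proportions in both rows give `Z = 0, p = 1`, as does a
#' degenerate table with zero trend variance.
#'
#' @param counts 2 x 3 matrix (rows: e.g. AUC-high cases, AUC-low controls;
#'   columns: wild, hetero, variant) or a list with `cases` and `controls`
#'   count vectors.
#' @param weights per-column scores; default `c(0, 1, 2)`.
#' @return A test result: `statistic` (Z), `p_value`, `counts`.
#' @export
cochran_armitage_trend <- function(counts, weights = c(0, 1, 2)) {
  if (is.list(counts) && !is.matrix(counts)) {
    counts <- rbind(cases = counts$cases, controls = counts$controls)
  }
  if (!is.matrix(counts) || nrow(counts) != 2 ||
      ncol(counts) != length(weights)) {
    stopf("counts must be a 2 x %d matrix", length(weights))
  }
  if (any(counts < 0)) stopf("negative counts")
  N <- sum(counts)
  if (N == 0) stopf("empty table")
  r <- counts[1, ]; n <- colSums(counts); R <- sum(r)
  u <- sum(weights * r) - R / N * sum(weights * n)
  v <- (R / N) * (1 - R / N) * (sum(n * weights^2) - sum(n * weights)^2 / N)
  if (v <= 0) return(test_result("Cochran-Armitage trend", 0, 1,
                                 counts = counts))
  z <- u / sqrt(v)
  test_result("Cochran-Armitage trend", z, 2 * stats::pnorm(-abs(z)),
              counts = counts)
}

#' Trend-test scan over a variant panel
#'
#' Dichotomizes patients into exposure-high and exposure-low groups at a
#' configurable AUC quantile (default the median), builds a 2 x 3
#' genotype-by-group table per variant, applies the Cochran-Armitage trend
#' test, and returns variants ranked by ascending p. Raw p-values are the
#' default ranking; a Bonferroni-adjusted column is included for reference.
#'
#' @param genotype_matrix patients x variants matrix of variant-allele counts
#'   (0, 1, 2) or categories (`"wild"`, `"hetero"`, `"variant"`); column names
#'   are variant ids.
#' @param auc actual AUC per patient (rows of `genotype_matrix`).
#' @param split_quantile AUC quantile for the high/low dichotomy; default 0.5.
#' @return Data frame sorted by ascending p: `variant`, six count columns,
#'   `z`, `p`, `p_bonferroni`, plus attribute `auc_threshold`.
#' @export
trend_scan <- function(genotype_matrix, auc, split_quantile = 0.5) {
  if (nrow(genotype_matrix) != length(auc)) stopf("row/AUC length mismatch")
  if (anyNA(auc)) stopf("missing AUC values")
  g <- genotype_matrix
  if (is.character(g)) {
    g <- matrix(match(genotype_matrix, GENOTYPE_LEVELS) - 1L,
                nrow = nrow(genotype_matrix),
                dimnames = dimnames(genotype_matrix))
    if (anyNA(g)) stopf("unknown genotype category in matrix")
  }
  thr <- stats::quantile(auc, split_quantile, type = 7)
  high <- auc > thr
  if (all(high) || !any(high)) stopf("degenerate AUC split")
  # vectorized 2 x 3 counts per variant
  cnt <- function(rows, cat_i) colSums(g[rows, , drop = FALSE] == cat_i)
  r0 <- cnt(high, 0L); r1 <- cnt(high, 1L); r2 <- cnt(high, 2L)
  s0 <- cnt(!high, 0L); s1 <- cnt(!high, 1L); s2 <- cnt(!high, 2L)
  n0 <- r0 + s0; n1 <- r1 + s1; n2 <- r2 + s2
  N <- n0 + n1 + n2; R <- r0 + r1 + r2
  u <- (r1 + 2 * r2) - R / N * (n1 + 2 * n2)
  v <- (R / N) * (1 - R / N) * ((n1 + 4 * n2) - (n1 + 2 * n2)^2 / N)
  z <- ifelse(v > 0, u / sqrt(pmax(v, .Machine$double.eps)), 0)
  p <- ifelse(v > 0, 2 * stats::pnorm(-abs(z)), 1)
  out <- data.frame(
    variant = colnames(g) %||% paste0("v", seq_along(p)),
    high_wild = r0, high_hetero = r1, high_variant = r2,
    low_wild = s0, low_hetero = s1, low_variant = s2,
    z = z, p = p,
    p_bonferroni = pmin(1, p * length(p)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p, out$variant), ]
  rownames(out) <- NULL
  attr(out, "auc_threshold") <- unname(thr)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
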