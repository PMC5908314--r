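# Leave-one-out (PRESS) mean squared error of OLS of y on X (with intercept),
# via the hat-matrix identity e_i / (1 - h_ii). Returns Inf for
# rank-deficient designs so selection skips them.
press_mse <- function(X, y) {
  Xi <- cbind(1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) return(Inf)
  beta <- qr.coef(qr_x, y)
  e <- y - Xi %*% beta
  h <- rowSums(qr.Q(qr_x)^2)
  if (any(h > 1 - 1e-10)) return(Inf)
  mean((e / (1 - h))^2)
}

#' Fit the exponential standard-AUC regression
#'
#' Models the dose-standardized AUC as
#' `y = exp(b0 + sum_i b_i x_i)` and estimates the coefficients by ordinary
#' least squares of `log(standard AUC)` on a selected subset of the candidate
#' covariates. Selection chooses exactly `k` of the candidates (default
#' `k = 8` of the 13: twelve genotype indicators plus dose):
#'
#' * `"forward_loo"` (default): forward selection minimizing leave-one-out
#'   squared error on the log scale, ties broken by lower column index;
#' * `"best_subset"`: exhaustive search over all size-`k` subsets by the same
#'   leave-one-out criterion (feasible at these candidate counts);
#' * `"none"`: no selection; `force_labels` (or all columns, if `k` equals the
#'   candidate count) are used as given.
#'
#' @param design numeric matrix from [build_design_matrix()] (patients x
#'   candidates, labelled columns).
#' @param standard_auc positive actual standard AUC values (ng.hr/ml per
#'   mg/day), one per design row.
#' @param k number of covariates to select.
#' @param selection_method `"forward_loo"`, `"best_subset"` or `"none"`.
#' @param force_labels character vector of column labels to use when
#'   `selection_method = "none"`.
#' @return A `fitted_auc_model`: intercept `b0`, named `coefficients` with
#'   OLS standard errors (`coef_se`, `b0_se`),
#'   `selected_labels`, `training_quartiles` (25th/75th percentiles of the
#'   training calculated AUC, type-7 linear interpolation), `fit_diagnostics`
#'   (in-sample R-squared on the log and AUC scales), `k`,
#'   `selection_method`, and a `training_hash` fingerprint.
#' @export
fit_exponential_model <- function(design, standard_auc, k = 8,
                                  selection_method = c("forward_loo",
                                                       "best_subset", "none"),
                                  force_labels = NULL) {
  selection_method <- match.arg(selection_method)
  if (any(!is.finite(standard_auc)) || any(standard_auc <= 0)) {
    bad <- rownames(design)[!is.finite(standard_auc) | standard_auc <= 0]
    stopf("non-positive standard AUC for patient(s): %s",
          paste(bad, collapse = ", "))
  }
  if (nrow(design) != length(standard_auc)) stopf("design/response mismatch")
  if (nrow(design) < k + 2) stopf("need at least k + 2 = %d patients", k + 2)
  y <- log(standard_auc)
  labels <- colnames(design)

  sel <- switch(selection_method,
    none = {
      if (is.null(force_labels)) force_labels <- labels
      if (!all(force_labels %in% labels)) stopf("unknown label in force_labels")
      match(force_labels, labels)
    },
    forward_loo = {
      chosen <- integer(0)
      for (step in seq_len(k)) {
        cand <- setdiff(seq_along(labels), chosen)
        score <- vapply(cand, function(j) {
          press_mse(design[, c(chosen, j), drop = FALSE], y)
        }, numeric(1))
        if (all(!is.finite(score))) stopf("rank-deficient selected design")
        chosen <- c(chosen, cand[which.min(score)])  # which.min: lowest index on ties
      }
      sort(chosen)
    },
    best_subset = {
      subsets <- utils::combn(seq_along(labels), k)
      score <- apply(subsets, 2, function(j) {
        press_mse(design[, j, drop = FALSE], y)
      })
      if (all(!is.finite(score))) stopf("rank-deficient selected design")
      subsets[, which.min(score)]
    })

  X <- design[, sel, drop = FALSE]
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xi, y)
  if (fit$rank < ncol(X) + 1) stopf("rank-deficient selected design")
  beta <- fit$coefficients
  dfree <- nrow(Xi) - ncol(Xi)
  sigma2 <- sum(fit$residuals^2) / dfree
  se <- sqrt(diag(chol2inv(chol(crossprod(Xi)))) * sigma2)
  pred_log <- y - fit$residuals
  r2_log <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  dose <- if ("dose_mg_per_day" %in% labels) design[, "dose_mg_per_day"] else
    rep(1, nrow(design))
  calc_auc <- exp(pred_log) * dose
  actual_auc <- standard_auc * dose
  r2_auc <- 1 - sum((actual_auc - calc_auc)^2) /
    sum((actual_auc - mean(actual_auc))^2)

  structure(
    list(b0 = unname(beta[1]),
         coefficients = stats::setNames(beta[-1], labels[sel]),
         coef_se = stats::setNames(se[-1], labels[sel]),
         b0_se = unname(se[1]),
         selected_labels = labels[sel],
         training_quartiles = unname(stats::quantile(calc_auc,
                                                     c(0.25, 0.75), type = 7)),
         fit_diagnostics = list(r_squared_log = r2_log,
                                r_squared_auc = r2_auc,
                                n_train = nrow(design)),
         k = k, selection_method = selection_method,
         training_hash = content_hash(list(design, standard_auc))),
    class = "fitted_auc_model")
}

#' @export
print.fitted_auc_model <- function(x, ...) {
  cat(sprintf(
    "Exponential standard-AUC model: %d covariates (%s), n = %d\n",
    length(x$selected_labels), x$selection_method,
    x$fit_diagnostics$n_train))
  cat(sprintf("  b0 = %.4f\n", x$b0))
  for (lab in x$selected_labels) {
    cat(sprintf("  %-28s %+.4f\n", lab, x$coefficients[[lab]]))
  }
  cat(sprintf("  in-sample R2 (log scale) = %.3f\n",
              x$fit_diagnostics$r_squared_log))
  cat(sprintf("  training calculated-AUC quartiles: %.1f / %.1f ng.hr/ml\n",
              x$training_quartiles[1], x$training_quartiles[2]))
  invisible(x)
}

#' Predict standard AUC for a covariate vector
#'
#' `y = exp(b0 + sum b_i x_i)` over the model's selected covariates; strictly
#' positive by the exponential link.
#'
#' @param model a `fitted_auc_model`.
#' @param design_vector named numeric vector (or one design-matrix row)
#'   supplying every selected label.
#' @return Predicted standard AUC (ng.hr/ml per mg/day).
#' @export
predict_standard_auc <- function(model, design_vector) {
  missing <- setdiff(model$selected_labels, names(design_vector))
  if (length(missing)) {
    stopf("design vector lacks covariate(s): %s", paste(missing, collapse = ", "))
  }
  exp(model$b0 + sum(model$coefficients *
                       design_vector[model$selected_labels]))
}

#' Predict calculated AUC (standard AUC times dose)
#'
#' The pre-treatment estimate of a patient's interval exposure at a candidate
#' daily dose.
#'
#' @inheritParams predict_standard_auc
#' @param dose daily dose in mg/day, within `[2, 20]`.
#' @return Calculated AUC in ng.hr/ml.
#' @export
predict_calculated_auc <- function(model, design_vector, dose) {
  if (!is.numeric(dose) || dose < 2 || dose > 20) {
    stopf("dose must lie in [2, 20] mg/day")
  }
  predict_standard_auc(model, design_vector) * dose
}

#' Categorize a calculated AUC against the training quartiles
#'
#' Quartiles are frozen from the training cohort's calculated AUC (type-7
#' linear interpolation between order statistics) and never refit at
#' prediction time. Boundaries are inclusive: at or below the 25th percentile
#' is `"low"`, at or above the 75th is `"high"`, otherwise `"mid"`.
#'
#' @param calculated_auc calculated AUC in ng.hr/ml (vectorized).
#' @param model a `fitted_auc_model` carrying `training_quartiles`.
#' @return Character vector in `{"low", "mid", "high"}`.
#' @export
categorize_auc <- function(calculated_auc, model) {
  q <- model$training_quartiles
  ifelse(calculated_auc <= q[1], "low",
         ifelse(calculated_auc >= q[2], "high", "mid"))
}

#' Dose advice for an exposure category
#'
#' Patients predicted into the low-exposure quartile are candidates for a
#' higher initial dose (exposure tracks response); the high quartile for a
#' lower dose (exposure tracks on-target toxicity); mid maintains the
#' standard start. Advisory only — no mg mapping is prescribed.
#'
#' @param category `"low"`, `"mid"` or `"high"` (vectorized).
#' @return Character vector in `{"consider_increase", "maintain",
#'   "consider_decrease"}`.
#' @export
recommend_dose_action <- function(category) {
  out <- c(low = "consider_increase", mid = "maintain",
           high = "consider_decrease")[category]
  if (anyNA(out)) stopf("unknown exposure category")
  unname(out)
}

#' Calibration of calculated against actual AUC
#'
#' Simple linear regression of actual on calculated AUC (R-squared and slope
#' p-value) plus a Kruskal-Wallis test of actual AUC across the calculated-AUC
#' quartile categories.
#'
#' @param calculated,actual paired AUC vectors, length >= 3.
#' @param model optional `fitted_auc_model`; when supplied, categories come
#'   from its frozen training quartiles, otherwise from the calculated
#'   vector's own quartiles.
#' @return List: `r_squared`, `regression_p`, `kw_p_by_category`, `n`.
#' @export
evaluate_calibration <- function(calculated, actual, model = NULL) {
  if (length(calculated) != length(actual)) stopf("length mismatch")
  if (length(calculated) < 3) stopf("need at least 3 paired values")
  reg <- simple_linear_regression(calculated, actual)
  cats <- if (!is.null(model)) categorize_auc(calculated, model) else {
    q <- stats::quantile(calculated, c(0.25, 0.75), type = 7)
    ifelse(calculated <= q[1], "low", ifelse(calculated >= q[2], "high", "mid"))
  }
  kw_p <- if (length(unique(cats)) < 2) NA_real_ else
    kruskal_wallis(split(actual, cats))$p_value
  list(r_squared = reg$r_squared, regression_p = reg$p_value,
       kw_p_by_category = kw_p, n = length(actual))
}

#' Serialize a fitted model to JSON
#'
#' Stores labels, coefficients, quartiles, `k`, the selection method and the
#' training-input content hash, so a frozen model can be applied
#' prospectively.
#'
#' @param model a `fitted_auc_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_auc_model <- function(model, path) {
  m <- unclass(model)
  # named numeric vectors serialize as JSON objects, not nameless arrays
  m$coefficients <- as.list(m$coefficients)
  m$coef_se <- as.list(m$coef_se)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path path written by [write_auc_model()].
#' @return A `fitted_auc_model`.
#' @export
read_auc_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$coefficients <- unlist(m$coefficients)
  m$coef_se <- unlist(m$coef_se)
  structure(m, class = "fitted_auc_model")
}
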