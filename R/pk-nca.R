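#' Construct a concentration-time profile
#'
#' One patient's sampled plasma concentrations over a dosing interval.
#' Times must be strictly increasing and start at 0 (the pre-dose sample);
#' concentrations are non-negative ng/ml. Negative concentrations are an input
#' error, never clipped.
#'
#' @param patient_id identifier.
#' @param times sampling times in hours.
#' @param concentrations plasma concentrations in ng/ml.
#' @param dose_mg_per_day daily dose in mg/day, within `[2, 20]`.
#' @return A `concentration_profile` object.
#' @export
concentration_profile <- function(patient_id, times, concentrations,
                                  dose_mg_per_day) {
  if (length(times) != length(concentrations)) {
    stopf("times and concentrations differ in length for %s", patient_id)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stopf("times must be strictly increasing for %s", patient_id)
  }
  if (any(concentrations < 0)) {
    stopf("negative concentration for %s", patient_id)
  }
  if (!is.null(dose_mg_per_day) && !is.na(dose_mg_per_day) &&
      (dose_mg_per_day < 2 || dose_mg_per_day > 20)) {
    stopf("dose for %s outside [2, 20] mg/day", patient_id)
  }
  structure(list(patient_id = patient_id, times = as.numeric(times),
                 concentrations = as.numeric(concentrations),
                 dose_mg_per_day = dose_mg_per_day),
            class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("Concentration profile %s (%g mg/day): %d samples over %g hr\n",
              x$patient_id, x$dose_mg_per_day, length(x$times),
              max(x$times)))
  invisible(x)
}

#' Linear trapezoidal AUC over the observed span
#'
#' Computes `sum((t[i+1] - t[i]) * (C[i] + C[i+1]) / 2)` over consecutive
#' samples — the standard model-free interval AUC for sparse sampling.
#'
#' @param profile a [concentration_profile()] (or any list with `times` and
#'   `concentrations`).
#' @return AUC in ng.hr/ml.
#' @examples
#' p <- concentration_profile("P1", c(0, 1, 2, 3, 4, 8, 12),
#'                            rep(10, 7), 10)
#' compute_auc_trapezoid(p)  # 120
#' @export
compute_auc_trapezoid <- function(profile) {
  t <- profile$times; c_ <- profile$concentrations
  if (length(t) < 2) stopf("need at least 2 samples to integrate")
  if (is.unsorted(t, strictly = TRUE)) stopf("times must be strictly increasing")
  if (any(c_ < 0)) stopf("negative concentration")
  sum(diff(t) * (utils::head(c_, -1) + utils::tail(c_, -1)) / 2)
}

#' Non-compartmental PK parameters for one profile
#'
#' Derives the interval AUC (linear trapezoid), total clearance, C-max, the
#' pre-dose concentration C-0hr and the end-of-interval trough. Clearance is
#' dose over AUC with unit conversion (mg -> ng, ml -> L):
#' `CL (L/hr) = dose_ng / AUC / 1e3`. The dose basis defaults to the
#' per-interval dose (daily / 2) because the AUC spans one 12-hr twice-daily
#' interval; `dose_basis = "daily"` uses the full daily dose.
#'
#' Profiles with fewer than 3 samples or no time-0 sample are non-evaluable
#' (`evaluable = FALSE`, parameters `NA`) rather than an error, as is a
#' zero AUC (clearance undefined).
#'
#' @param profile a [concentration_profile()].
#' @param dose_basis `"interval"` (default) or `"daily"`.
#' @return List of class `pk_parameters`: `patient_id`, `auc_0_12`,
#'   `total_clearance`, `c_max`, `c_0hr`, `trough`, `evaluable`, `dose_basis`.
#' @examples
#' p <- concentration_profile("P1", c(0, 6, 12), c(10, 10, 10), 10)
#' compute_pk_params(p)$total_clearance  # 5 mg / 120 ng.hr/ml -> 41.7 L/hr
#' @export
compute_pk_params <- function(profile, dose_basis = c("interval", "daily")) {
  dose_basis <- match.arg(dose_basis)
  na_out <- structure(
    list(patient_id = profile$patient_id, auc_0_12 = NA_real_,
         total_clearance = NA_real_, c_max = NA_real_, c_0hr = NA_real_,
         trough = NA_real_, evaluable = FALSE, dose_basis = dose_basis),
    class = "pk_parameters")
  if (length(profile$times) < 3 || profile$times[1] != 0) return(na_out)
  auc <- compute_auc_trapezoid(profile)
  dose_mg <- if (dose_basis == "interval") profile$dose_mg_per_day / 2 else
    profile$dose_mg_per_day
  cl <- if (auc > 0) dose_mg * 1e6 / auc / 1e3 else NA_real_
  structure(
    list(patient_id = profile$patient_id, auc_0_12 = auc,
         total_clearance = cl,
         c_max = max(profile$concentrations),
         c_0hr = profile$concentrations[1],
         trough = profile$concentrations[length(profile$concentrations)],
         evaluable = auc > 0, dose_basis = dose_basis),
    class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf(
    "PK parameters %s: AUC0-12 %.1f ng.hr/ml, CL %.1f L/hr (%s dose), Cmax %.1f, C0hr %.1f, trough %.1f\n",
    x$patient_id, x$auc_0_12, x$total_clearance, x$dose_basis, x$c_max,
    x$c_0hr, x$trough))
  invisible(x)
}

#' NCA over a set of profiles
#'
#' @param profiles list of [concentration_profile()].
#' @param dose_basis passed to [compute_pk_params()].
#' @return Data frame, one row per patient, columns as in `pk_parameters`.
#' @export
compute_pk_table <- function(profiles, dose_basis = c("interval", "daily")) {
  dose_basis <- match.arg(dose_basis)
  rows <- lapply(profiles, function(p) {
    as.data.frame(unclass(compute_pk_params(p, dose_basis)),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median and range summary of PK parameters
#'
#' Reproduces the shape of a baseline PK table: per-parameter median, minimum
#' and maximum over evaluable patients.
#'
#' @param pk_table data frame from [compute_pk_table()].
#' @return Data frame with columns `parameter`, `median`, `min`, `max`, `n`.
#' @export
summarize_pk <- function(pk_table) {
  if (nrow(pk_table) == 0) stopf("empty PK table")
  keep <- pk_table[pk_table$evaluable, , drop = FALSE]
  if (nrow(keep) == 0) stopf("no evaluable patients")
  params <- c("auc_0_12", "total_clearance", "c_max", "c_0hr", "trough")
  do.call(rbind, lapply(params, function(p) {
    v <- keep[[p]]
    data.frame(parameter = p, median = stats::median(v), min = min(v),
               max = max(v), n = length(v), stringsAsFactors = FALSE)
  }))
}
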