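#' Run the full pharmacogenetics-AUC pipeline on a synthetic cohort
#'
#' Orchestrates every stage end to end: simulate (or ingest) a cohort,
#' non-compartmental analysis of the concentration profiles, design-matrix
#' construction, model fitting on the training split, prediction on the
#' validation split, calibration evaluation, a trend scan over the panel loci,
#' and the efficacy / adverse-event tables. All artifacts are written under
#' `out_dir` as headered CSV (data), JSON (model, manifest); each stage logs
#' one INFO line to stderr with its parameter echo. Any stage failure aborts
#' with the failing stage named and leaves a `FAILED` marker next to the
#' partial outputs.
#'
#' @param config a [cohort_config()]; its `seed` drives every random stream.
#' @param out_dir run directory (created if needed).
#' @param k,selection_method passed to [fit_exponential_model()].
#' @param dose_basis passed to [compute_pk_table()].
#' @return Invisibly, the manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, k = 8,
                         selection_method = "forward_loo",
                         dose_basis = "interval") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  t_iso <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  stage <- function(name, expr) {
    message(sprintf("INFO [%s] starting", name))
    res <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("FAILED at stage %s: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    stages[[name]] <<- "PASSED"
    res
  }

  cohort <- stage("simulate", {
    message(sprintf("INFO [simulate] n = %d + %d, seed = %d",
                    config$n_train, config$n_validation, config$seed))
    ch <- generate_cohort(config)
    write_cohort(ch, out_dir)
    ch
  })

  pk <- stage("nca", {
    message(sprintf("INFO [nca] dose basis = %s", dose_basis))
    tab <- compute_pk_table(cohort$profiles, dose_basis)
    utils::write.csv(tab, file.path(out_dir, "pk_params.csv"),
                     row.names = FALSE, quote = FALSE)
    tab
  })

  design <- NULL
  model <- stage("fit", {
    message(sprintf("INFO [fit] k = %d, selection = %s", k, selection_method))
    # the stage expression evaluates in this function's frame, so this
    # assignment updates the local `design` used by later stages
    design <- build_design_matrix(
      cohort$genotypes, cohort$truth[, c("patient_id", "dose_mg_per_day")],
      config$loci)
    train_ids <- cohort$truth$patient_id[cohort$truth$split == "training"]
    idx <- rownames(design) %in% train_ids
    std_auc <- pk$auc_0_12[match(rownames(design)[idx], pk$patient_id)] /
      cohort$truth$dose_mg_per_day[match(rownames(design)[idx],
                                         cohort$truth$patient_id)]
    m <- fit_exponential_model(design[idx, , drop = FALSE], std_auc, k = k,
                               selection_method = selection_method)
    write_auc_model(m, file.path(out_dir, "model.json"))
    m
  })

  predictions <- stage("predict", {
    dose <- cohort$truth$dose_mg_per_day[match(rownames(design),
                                               cohort$truth$patient_id)]
    calc <- vapply(seq_len(nrow(design)), function(i) {
      predict_calculated_auc(model, design[i, ], dose[i])
    }, numeric(1))
    cat_v <- categorize_auc(calc, model)
    out <- data.frame(
      patient_id = rownames(design),
      split = cohort$truth$split[match(rownames(design),
                                       cohort$truth$patient_id)],
      dose_mg_per_day = dose,
      calculated_auc = calc,
      actual_auc = pk$auc_0_12[match(rownames(design), pk$patient_id)],
      category = cat_v,
      action = recommend_dose_action(cat_v),
      stringsAsFactors = FALSE)
    utils::write.csv(out, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE, quote = FALSE)
    out
  })

  calibration <- stage("evaluate", {
    ev <- lapply(split(predictions, predictions$split), function(d) {
      evaluate_calibration(d$calculated_auc, d$actual_auc, model)
    })
    message(sprintf("INFO [evaluate] training R2 = %.3f, validation R2 = %.3f",
                    ev$training$r_squared, ev$validation$r_squared))
    ev
  })

  scan <- stage("scan", {
    wide <- genotype_wide(cohort$genotypes)
    auc <- pk$auc_0_12[match(rownames(wide), pk$patient_id)]
    sc <- trend_scan(wide, auc)
    utils::write.csv(sc, file.path(out_dir, "scan.csv"),
                     row.names = FALSE, quote = FALSE)
    sc
  })

  report <- stage("report", {
    resp <- best_response_table(cohort$outcomes)
    ae <- ae_table(cohort$outcomes)
    utils::write.csv(resp, file.path(out_dir, "best_response.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(ae, file.path(out_dir, "adverse_events.csv"),
                     row.names = FALSE, quote = FALSE)
    list(best_response = resp, adverse_events = ae)
  })

  manifest <- list(
    created = t_iso(),
    seed = config$seed,
    n_train = config$n_train, n_validation = config$n_validation,
    k = k, selection_method = selection_method, dose_basis = dose_basis,
    stages = stages,
    calibration = calibration,
    selected_labels = model$selected_labels,
    hashes = list(
      config = content_hash(unclass(config)),
      predictions = content_hash(predictions),
      model = model$training_hash))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("INFO [pipeline] all stages PASSED")
  invisible(manifest)
}

#' Widen a long genotype table to a patient x variant category matrix
#'
#' @param genotypes long table (`patient_id`, `rsid`, `category`).
#' @return Character matrix, patients as rows, rsids as columns.
#' @export
genotype_wide <- function(genotypes) {
  ids <- unique(genotypes$patient_id)
  rsids <- unique(genotypes$rsid)
  m <- matrix(NA_character_, length(ids), length(rsids),
              dimnames = list(ids, rsids))
  m[cbind(match(genotypes$patient_id, ids),
          match(genotypes$rsid, rsids))] <- genotypes$category
  m
}
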