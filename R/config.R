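#' Read a cohort configuration from JSON or YAML
#'
#' The document mirrors [cohort_config()]: top-level scalar fields by name, a
#' `loci` array of objects with the [locus_definition()] fields, `dose_policy`
#' as an object mapping dose (mg/day) to probability, and `outcome_links` as
#' an object of `[intercept, slope]` pairs (scalar for `hypertension`).
#' Omitted fields keep their defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- list()
  for (f in c("n_train", "n_validation", "intercept_b0", "effect_dose",
              "residual_sd", "sampling_times", "measurement_cv", "ka_range",
              "ke_range", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$dose_policy)) {
    args$dose_policy <- unlist(raw$dose_policy)
  }
  if (!is.null(raw$loci)) {
    loci_raw <- raw$loci
    if (is.data.frame(loci_raw)) {
      loci_raw <- lapply(seq_len(nrow(loci_raw)), function(i) {
        as.list(loci_raw[i, ])
      })
    }
    args$loci <- lapply(loci_raw, function(l) {
      locus_definition(l$rsid, l$gene_label, l$variant_allele_frequency,
                       l$effect_hetero %||% 0, l$effect_variant %||% 0)
    })
  }
  if (!is.null(raw$outcome_links)) {
    ol <- lapply(raw$outcome_links, unlist)
    args$outcome_links <- do.call(outcome_links, ol)
  }
  do.call(cohort_config, args)
}
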