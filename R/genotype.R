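#' Dummy-code a three-way genotype category
#'
#' Each locus contributes two indicator covariates: wild-type is the reference
#' `(0, 0)`, heterozygous is `(1, 0)`, homozygous variant is `(0, 1)`.
#'
#' @param category one of `"wild"`, `"hetero"`, `"variant"`.
#' @return Integer vector of length 2.
#' @export
encode_genotype <- function(category) {
  switch(as.character(category),
         wild = c(0L, 0L), hetero = c(1L, 0L), variant = c(0L, 1L),
         stopf("unknown genotype category '%s'", category))
}

#' Invert the genotype dummy coding
#'
#' @param pair integer vector of length 2; one of `(0,0)`, `(1,0)`, `(0,1)`.
#' @return The genotype category string.
#' @export
decode_genotype <- function(pair) {
  if (length(pair) != 2) stopf("indicator pair must have length 2")
  key <- paste(pair, collapse = ",")
  switch(key, "0,0" = "wild", "1,0" = "hetero", "0,1" = "variant",
         stopf("inadmissible indicator pair (%s)", key))
}

#' Candidate covariate labels for a panel
#'
#' Two indicator labels per locus in panel order (`<gene>_<rsid>_het`,
#' `<gene>_<rsid>_var`), then `dose_mg_per_day` — the 13 candidate covariates
#' for the default six-locus panel.
#'
#' @param loci list of [locus_definition()].
#' @return Character vector of length `2 * length(loci) + 1`.
#' @export
candidate_labels <- function(loci = default_panel()) {
  lab <- unlist(lapply(loci, function(l) {
    paste(gsub("[^A-Za-z0-9]", "", l$gene_label), l$rsid, c("het", "var"),
          sep = "_")
  }))
  c(lab, "dose_mg_per_day")
}

#' Build the candidate design matrix
#'
#' One row per patient: the six dummy-coded loci in panel order followed by
#' the untransformed daily dose (mg/day) — 13 columns for the default panel.
#' Column order is fixed by the panel listing so coefficient labels are
#' reproducible. Patients missing a call at any panel locus are dropped and
#' reported via the `non_evaluable` attribute; a missing dose is an error.
#'
#' @param genotypes long table (`patient_id`, `rsid`, `category`).
#' @param doses data frame (`patient_id`, `dose_mg_per_day`) or named vector.
#' @param loci list of [locus_definition()]; default [default_panel()].
#' @return Numeric matrix with patient ids as row names, candidate labels as
#'   column names, and attribute `non_evaluable` (character vector of dropped
#'   patient ids).
#' @export
build_design_matrix <- function(genotypes, doses, loci = default_panel()) {
  if (is.data.frame(doses)) {
    doses <- stats::setNames(doses$dose_mg_per_day, doses$patient_id)
  }
  ids <- unique(genotypes$patient_id)
  if (any(!ids %in% names(doses)) || anyNA(doses[as.character(ids)])) {
    stopf("missing dose for patient(s): %s",
          paste(setdiff(ids, names(doses)), collapse = ", "))
  }
  rsids <- vapply(loci, `[[`, character(1), "rsid")
  rows <- lapply(ids, function(id) {
    g <- genotypes[genotypes$patient_id == id, ]
    cats <- g$category[match(rsids, g$rsid)]
    if (anyNA(cats) || any(cats == "missing")) return(NULL)
    c(unlist(lapply(cats, encode_genotype)), unname(doses[[as.character(id)]]))
  })
  ok <- !vapply(rows, is.null, logical(1))
  x <- do.call(rbind, rows[ok])
  rownames(x) <- ids[ok]
  colnames(x) <- candidate_labels(loci)
  attr(x, "non_evaluable") <- as.character(ids[!ok])
  x
}

#' Read panel genotypes from a VCF
#'
#' Matches panel rsIDs against the VCF ID column and collapses diploid GT
#' fields to the three-way category: `0/0` is wild, exactly one non-reference
#' allele is hetero, and any two non-reference alleles — including distinct
#' alternates at multi-allelic sites such as ABCB1 2677G>T/A, e.g. `1/2` —
#' count as variant. Missing genotypes (`./.`) and panel rsIDs absent from the
#' VCF become `"missing"` calls.
#'
#' @param vcf_path path to a VCF file.
#' @param loci list of [locus_definition()]; default [default_panel()].
#' @return Long data frame (`patient_id`, `rsid`, `category`) covering every
#'   sample x panel locus; `category` includes `"missing"` where uncalled.
#' @export
read_genotypes_vcf <- function(vcf_path, loci = default_panel()) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rsids <- vapply(loci, `[[`, character(1), "rsid")
  site_ids <- vcf@fix[, "ID"]
  samples <- colnames(gt)
  out <- lapply(rsids, function(rs) {
    i <- match(rs, site_ids)
    cat_v <- if (is.na(i)) rep("missing", length(samples)) else
      vapply(gt[i, ], classify_gt, character(1))
    data.frame(patient_id = samples, rsid = rs, category = cat_v,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Diploid GT string -> category; any non-reference allele counts toward the
# variant-allele dose, so "1/2" at a triallelic site is homozygous variant.
classify_gt <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) != 2 || !all(grepl("^[0-9.]+$", alleles))) {
    stopf("malformed GT field '%s'", gt)
  }
  if (any(alleles == ".")) return("missing")
  n_alt <- sum(alleles != "0")
  c("wild", "hetero", "variant")[n_alt + 1]
}

#' Concordance rate between two genotype call sets
#'
#' Fraction of shared patient x locus keys with identical category — the
#' statistic used to compare genotyping platforms (e.g. Sanger sequencing
#' versus DNA microarray).
#'
#' @param calls_a,calls_b long genotype tables (`patient_id`, `rsid`,
#'   `category`) covering the same keys.
#' @return Fraction in `[0, 1]`.
#' @export
concordance_rate <- function(calls_a, calls_b) {
  key_a <- paste(calls_a$patient_id, calls_a$rsid, sep = "\r")
  key_b <- paste(calls_b$patient_id, calls_b$rsid, sep = "\r")
  if (!setequal(key_a, key_b)) stopf("call sets cover different keys")
  m <- match(key_a, key_b)
  mean(calls_a$category == calls_b$category[m])
}
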