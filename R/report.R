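RESPONSE_LEVELS <- c("CR", "PR", "SD", "PD", "NE")

#' Best-response tabulation
#'
#' Counts and one-decimal percentages per RECIST best-response category
#' (complete response, partial response, stable disease, progressive disease,
#' not evaluated), plus the objective response rate (CR + PR). Percentages are
#' computed against the full cohort `n` — including non-evaluable patients —
#' and rounded half up to one decimal, so 11 of 44 prints as 25.0.
#'
#' @param best_response character vector with one best-response value per
#'   patient (among `CR, PR, SD, PD, NE`), or an outcomes data frame carrying
#'   `patient_id` and `best_response` columns.
#' @param n cohort size; defaults to the number of patients supplied, and must
#'   match it when given.
#' @return Data frame (`category`, `count`, `percent`) with rows for the five
#'   categories and a final `ORR` row.
#' @export
best_response_table <- function(best_response, n = NULL) {
  if (is.data.frame(best_response)) {
    d <- unique(best_response[, c("patient_id", "best_response")])
    if (anyDuplicated(d$patient_id)) {
      stopf("conflicting best_response for a patient")
    }
    best_response <- d$best_response
  }
  if (!all(best_response %in% RESPONSE_LEVELS)) {
    stopf("best_response values must be among %s",
          paste(RESPONSE_LEVELS, collapse = ", "))
  }
  if (is.null(n)) n <- length(best_response)
  if (n != length(best_response)) {
    stopf("n (%d) does not match the %d response records", n,
          length(best_response))
  }
  counts <- vapply(RESPONSE_LEVELS, function(l) sum(best_response == l),
                   integer(1))
  counts <- c(counts, ORR = unname(counts["CR"] + counts["PR"]))
  data.frame(category = names(counts), count = unname(counts),
             percent = round_half_up(100 * unname(counts) / n, 1),
             stringsAsFactors = FALSE)
}

#' Adverse-event grade tabulation
#'
#' Per adverse event, counts and one-decimal percentages (against the full
#' cohort `n`, rounded half up) of grade 2 and grade 3 events, tabulated
#' separately.
#'
#' @param outcomes long data frame with `patient_id`, `ae`, `grade`
#'   (grades in `0..3`).
#' @param n cohort size; defaults to the number of distinct patients.
#' @return Data frame: `ae`, `g2_count`, `g2_percent`, `g3_count`,
#'   `g3_percent`.
#' @export
ae_table <- function(outcomes, n = NULL) {
  if (!all(outcomes$grade %in% 0:3)) stopf("AE grades must be in 0..3")
  if (is.null(n)) n <- length(unique(outcomes$patient_id))
  aes <- unique(outcomes$ae)
  do.call(rbind, lapply(aes, function(a) {
    rows <- outcomes[outcomes$ae == a, ]
    g2 <- sum(rows$grade == 2); g3 <- sum(rows$grade == 3)
    data.frame(ae = a, g2_count = g2,
               g2_percent = round_half_up(100 * g2 / n, 1),
               g3_count = g3,
               g3_percent = round_half_up(100 * g3 / n, 1),
               stringsAsFactors = FALSE)
  }))
}
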