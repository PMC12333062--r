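#' Published infusion-reaction report counts for 25 antitumor antibodies
#'
#' Reference counts extracted from a JADER analysis (April 2004 to
#' February 2022) of infusion reactions — MedDRA PTs 10051792
#' (infusion-related reaction) and 10052015 (cytokine release syndrome) —
#' across 25 intravenous antitumor antibodies. One row per antibody:
#' `ir_cases` (event-positive cases listing the drug as suspected),
#' `reports` (all such cases), the curated `adcc_status` and
#' `antibody_type` attributes, the molecular `target`, and the published
#' ROR, 95% CI and signal flag (`*_printed` columns) for cross-checking.
#'
#' @return A tibble with 25 rows.
#' @seealso [jader_ir_reference()] for the universe totals these counts
#'   were published against.
#' @export
jader_ir_counts <- function() {
  path <- system.file("extdata", "jader_ir_counts.csv", package = "rorsignal",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    drug_name = "c", antibody_type = "c", ir_cases = "i", reports = "i",
    adcc_status = "c", target = "c", ror_printed = "d",
    ci_low_printed = "d", ci_high_printed = "d", signal_printed = "l"
  ), progress = FALSE)
}

#' Universe totals and event definition of the bundled reference counts
#'
#' The analysis universe behind [jader_ir_counts()]: 97,567 cases of
#' suspected intravenous biologics, of which 1,762 reported an infusion
#' reaction.
#'
#' @return A list with `n_total`, `n_event`, and `event_pt_codes`.
#' @export
jader_ir_reference <- function() {
  list(n_total = 97567L,
       n_event = 1762L,
       event_pt_codes = c("10051792", "10052015"))
}

#' Attribute map of the bundled reference antibodies
#'
#' @return A tibble with columns `drug_name`, `adcc_status`,
#'   `antibody_type`, `target` for the 25 reference antibodies.
#' @export
jader_attribute_map <- function() {
  jader_ir_counts()[, c("drug_name", "adcc_status", "antibody_type", "target")]
}
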