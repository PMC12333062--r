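#' Read a drug attribute map
#'
#' Curated per-drug attributes used for stratified comparison: ADCC status
#' (does the antibody recruit effector cells for target lysis) and antibody
#' type (degree of humanization). These assignments come from package
#' inserts and the literature; they are data, not computation.
#'
#' @param path CSV with columns `drug_name`, `adcc_status`
#'   (`positive`/`negative`), `antibody_type`
#'   (`mouse`/`chimeric`/`humanized`/`fully_human`) and optionally
#'   `target`.
#' @return A tibble; drug names normalized, vocabularies validated.
#' @export
read_attribute_map <- function(path) {
  map <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("drug_name", "adcc_status", "antibody_type")
  absent <- setdiff(required, names(map))
  if (length(absent)) {
    stop("attribute map is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  map$drug_name <- normalize_drug_name(map$drug_name)
  if (anyDuplicated(map$drug_name)) {
    stop("attribute map lists a drug more than once", call. = FALSE)
  }
  if (!all(map$adcc_status %in% c("positive", "negative"))) {
    stop("adcc_status must be 'positive' or 'negative'", call. = FALSE)
  }
  if (!all(map$antibody_type %in% antibody_type_levels)) {
    stop("antibody_type must be one of: ",
         paste(antibody_type_levels, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(map)
}

antibody_type_levels <- c("mouse", "chimeric", "humanized", "fully_human")

#' Pooled 2x2 table for a drug group
#'
#' Sums the member drugs' event counts and report counts and contrasts the
#' pooled group against the rest of the universe. Pooling is additive over
#' drugs (a case suspected of two member drugs contributes once per drug),
#' matching the convention of published group tables whose totals are the
#' column sums of the per-drug rows.
#'
#' @param x An `analysis_universe`, or a counts data frame with columns
#'   `drug_name`, `ir_cases`, `reports`.
#' @param drugs Character vector naming the member drugs (nonempty).
#' @param ... Passed to methods; the counts method requires `n_total` and
#'   `n_event`.
#' @return A `contingency_2x2`.
#' @export
pooled_contingency <- function(x, drugs, ...) UseMethod("pooled_contingency")

#' @rdname pooled_contingency
#' @export
pooled_contingency.analysis_universe <- function(x, drugs, ...) {
  stopifnot(length(drugs) >= 1)
  per_drug <- lapply(drugs, function(d) build_contingency(x, d))
  a <- sum(vapply(per_drug, `[[`, integer(1), "a"))
  ab <- sum(vapply(per_drug, function(t) t$a + t$b, integer(1)))
  contingency_from_counts(a, ab, x$n_total, x$n_event)
}

#' @rdname pooled_contingency
#' @param n_total,n_event Universe totals for the counts method.
#' @export
pooled_contingency.data.frame <- function(x, drugs, n_total, n_event, ...) {
  stopifnot(length(drugs) >= 1)
  missing_drugs <- setdiff(drugs, x$drug_name)
  if (length(missing_drugs)) {
    stop("drug(s) absent from counts table: ",
         paste(missing_drugs, collapse = ", "), call. = FALSE)
  }
  sub <- x[x$drug_name %in% drugs, ]
  contingency_from_counts(sum(sub$ir_cases), sum(sub$reports),
                          n_total, n_event)
}

#' Pooled group disproportionality by attribute level
#'
#' Computes one pooled ROR per level of a stratifying attribute (e.g. the
#' ADCC-positive and ADCC-negative groups).
#'
#' @param x Universe or counts table, as for [pooled_contingency()].
#' @param attribute_map Tibble from [read_attribute_map()].
#' @param attribute Column of the map to stratify by (default
#'   `"adcc_status"`).
#' @param ... Passed to [pooled_contingency()] methods (`n_total`,
#'   `n_event` for the counts method) .
#' @inheritParams analyze_universe
#' @return A tibble with one row per attribute level: counts, pooled
#'   `ror`, `ci_low`, `ci_high`, `signal`.
#' @export
pooled_by_attribute <- function(x, attribute_map, attribute = "adcc_status",
                                conf = 0.95, continuity = FALSE, ...) {
  levels_ <- attribute_levels(attribute_map, attribute)
  rows <- lapply(levels_, function(lv) {
    drugs <- attribute_map$drug_name[attribute_map[[attribute]] == lv]
    tb <- pooled_contingency(x, drugs, ...)
    est <- ror_with_ci(tb, conf = conf, continuity = continuity)
    tibble::tibble(level = lv, n_drugs = length(drugs),
                   a = tb$a, b = tb$b, c = tb$c, d = tb$d,
                   reports = tb$a + tb$b,
                   ror = est$ror, ci_low = est$ci_low, ci_high = est$ci_high,
                   signal = signal_flag(tb, est$ci_low))
  })
  dplyr::bind_rows(rows)
}

attribute_levels <- function(attribute_map, attribute) {
  if (!attribute %in% names(attribute_map)) {
    stop("attribute map has no column '", attribute, "'", call. = FALSE)
  }
  if (attribute == "adcc_status") return(c("positive", "negative"))
  if (attribute == "antibody_type") {
    return(intersect(antibody_type_levels, unique(attribute_map[[attribute]])))
  }
  unique(attribute_map[[attribute]])
}

#' Cross-tabulate signal detection against a drug attribute
#'
#' Builds the 2xK detection table (signal detected / not detected by
#' attribute level) used to compare how often the disproportionality rule
#' fires across drug groups.
#'
#' @param results Signal-result tibble from [analyze_universe()] or
#'   [analyze_counts()].
#' @param attribute_map Tibble from [read_attribute_map()].
#' @param attribute Stratifying column (default `"adcc_status"`).
#' @return An integer matrix with rows `detected`, `not_detected` and one
#'   column per attribute level. A drug missing from the map is a hard
#'   error naming it.
#' @export
detection_table <- function(results, attribute_map, attribute = "adcc_status") {
  if (nrow(results) == 0) {
    return(matrix(integer(0), nrow = 2, ncol = 0,
                  dimnames = list(c("detected", "not_detected"), NULL)))
  }
  missing_drugs <- setdiff(results$drug_name, attribute_map$drug_name)
  if (length(missing_drugs)) {
    stop("drug(s) missing from attribute map: ",
         paste(missing_drugs, collapse = ", "), call. = FALSE)
  }
  levels_ <- attribute_levels(attribute_map, attribute)
  lv <- attribute_map[[attribute]][match(results$drug_name,
                                         attribute_map$drug_name)]
  det <- vapply(levels_, function(l) sum(results$signal & lv == l), integer(1))
  nod <- vapply(levels_, function(l) sum(!results$signal & lv == l), integer(1))
  matrix(c(det, nod), nrow = 2, byrow = TRUE,
         dimnames = list(c("detected", "not_detected"), levels_))
}

#' Exact test for a 2xK detection table
#'
#' Freeman–Halton extension of Fisher's exact test: the p-value is the sum
#' of the probabilities, under the margin-fixed multivariate hypergeometric
#' null, of every 2xK table whose point probability does not exceed the
#' observed table's. For K = 2 it coincides with [fisher_exact_2x2()]. A
#' table with an all-zero row or column gives p = 1. Exact enumeration is
#' refused above a configurable grand-total cap rather than silently
#' approximated.
#'
#' @param table 2xK integer matrix (e.g. from [detection_table()]).
#' @param max_total Largest grand total accepted for exact computation
#'   (default 2000).
#' @return The exact two-sided p-value.
#' @export
fisher_exact_2xk <- function(table, max_total = 2000) {
  stopifnot(is.matrix(table), nrow(table) == 2, ncol(table) >= 2,
            all(table >= 0))
  if (any(rowSums(table) == 0) || all(colSums(table) == 0)) return(1)
  if (sum(table) > max_total) {
    stop(sprintf(paste0("exact test not computed: grand total %d exceeds the ",
                        "enumeration cap of %d"), sum(table), max_total),
         call. = FALSE)
  }
  table <- table[, colSums(table) > 0, drop = FALSE]
  if (ncol(table) < 2) return(1)
  stats::fisher.test(table, workspace = 2e7)$p.value
}
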