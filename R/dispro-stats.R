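#' Construct a 2x2 disproportionality table
#'
#' The standard pharmacovigilance contingency table for one drug (or drug
#' group) against all other drugs in the analysis universe:
#' `a` = event-positive cases listing the drug, `b` = event-negative cases
#' listing it, `c` = remaining event-positive cases, `d` = remaining
#' event-negative cases.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be nonnegative integers", call. = FALSE)
  }
  cells <- as.integer(round(cells))
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4]),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- as.matrix(x)
  cat("2x2 disproportionality table:\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
         dimnames = list(c("drug", "other"), c("event", "no_event")))
}

#' Build the 2x2 table for one drug against the rest of the universe
#'
#' @param universe An `analysis_universe` from [build_universe()].
#' @param drug Drug name (normalized as by [normalize_drug_name()]).
#' @return A `contingency_2x2`. A drug absent from the universe yields
#'   `a = b = 0` with a warning.
#' @export
build_contingency <- function(universe, drug) {
  stopifnot(inherits(universe, "analysis_universe"))
  ids <- universe$drug_cases$case_id[universe$drug_cases$drug_name == drug]
  if (length(ids) == 0) {
    warning(sprintf("drug '%s' not present in universe; returning empty margin",
                    drug), call. = FALSE)
  }
  flagged <- universe$cases$event_flag[universe$cases$case_id %in% ids]
  a <- sum(flagged)
  b <- length(flagged) - a
  contingency_2x2(a, b, universe$n_event - a,
                  universe$n_total - length(flagged) - (universe$n_event - a))
}

#' Build a 2x2 table from published marginal counts
#'
#' Reconstructs the disproportionality table from the numbers a report
#' table prints: the drug's event-positive case count, the drug's total
#' report count, and the universe totals.
#'
#' @param n_drug_event Event-positive cases listing the drug (`a`).
#' @param n_drug_total All cases listing the drug (`a + b`).
#' @param n_total Cases in the analysis universe.
#' @param n_event Event-positive cases in the universe.
#' @return A `contingency_2x2`.
#' @export
contingency_from_counts <- function(n_drug_event, n_drug_total, n_total, n_event) {
  a <- n_drug_event
  b <- n_drug_total - a
  c <- n_event - a
  contingency_2x2(a, b, c, n_total - n_drug_total - c)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' Point estimate `(a*d)/(b*c)` with the Woolf log-normal interval
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell makes
#' the estimate undefined (reported as `NA` with `undefined = TRUE`) unless
#' the opt-in Haldane–Anscombe continuity correction (+0.5 to every cell)
#' is enabled. No rounding is applied here; round only for display.
#'
#' @param table A `contingency_2x2`.
#' @param conf Confidence level (default 0.95).
#' @param continuity Apply the +0.5 continuity correction to all four
#'   cells? Default `FALSE`.
#' @return A list with `ror`, `ci_low`, `ci_high`, `undefined`.
#' @export
ror_with_ci <- function(table, conf = 0.95, continuity = FALSE) {
  stopifnot(inherits(table, "contingency_2x2"))
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells == 0) && !continuity) {
    return(list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                undefined = TRUE))
  }
  if (continuity) cells <- cells + 0.5
  z <- stats::qnorm((1 + conf) / 2)
  log_ror <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  list(ror = exp(log_ror),
       ci_low = exp(log_ror - z * se),
       ci_high = exp(log_ror + z * se),
       undefined = FALSE)
}

#' Disproportionality signal rule
#'
#' A signal is declared when the lower 95% confidence bound of the ROR is
#' strictly greater than 1 and at least two event cases list the drug. An
#' undefined interval (zero cell) never signals.
#'
#' @param table A `contingency_2x2`.
#' @param ci_low Lower confidence bound from [ror_with_ci()] (may be `NA`).
#' @return `TRUE` or `FALSE`.
#' @export
signal_flag <- function(table, ci_low) {
  stopifnot(inherits(table, "contingency_2x2"))
  !is.na(ci_low) && ci_low > 1 && table$a >= 2
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the small-p-values rule: the sum of hypergeometric
#' point probabilities, over all tables with the observed margins, that do
#' not exceed the probability of the observed table. A zero margin gives
#' p = 1. With very large counts the p-value can fall below the smallest
#' representable double and is reported as 0; downstream volcano handling
#' flags such drugs as excluded rather than plotting infinities.
#'
#' @param table A `contingency_2x2` or a 2x2 integer matrix.
#' @return The two-sided p-value in `[0, 1]`.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- if (inherits(table, "contingency_2x2")) as.matrix(table) else table
  stopifnot(is.matrix(m), all(dim(m) == 2), all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Benjamini–Hochberg p-value adjustment
#'
#' Step-up FDR adjustment across the per-drug exact-test p-values of one
#' analysis run; input order is preserved and adjusted values are capped
#' at 1.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  # exact zeros are admitted: the exact test underflows on very large tables
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Per-drug disproportionality analysis of a universe
#'
#' Runs the full statistics core for each drug in the universe: 2x2 table,
#' ROR with Woolf CI, signal rule, two-sided exact test, and BH adjustment
#' across the drugs analyzed in this run.
#'
#' @param universe An `analysis_universe`.
#' @param drugs Drugs to analyze (default: every drug in the universe).
#' @param conf Confidence level for the CI.
#' @param continuity Continuity-correction flag, see [ror_with_ci()].
#' @return A tibble with one row per drug: counts (`a`, `b`, `c`, `d`,
#'   `reports = a + b`), `ror`, `ci_low`, `ci_high`, `p_value`,
#'   `p_adjusted`, `signal`, `log_ror`, `neg_log10_p`.
#' @export
analyze_universe <- function(universe, drugs = universe_drugs(universe),
                             conf = 0.95, continuity = FALSE) {
  tables <- lapply(drugs, function(d) build_contingency(universe, d))
  signal_results(drugs, tables, conf = conf, continuity = continuity)
}

#' Per-drug disproportionality analysis from published counts
#'
#' Fixture-based entry point: rebuilds each drug's 2x2 from its printed
#' event and report counts against stated universe totals, then applies the
#' same statistics core as [analyze_universe()].
#'
#' @param counts Data frame with columns `drug_name`, `ir_cases` (the
#'   drug's event-positive case count) and `reports` (its total case
#'   count).
#' @param n_total,n_event Universe totals the counts were published
#'   against.
#' @inheritParams analyze_universe
#' @return The same tibble layout as [analyze_universe()].
#' @export
analyze_counts <- function(counts, n_total, n_event,
                           conf = 0.95, continuity = FALSE) {
  stopifnot(all(c("drug_name", "ir_cases", "reports") %in% names(counts)))
  tables <- Map(contingency_from_counts, counts$ir_cases, counts$reports,
                n_total, n_event)
  signal_results(counts$drug_name, tables, conf = conf, continuity = continuity)
}

signal_results <- function(drug_names, tables, conf = 0.95, continuity = FALSE) {
  rows <- Map(function(nm, tb) {
    est <- ror_with_ci(tb, conf = conf, continuity = continuity)
    p <- fisher_exact_2x2(tb)
    tibble::tibble(
      drug_name = nm,
      a = tb$a, b = tb$b, c = tb$c, d = tb$d,
      reports = tb$a + tb$b,
      ror = est$ror, ci_low = est$ci_low, ci_high = est$ci_high,
      ror_undefined = est$undefined,
      p_value = p,
      signal = signal_flag(tb, est$ci_low),
      log_ror = log(est$ror),
      neg_log10_p = -log10(p)
    )
  }, drug_names, tables)
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$p_adjusted <- bh_adjust(out$p_value)
    out <- dplyr::relocate(out, "p_adjusted", .after = "p_value")
  }
  out
}

#' Round a signal-result table for display
#'
#' Report-time rounding convention: ROR and CI bounds to 2 decimal places,
#' p-values to 4. Internal computations are never rounded.
#'
#' @param results Tibble from [analyze_universe()] or [analyze_counts()].
#' @return The tibble with rounded display columns.
#' @export
format_signal_results <- function(results) {
  dplyr::mutate(
    results,
    dplyr::across(dplyr::any_of(c("ror", "ci_low", "ci_high")), ~ round(.x, 2)),
    dplyr::across(dplyr::any_of(c("p_value", "p_adjusted")), ~ round(.x, 4))
  )
}
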