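#' Default column mapping for the four-table report layout
#'
#' Maps canonical column names to the column names found in the CSV files.
#' Override individual entries to read files whose headers differ (real
#' JADER extracts use Japanese headers; a translated mapping slots in here).
#'
#' @return A named list of named character vectors, one per table
#'   (`demo`, `drug`, `reac`, `hist`); names are canonical, values are the
#'   file column names.
#' @export
default_schema <- function() {
  list(
    demo = c(case_id = "case_id", sex = "sex", age = "age", weight = "weight"),
    drug = c(case_id = "case_id", drug_name = "drug_name",
             role = "role", route = "route"),
    reac = c(case_id = "case_id", pt_code = "pt_code",
             pt_name = "pt_name", outcome = "outcome"),
    hist = c(case_id = "case_id", disease = "disease")
  )
}

#' Read the four report tables from CSV files
#'
#' Reads and type-checks the case-keyed tables, renaming file columns to the
#' canonical schema. A declared column missing from a file is a hard error
#' naming both the file and the column.
#'
#' @param paths Named character vector or list with entries `demo`, `drug`,
#'   `reac`, `hist` giving the file paths (a directory containing
#'   `demo.csv` etc. is also accepted).
#' @param schema Column mapping as returned by [default_schema()].
#' @param encoding Character encoding of the files (default UTF-8; real
#'   JADER distributions ship Shift-JIS, pass `"Shift_JIS"`).
#' @return A `report_tables` list of four tibbles with canonical columns.
#' @export
read_report_tables <- function(paths, schema = default_schema(),
                               encoding = "UTF-8") {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    paths <- stats::setNames(
      file.path(paths, paste0(names(schema), ".csv")), names(schema))
  }
  missing_tables <- setdiff(names(schema), names(paths))
  if (length(missing_tables)) {
    stop("no path given for table(s): ", paste(missing_tables, collapse = ", "),
         call. = FALSE)
  }
  loc <- readr::locale(encoding = encoding)
  out <- lapply(names(schema), function(nm) {
    path <- paths[[nm]]
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    tab <- tryCatch(
      readr::read_csv(path, col_types = readr::cols(.default = "c"),
                      locale = loc, progress = FALSE),
      error = function(e) {
        stop(sprintf("failed to read '%s' with encoding %s: %s",
                     path, encoding, conditionMessage(e)), call. = FALSE)
      }
    )
    map <- schema[[nm]]
    absent <- setdiff(unname(map), names(tab))
    if (length(absent)) {
      stop(sprintf("file '%s' is missing declared column(s): %s",
                   path, paste(absent, collapse = ", ")), call. = FALSE)
    }
    tab <- tab[, unname(map), drop = FALSE]
    names(tab) <- names(map)
    tab
  })
  names(out) <- names(schema)
  structure(out, class = "report_tables")
}

#' Normalize drug names for matching
#'
#' Trims and collapses whitespace, folds case, and applies an optional
#' user-supplied synonym map (applied after folding). No other unification
#' of brand, generic or transliterated names is attempted.
#'
#' @param x Character vector of drug names.
#' @param synonyms Optional named character vector mapping folded variants
#'   to canonical names.
#' @return Normalized character vector.
#' @export
normalize_drug_name <- function(x, synonyms = NULL) {
  out <- tolower(trimws(gsub("[[:space:]]+", " ", x)))
  if (!is.null(synonyms)) {
    hit <- out %in% names(synonyms)
    out[hit] <- unname(synonyms[out[hit]])
  }
  out
}

drug_role_levels <- c("suspected", "concomitant", "interaction")
drug_route_levels <- c("intravenous", "oral", "other_unknown")

#' Build the analysis universe from the integrated tables
#'
#' Integrates the tables on the case identifier and applies the study's
#' inclusion rules: drug mentions are kept only when their involvement role
#' and administration route pass the filters (the headline analysis keeps
#' suspected, intravenous mentions), drug names are normalized and duplicate
#' (case, drug) pairs deduplicated, and a case is flagged event-positive
#' when any of its adverse events carries one of the target MedDRA PT codes
#' (a case with several target PTs counts once). The universe consists of
#' the cases retaining at least one qualifying drug mention; its totals
#' `n_total` and `n_event` are the background for all disproportionality
#' contrasts.
#'
#' @param tables A `report_tables` list.
#' @param event_pt_codes Character vector of target PT codes (nonempty).
#' @param role_filter Roles retained (default `"suspected"`).
#' @param route_filter Routes retained (default `"intravenous"`).
#' @param synonyms Optional synonym map passed to [normalize_drug_name()].
#' @return An object of class `analysis_universe`: a list with tibbles
#'   `cases` (case_id, event_flag) and `drug_cases` (case_id, drug_name,
#'   deduplicated), and integers `n_total`, `n_event`.
#' @export
build_universe <- function(tables, event_pt_codes,
                           role_filter = "suspected",
                           route_filter = "intravenous",
                           synonyms = NULL) {
  stopifnot(length(event_pt_codes) >= 1)
  drug <- tibble::as_tibble(tables$drug)
  reac <- tibble::as_tibble(tables$reac)

  unknown_role <- !drug$role %in% drug_role_levels
  if (any(unknown_role)) {
    warning(sprintf("%d drug mention(s) with unknown role mapped to 'other_unknown'",
                    sum(unknown_role)), call. = FALSE)
    drug$role[unknown_role] <- "other_unknown"
  }
  unknown_route <- !drug$route %in% drug_route_levels
  if (any(unknown_route)) {
    warning(sprintf("%d drug mention(s) with unknown route mapped to 'other_unknown'",
                    sum(unknown_route)), call. = FALSE)
    drug$route[unknown_route] <- "other_unknown"
  }

  kept <- drug[drug$role %in% role_filter & drug$route %in% route_filter, ]
  kept$drug_name <- normalize_drug_name(kept$drug_name, synonyms)
  drug_cases <- dplyr::distinct(kept[, c("case_id", "drug_name")])

  event_cases <- unique(reac$case_id[reac$pt_code %in% event_pt_codes])
  universe_ids <- sort(unique(drug_cases$case_id))
  cases <- tibble::tibble(case_id = universe_ids,
                          event_flag = universe_ids %in% event_cases)
  if (nrow(cases) == 0) {
    message("analysis universe is empty after role/route filtering")
  }
  structure(
    list(cases = cases,
         drug_cases = dplyr::arrange(drug_cases, .data$case_id, .data$drug_name),
         n_total = nrow(cases),
         n_event = sum(cases$event_flag),
         role_filter = role_filter,
         route_filter = route_filter,
         event_pt_codes = as.character(event_pt_codes)),
    class = "analysis_universe"
  )
}

#' @export
print.analysis_universe <- function(x, ...) {
  cat(sprintf("Analysis universe: %d cases, %d event-positive, %d drugs\n",
              x$n_total, x$n_event, length(unique(x$drug_cases$drug_name))))
  cat(sprintf("  roles kept:  %s\n", paste(x$role_filter, collapse = ", ")))
  cat(sprintf("  routes kept: %s\n", paste(x$route_filter, collapse = ", ")))
  cat(sprintf("  target PTs:  %s\n", paste(x$event_pt_codes, collapse = ", ")))
  invisible(x)
}

#' Drugs present in an analysis universe
#'
#' @param universe An `analysis_universe`.
#' @param background Include the synthetic background pool drugs
#'   (names starting `background_drug_`)? Default `TRUE`.
#' @return Sorted character vector of drug names.
#' @export
universe_drugs <- function(universe, background = TRUE) {
  drugs <- sort(unique(universe$drug_cases$drug_name))
  if (!background) drugs <- drugs[!startsWith(drugs, "background_drug_")]
  drugs
}
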