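#' Configure an end-to-end disproportionality run
#'
#' A pipeline run takes exactly one input source: a synthetic-report
#' generator configuration, paths to existing four-table CSVs, or a
#' published per-drug counts table with its universe totals.
#'
#' @param generator Optional [generator_config()]: simulate the database.
#' @param table_paths Optional paths accepted by [read_report_tables()].
#' @param counts Optional counts data frame (`drug_name`, `ir_cases`,
#'   `reports`); requires `n_total` and `n_event`.
#' @param n_total,n_event Universe totals accompanying `counts`.
#' @param attribute_map Optional per-drug attribute table (a data frame, or
#'   a CSV path read via [read_attribute_map()]); enables the stratified
#'   comparison stages.
#' @param event_pt_codes Target MedDRA PT codes.
#' @param role_filter,route_filter Inclusion filters for drug mentions.
#' @param synonyms Optional drug-name synonym map.
#' @param conf Confidence level.
#' @param continuity Continuity-correction flag for [ror_with_ci()].
#' @param p_floor Smallest p-value plotted on the volcano; smaller values
#'   are flagged excluded (see [volcano_points()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator = NULL, table_paths = NULL,
                            counts = NULL, n_total = NULL, n_event = NULL,
                            attribute_map = NULL,
                            event_pt_codes = c("10051792", "10052015"),
                            role_filter = "suspected",
                            route_filter = "intravenous",
                            synonyms = NULL, conf = 0.95,
                            continuity = FALSE, p_floor = 1e-300) {
  sources <- c(!is.null(generator), !is.null(table_paths), !is.null(counts))
  if (sum(sources) != 1) {
    stop("exactly one of generator, table_paths, counts must be given",
         call. = FALSE)
  }
  if (!is.null(counts) && (is.null(n_total) || is.null(n_event))) {
    stop("counts input requires n_total and n_event", call. = FALSE)
  }
  if (is.character(attribute_map)) {
    attribute_map <- read_attribute_map(attribute_map)
  }
  structure(list(generator = generator, table_paths = table_paths,
                 counts = counts, n_total = n_total, n_event = n_event,
                 attribute_map = attribute_map,
                 event_pt_codes = event_pt_codes,
                 role_filter = role_filter, route_filter = route_filter,
                 synonyms = synonyms, conf = conf, continuity = continuity,
                 p_floor = p_floor),
            class = "pipeline_config")
}

#' Pipeline configuration for the bundled reference counts
#'
#' Convenience wrapper: the packaged 25-antibody infusion-reaction counts
#' with their published universe totals and curated attribute map.
#'
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
jader_fixture_config <- function(...) {
  ref <- jader_ir_reference()
  pipeline_config(counts = jader_ir_counts(),
                  n_total = ref$n_total, n_event = ref$n_event,
                  attribute_map = jader_attribute_map(),
                  event_pt_codes = ref$event_pt_codes, ...)
}

#' Run the full disproportionality pipeline
#'
#' Orchestrates generate/read -> integrate and filter -> per-drug ROR
#' statistics -> stratified comparison -> volcano coordinates. Reruns with
#' the same configuration are bit-identical. If `output_dir` is given,
#' every stage output is written there as CSV/JSON along with a manifest
#' recording the configuration hash, seed, and row counts at each filter
#' stage.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional output directory.
#' @return A `pipeline_result` list: `per_drug` (signal results tibble),
#'   `pooled` (group RORs by ADCC status, if an attribute map is present),
#'   `detection` (named list of 2xK detection tables with exact-test
#'   p-values), `volcano` (tibble of plot coordinates), `universe_totals`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(config_hash = rlang::hash(unclass(config)),
                   seed = if (!is.null(config$generator)) config$generator$seed)

  if (!is.null(config$counts)) {
    results <- analyze_counts(config$counts, config$n_total, config$n_event,
                              conf = config$conf,
                              continuity = config$continuity)
    totals <- list(n_total = config$n_total, n_event = config$n_event)
    manifest$stage_counts <- list(drugs_analyzed = nrow(results))
    universe <- NULL
  } else {
    tables <- if (!is.null(config$generator)) {
      generate_reports(config$generator)
    } else {
      read_report_tables(config$table_paths)
    }
    universe <- build_universe(tables, config$event_pt_codes,
                               role_filter = config$role_filter,
                               route_filter = config$route_filter,
                               synonyms = config$synonyms)
    manifest$stage_counts <- list(
      drug_mentions_raw = nrow(tables$drug),
      drug_mentions_role_pass = sum(tables$drug$role %in% config$role_filter),
      drug_mentions_kept = sum(tables$drug$role %in% config$role_filter &
                                 tables$drug$route %in% config$route_filter),
      n_total = universe$n_total,
      n_event = universe$n_event
    )
    results <- analyze_universe(universe, conf = config$conf,
                                continuity = config$continuity)
    totals <- list(n_total = universe$n_total, n_event = universe$n_event)
  }

  pooled <- NULL
  detection <- list()
  amap <- config$attribute_map
  if (!is.null(amap) && nrow(results) > 0) {
    mapped <- results[results$drug_name %in% amap$drug_name, ]
    pool_input <- if (!is.null(config$counts)) config$counts else universe
    pool_args <- if (!is.null(config$counts)) {
      list(n_total = config$n_total, n_event = config$n_event)
    } else list()
    pooled <- do.call(pooled_by_attribute,
                      c(list(pool_input, amap, "adcc_status",
                             conf = config$conf,
                             continuity = config$continuity), pool_args))
    for (attr in intersect(c("adcc_status", "antibody_type"), names(amap))) {
      tab <- detection_table(mapped, amap, attr)
      detection[[attr]] <- list(table = tab, p_value = fisher_exact_2xk(tab))
    }
  }

  volcano <- volcano_points(results, p_floor = config$p_floor)

  result <- structure(
    list(per_drug = results, pooled = pooled, detection = detection,
         volcano = volcano, universe_totals = totals, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(output_dir)) write_pipeline_result(result, output_dir)
  result
}

#' Write a pipeline result bundle to disk
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_pipeline_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(format_signal_results(result$per_drug),
                   file.path(dir, "per_drug_signals.csv"))
  if (!is.null(result$pooled)) {
    readr::write_csv(result$pooled, file.path(dir, "pooled_groups.csv"))
  }
  if (length(result$detection)) {
    det <- lapply(result$detection, function(d) {
      list(table = apply(d$table, 1, as.list), p_value = d$p_value)
    })
    jsonlite::write_json(det, file.path(dir, "detection_tables.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  readr::write_csv(result$volcano, file.path(dir, "volcano_points.csv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Disproportionality pipeline result: %d drugs, universe %s/%s\n",
              nrow(x$per_drug),
              format(x$universe_totals$n_total, big.mark = ","),
              format(x$universe_totals$n_event, big.mark = ",")))
  cat(sprintf("  signals detected: %d\n", sum(x$per_drug$signal)))
  for (nm in names(x$detection)) {
    cat(sprintf("  %s comparison: exact p = %.4g\n", nm,
                x$detection[[nm]]$p_value))
  }
  invisible(x)
}

#' Volcano-plot coordinates from signal results
#'
#' One point per drug: `x` is the natural log of the ROR, `y` the negative
#' base-10 log of the unadjusted exact-test p-value. Drugs whose ROR is
#' undefined (zero cell) or whose p-value falls below `p_floor` — including
#' exact zeros after double underflow on very large tables — are flagged
#' `excluded` with a reason rather than plotted at infinity.
#'
#' @param results Signal-result tibble.
#' @param p_floor Exclusion threshold for the p-value (default 1e-300).
#' @return A tibble: `drug_name`, `x`, `y`, `excluded`, `reason`.
#' @export
volcano_points <- function(results, p_floor = 1e-300) {
  if (nrow(results) == 0) {
    return(tibble::tibble(drug_name = character(), x = numeric(),
                          y = numeric(), excluded = logical(),
                          reason = character()))
  }
  undefined <- results$ror_undefined
  underflow <- !undefined & results$p_value < p_floor
  tibble::tibble(
    drug_name = results$drug_name,
    x = ifelse(undefined, NA_real_, results$log_ror),
    y = ifelse(undefined | underflow, NA_real_, results$neg_log10_p),
    excluded = undefined | underflow,
    reason = dplyr::case_when(undefined ~ "undefined ROR",
                              underflow ~ "p underflow",
                              TRUE ~ "")
  )
}

#' Render the volcano plot
#'
#' Optional figure stage: the coordinate table is always the primary
#' output; rendering requires ggplot2.
#'
#' @param points Tibble from [volcano_points()].
#' @param attribute_map Optional attribute map used to color points by
#'   ADCC status.
#' @return A ggplot object.
#' @export
plot_volcano <- function(points, attribute_map = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plot rendering", call. = FALSE)
  }
  pts <- points[!points$excluded, ]
  if (!is.null(attribute_map)) {
    pts$adcc_status <- attribute_map$adcc_status[
      match(pts$drug_name, attribute_map$drug_name)]
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                           color = .data$adcc_status))
  } else {
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y))
  }
  p +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "ln(ROR)", y = expression(-log[10](italic(p))))
}
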