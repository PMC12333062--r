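#' Configuration for the synthetic spontaneous-report generator
#'
#' Describes a synthetic case-keyed adverse-event report database in the
#' four-table JADER layout (demographics, drug mentions, adverse events,
#' medical history) with known disproportionality structure. Each case is
#' assigned one suspected drug; a drug with planted odds multiplier `r`
#' gives its cases target-event probability `r*q / (1 - q + r*q)` where `q`
#' is the background event rate, so the population reporting odds ratio of
#' that drug against the background pool equals `r`.
#'
#' @param n_cases Number of case reports to generate (positive integer).
#' @param background_event_rate Probability in (0, 1) that a case whose
#'   suspected drug is neutral (odds multiplier 1) reports the target event.
#' @param drug_profiles Data frame with one row per planted drug and columns
#'   `drug_name` (string), `share` (fraction of cases assigned to the drug),
#'   and optionally `planted_ror` (positive odds multiplier, default 1),
#'   `route` (`"intravenous"` or `"oral"`, default `"intravenous"`) and
#'   `role_noise` (fraction of the drug's mentions downgraded from suspected
#'   to concomitant, default 0). Shares must sum to at most 1; the remainder
#'   of cases is assigned to a neutral background drug pool.
#' @param event_pt_codes Character vector of MedDRA Preferred Term codes
#'   used for the target event.
#' @param decoy_pt_codes Character vector of non-target PT codes used for
#'   unrelated adverse events.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#' @param n_background_drugs Number of neutral intravenous drugs sharing the
#'   unassigned case fraction.
#' @param multi_drug_prob Probability that a case carries one extra suspected
#'   background-drug mention (off by default: the headline analysis treats
#'   one suspected drug per case).
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_cases,
                             background_event_rate,
                             drug_profiles,
                             event_pt_codes = c("10051792", "10052015"),
                             decoy_pt_codes = sprintf("1%07d", 1:20),
                             seed = 1L,
                             n_background_drugs = 5L,
                             multi_drug_prob = 0) {
  profiles <- tibble::as_tibble(drug_profiles)
  if (!all(c("drug_name", "share") %in% names(profiles))) {
    stop("drug_profiles must have columns 'drug_name' and 'share'", call. = FALSE)
  }
  if (!"planted_ror" %in% names(profiles)) profiles$planted_ror <- 1
  if (!"route" %in% names(profiles)) profiles$route <- "intravenous"
  if (!"role_noise" %in% names(profiles)) profiles$role_noise <- 0

  cfg <- structure(
    list(
      n_cases = as.integer(n_cases),
      background_event_rate = background_event_rate,
      drug_profiles = profiles,
      event_pt_codes = as.character(event_pt_codes),
      decoy_pt_codes = as.character(decoy_pt_codes),
      seed = as.integer(seed),
      n_background_drugs = as.integer(n_background_drugs),
      multi_drug_prob = multi_drug_prob
    ),
    class = "generator_config"
  )
  validate_generator_config(cfg)
}

#' @rdname generator_config
#' @param config An object to validate.
#' @export
validate_generator_config <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  p <- config$drug_profiles
  if (is.na(config$n_cases) || config$n_cases < 1) {
    stop("invalid generator config: n_cases must be >= 1", call. = FALSE)
  }
  q <- config$background_event_rate
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q <= 0 || q >= 1) {
    stop("invalid generator config: background_event_rate must lie in (0, 1)",
         call. = FALSE)
  }
  if (anyDuplicated(p$drug_name)) {
    stop("invalid generator config: duplicated drug_name in drug_profiles",
         call. = FALSE)
  }
  if (any(p$share < 0) || sum(p$share) > 1 + 1e-12) {
    stop("invalid generator config: drug shares must be >= 0 and sum to <= 1",
         call. = FALSE)
  }
  if (any(!is.finite(p$planted_ror)) || any(p$planted_ror <= 0)) {
    stop("invalid generator config: all planted_ror must be > 0", call. = FALSE)
  }
  if (!all(p$route %in% c("intravenous", "oral"))) {
    stop("invalid generator config: route must be 'intravenous' or 'oral'",
         call. = FALSE)
  }
  if (any(p$role_noise < 0) || any(p$role_noise > 1)) {
    stop("invalid generator config: role_noise must lie in [0, 1]", call. = FALSE)
  }
  if (length(config$event_pt_codes) < 1 || any(!nzchar(config$event_pt_codes))) {
    stop("invalid generator config: event_pt_codes must be nonempty strings",
         call. = FALSE)
  }
  if (config$multi_drug_prob < 0 || config$multi_drug_prob > 1) {
    stop("invalid generator config: multi_drug_prob must lie in [0, 1]",
         call. = FALSE)
  }
  invisible(config)
}

#' Read a generator configuration from a YAML file
#'
#' The file holds the scalar fields of [generator_config()] plus a
#' `drug_profiles` list of per-drug mappings.
#'
#' @param path Path to a YAML file.
#' @return A `generator_config` object.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  profiles <- dplyr::bind_rows(lapply(raw$drug_profiles, tibble::as_tibble))
  for (col in intersect(c("share", "planted_ror", "role_noise"),
                        names(profiles))) {
    profiles[[col]] <- as.numeric(profiles[[col]])
  }
  args <- raw[setdiff(names(raw), "drug_profiles")]
  do.call(generator_config, c(list(drug_profiles = profiles), args))
}

# Case-level event probability implied by an odds multiplier r at baseline
# rate q: odds are multiplied, not risks, so the population ROR equals r.
planted_event_prob <- function(r, q) r * q / (1 - q + r * q)

#' Generate a synthetic four-table report database
#'
#' Emits the four case-keyed tables of the JADER layout as UTF-8-friendly
#' tibbles: `demo` (case_id, sex, age, weight), `drug` (case_id, drug_name,
#' role, route), `reac` (case_id, pt_code, pt_name, outcome) and `hist`
#' (case_id, disease). Every case appears exactly once in `demo` and has at
#' least one drug mention. Output is byte-identical for identical
#' configurations.
#'
#' @param config A [generator_config()] object.
#' @return A named list of four tibbles with class `report_tables`.
#' @export
generate_reports <- function(config) {
  validate_generator_config(config)
  n <- config$n_cases
  q <- config$background_event_rate
  profiles <- config$drug_profiles

  # one master seed; deterministic sub-streams per generation stage
  sub_seeds <- withr::with_seed(config$seed,
                                sample.int(.Machine$integer.max, 4L))

  bg_names <- sprintf("background_drug_%02d", seq_len(config$n_background_drugs))
  bg_share <- max(0, 1 - sum(profiles$share))
  pool <- dplyr::bind_rows(
    profiles[, c("drug_name", "share", "planted_ror", "route", "role_noise")],
    tibble::tibble(drug_name = bg_names,
                   share = bg_share / length(bg_names),
                   planted_ror = 1, route = "intravenous", role_noise = 0)
  )

  case_id <- sprintf("CASE%07d", seq_len(n))

  assign <- withr::with_seed(sub_seeds[1], {
    idx <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$share)
    event <- stats::rbinom(n, 1L,
                           planted_event_prob(pool$planted_ror[idx], q)) == 1L
    downgraded <- stats::runif(n) < pool$role_noise[idx]
    extra <- stats::runif(n) < config$multi_drug_prob
    extra_idx <- sample.int(length(bg_names), n, replace = TRUE)
    list(idx = idx, event = event, downgraded = downgraded,
         extra = extra, extra_idx = extra_idx)
  })

  drug <- tibble::tibble(
    case_id = case_id,
    drug_name = pool$drug_name[assign$idx],
    role = ifelse(assign$downgraded, "concomitant", "suspected"),
    route = pool$route[assign$idx]
  )
  if (any(assign$extra)) {
    drug <- dplyr::bind_rows(drug, tibble::tibble(
      case_id = case_id[assign$extra],
      drug_name = bg_names[assign$extra_idx[assign$extra]],
      role = "suspected",
      route = "intravenous"
    ))
    drug <- dplyr::arrange(drug, .data$case_id, .data$drug_name)
  }

  demo <- withr::with_seed(sub_seeds[2], tibble::tibble(
    case_id = case_id,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = sprintf("%d0s", sample(2:8, n, replace = TRUE)),
    weight = sprintf("%dkg", sample(seq(40L, 90L, 10L), n, replace = TRUE))
  ))

  reac <- withr::with_seed(sub_seeds[3], {
    ev <- tibble::tibble(
      case_id = case_id[assign$event],
      pt_code = sample(config$event_pt_codes, sum(assign$event), replace = TRUE)
    )
    n_decoy <- stats::rpois(n, 1)
    dc <- tibble::tibble(
      case_id = rep(case_id, n_decoy),
      pt_code = sample(config$decoy_pt_codes, sum(n_decoy), replace = TRUE)
    )
    out <- dplyr::bind_rows(ev, dc)
    out$pt_name <- paste0("PT_", out$pt_code)
    out$outcome <- sample(c("recovered", "recovering", "unknown"),
                          nrow(out), replace = TRUE)
    dplyr::arrange(out, .data$case_id, .data$pt_code)
  })

  hist <- withr::with_seed(sub_seeds[4], {
    has <- stats::runif(n) < 0.3
    tibble::tibble(
      case_id = case_id[has],
      disease = sample(c("breast cancer", "lung cancer", "lymphoma",
                         "colorectal cancer", "leukemia"),
                       sum(has), replace = TRUE)
    )
  })

  structure(list(demo = demo, drug = drug, reac = reac, hist = hist),
            class = "report_tables")
}

#' Write the four report tables as CSV files
#'
#' @param tables A `report_tables` list as returned by [generate_reports()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written
#'   (`demo.csv`, `drug.csv`, `reac.csv`, `hist.csv`).
#' @export
write_report_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "report_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' @export
print.report_tables <- function(x, ...) {
  cat("Synthetic report tables:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-5s %6d rows x %d cols\n", nm, nrow(x[[nm]]), ncol(x[[nm]])))
  }
  invisible(x)
}
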