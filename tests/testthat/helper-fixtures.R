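# Small synthetic configurations reused across test files.

small_profile <- function(...) {
  defaults <- data.frame(drug_name = "drugA", share = 0.2, planted_ror = 3,
                         route = "intravenous", role_noise = 0)
  args <- list(...)
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  defaults
}

small_config <- function(n_cases = 400, q = 0.05, profiles = small_profile(),
                         seed = 7, ...) {
  generator_config(n_cases = n_cases, background_event_rate = q,
                   drug_profiles = profiles, seed = seed, ...)
}

# Hand-built four-table set for precise ingest edge cases.
toy_tables <- function(drug_rows, reac_rows,
                       case_ids = unique(drug_rows$case_id)) {
  structure(list(
    demo = tibble::tibble(case_id = case_ids, sex = "female",
                          age = "60s", weight = "60kg"),
    drug = tibble::as_tibble(drug_rows),
    reac = tibble::as_tibble(reac_rows),
    hist = tibble::tibble(case_id = character(), disease = character())
  ), class = "report_tables")
}

drug_row <- function(case_id, drug_name, role = "suspected",
                     route = "intravenous") {
  tibble::tibble(case_id = case_id, drug_name = drug_name,
                 role = role, route = route)
}

reac_row <- function(case_id, pt_code) {
  tibble::tibble(case_id = case_id, pt_code = pt_code,
                 pt_name = paste0("PT_", pt_code), outcome = "unknown")
}

ir_pts <- c("10051792", "10052015")
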