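# Reading and writing the register CSV schemas (RFC 4180, UTF-8, ISO dates).

DRUG_CLASSES <- c("stimulant", "non_stimulant", "other_psychotropic")
ADHD_CLASSES <- c("stimulant", "non_stimulant")

PERSONS_CORE <- c("person_id", "sex", "age_at_index", "index_date",
                  "education_level", "death_date", "emigration_date")
DISP_COLS <- c("person_id", "date", "drug_class", "days_supply")
EVENT_COLS <- c("person_id", "date", "outcome_type")

validate_registry <- function(persons, dispensations, events) {
  check_columns(persons, PERSONS_CORE, "persons")
  check_columns(dispensations, DISP_COLS, "dispensations")
  check_columns(events, EVENT_COLS, "events")
  bad <- setdiff(unique(dispensations$drug_class), DRUG_CLASSES)
  if (length(bad)) {
    stop_validation(
      "dispensations: unknown drug_class value(s) %s (column drug_class)",
      paste(sQuote(bad), collapse = ", "))
  }
  if (nrow(dispensations) && any(dispensations$days_supply < 0)) {
    stop_validation("dispensations: negative days_supply")
  }
  if (anyDuplicated(persons$person_id)) {
    stop_validation("persons: duplicated person_id")
  }
  invisible(TRUE)
}

#' Write register tables to CSV
#'
#' Writes `persons.csv`, `dispensations.csv`, `events.csv` with documented
#' column order, ISO-8601 dates, UTF-8. Round-trips losslessly through
#' [read_register_tables()].
#'
#' @param persons,dispensations,events register tables (see
#'   [simulate_cohort()] for schemas).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_register_tables <- function(persons, dispensations, events, out_dir) {
  validate_registry(persons, dispensations, events)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  persons <- data.table::as.data.table(persons)
  extra <- setdiff(names(persons), PERSONS_CORE)
  data.table::setcolorder(persons, c(PERSONS_CORE, extra))
  paths <- file.path(out_dir,
                     c("persons.csv", "dispensations.csv", "events.csv"))
  data.table::fwrite(persons, paths[1], dateTimeAs = "ISO")
  data.table::fwrite(
    data.table::as.data.table(dispensations)[, DISP_COLS, with = FALSE],
    paths[2], dateTimeAs = "ISO")
  data.table::fwrite(
    data.table::as.data.table(events)[, EVENT_COLS, with = FALSE],
    paths[3], dateTimeAs = "ISO")
  invisible(paths)
}

#' Read register tables from CSV
#'
#' @param dir directory containing `persons.csv`, `dispensations.csv`,
#'   `events.csv`.
#' @return list with data.tables `persons`, `dispensations`, `events`.
#' @export
read_register_tables <- function(dir) {
  paths <- file.path(dir, c("persons.csv", "dispensations.csv",
                            "events.csv"))
  miss <- paths[!file.exists(paths)]
  if (length(miss)) {
    stop_validation("missing register file(s): %s",
                    paste(basename(miss), collapse = ", "))
  }
  persons <- data.table::fread(paths[1])
  for (col in c("index_date", "death_date", "emigration_date")) {
    persons[[col]] <- as.Date(persons[[col]])
  }
  dispensations <- data.table::fread(paths[2])
  if (nrow(dispensations)) dispensations$date <- as.Date(dispensations$date)
  else dispensations$date <- as.Date(dispensations$date)
  events <- data.table::fread(paths[3],
                              colClasses = list(character = "outcome_type"))
  events$date <- as.Date(events$date)
  validate_registry(persons, dispensations, events)
  list(persons = persons, dispensations = dispensations, events = events)
}
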