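# Canonical data model: linked household / individual / inpatient-episode /
# outpatient-spell tables with survey multiplier weights. A column-mapping
# config adapts arbitrary survey extracts to the canonical field names, and a
# state-recoding table supports clubbing small states/UTs into pooled codes.

HOUSEHOLD_COLS <- c(
  "household_id", "state", "sector",
  "total_monthly_expenditure", "household_size", "weight"
)
INDIVIDUAL_COLS <- c("person_id", "household_id", "age", "sex", "weight")
INPATIENT_COLS <- c(
  "episode_id", "person_id", "ailment_code", "facility", "stay_days",
  OOPE_COMPONENTS, "weight"
)
OUTPATIENT_COLS <- c(
  "spell_id", "person_id", "visit_ailment_codes", "ailment_duration_days",
  "facility", OOPE_COMPONENTS, "weight"
)

TABLE_REQUIRED_COLS <- list(
  households = HOUSEHOLD_COLS,
  individuals = INDIVIDUAL_COLS,
  inpatient = INPATIENT_COLS,
  outpatient = OUTPATIENT_COLS
)

TABLE_NUMERIC_COLS <- list(
  households = c("total_monthly_expenditure", "household_size", "weight"),
  individuals = c("age", "weight"),
  inpatient = c("stay_days", OOPE_COMPONENTS, "weight"),
  outpatient = c("ailment_duration_days", OOPE_COMPONENTS, "weight")
)

#' Construct a survey dataset from its four component tables
#'
#' Bundles the household, individual, inpatient-episode and outpatient-spell
#' tables into a `survey_dataset` object. Tables must already use the
#' canonical column names (see [load_survey()] for mapping arbitrary files).
#' Multi-visit outpatient ailment codes are stored as a single
#' `visit_ailment_codes` string with `";"` separating visits, because a spell
#' carries one pooled out-of-pocket amount for all its visits.
#'
#' @param households,individuals,inpatient,outpatient Data frames with the
#'   canonical columns.
#' @return A `survey_dataset`: a named list of four tibbles.
#' @export
survey_dataset <- function(households, individuals, inpatient, outpatient) {
  tabs <- list(
    households = tibble::as_tibble(households),
    individuals = tibble::as_tibble(individuals),
    inpatient = tibble::as_tibble(inpatient),
    outpatient = tibble::as_tibble(outpatient)
  )
  for (nm in names(tabs)) {
    stop_if_missing_cols(tabs[[nm]], TABLE_REQUIRED_COLS[[nm]],
      what = sprintf("`%s` table", nm)
    )
  }
  structure(tabs, class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Describe the input files of a survey extract
#'
#' @param households,individuals,inpatient,outpatient Paths to the four CSV
#'   files.
#' @param column_map Optional named list, one entry per table, each a named
#'   character vector `c(canonical = "source_column")` mapping source column
#'   names onto the canonical schema. Unmapped canonical names are assumed to
#'   be present verbatim.
#' @param state_recode Optional named character vector `c(source = "pooled")`
#'   applied to household state codes after loading, e.g. to club small
#'   states or union territories into one pooled code.
#' @return A `survey_paths` list consumed by [load_survey()].
#' @export
survey_paths <- function(households, individuals, inpatient, outpatient,
                         column_map = list(), state_recode = NULL) {
  structure(
    list(
      paths = list(
        households = households, individuals = individuals,
        inpatient = inpatient, outpatient = outpatient
      ),
      column_map = column_map,
      state_recode = state_recode
    ),
    class = "survey_paths"
  )
}

#' Read a survey-paths config from JSON
#'
#' The JSON object holds `paths` (four file paths, resolved relative to the
#' JSON file), optional `column_map` and optional `state_recode`.
#'
#' @param path Path to the JSON config.
#' @return A `survey_paths` object.
#' @export
read_survey_paths <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(is.list(cfg$paths))
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base, p)
  }
  survey_paths(
    households = resolve(cfg$paths$households),
    individuals = resolve(cfg$paths$individuals),
    inpatient = resolve(cfg$paths$inpatient),
    outpatient = resolve(cfg$paths$outpatient),
    column_map = lapply(cfg$column_map, unlist),
    state_recode = unlist(cfg$state_recode)
  )
}

read_one_table <- function(path, table_name, column_map) {
  if (!file.exists(path)) {
    abort(sprintf("Input file for `%s` not found: %s", table_name, path))
  }
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  map <- column_map[[table_name]] %||% character()
  for (canonical in names(map)) {
    src <- map[[canonical]]
    if (!src %in% names(raw)) {
      abort(sprintf(
        "Column mapping for `%s` names source column `%s`, absent from %s",
        table_name, src, path
      ))
    }
    names(raw)[names(raw) == src] <- canonical
  }
  required <- TABLE_REQUIRED_COLS[[table_name]]
  # missing OOPE components are filled with 0 (blank-zero convention), with a
  # warning; any other missing required column is fatal
  miss <- setdiff(required, names(raw))
  fillable <- intersect(miss, OOPE_COMPONENTS)
  if (length(fillable) > 0) {
    warn(sprintf(
      "`%s`: missing OOPE column(s) %s treated as 0",
      table_name, paste(fillable, collapse = ", ")
    ))
    for (col in fillable) raw[[col]] <- "0"
    miss <- setdiff(miss, fillable)
  }
  if (length(miss) > 0) {
    abort(sprintf(
      "`%s` (%s) lacks required column(s) after mapping: %s",
      table_name, path, paste(miss, collapse = ", ")
    ))
  }
  raw
}

# convert declared-numeric columns in place; unparseable non-empty cells are
# recorded as deferred record-level parse errors (the cell becomes NA)
coerce_numeric_cols <- function(df, table_name, id_col) {
  parse_errors <- list()
  for (col in TABLE_NUMERIC_COLS[[table_name]]) {
    if (col %in% OOPE_COMPONENTS) {
      blank <- is.na(df[[col]]) | trimws(df[[col]]) == ""
      if (any(blank)) {
        warn(sprintf(
          "`%s`: %d blank `%s` cell(s) treated as 0",
          table_name, sum(blank), col
        ))
        df[[col]][blank] <- "0"
      }
    }
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(val) & !is.na(df[[col]]) & trimws(df[[col]]) != ""
    if (any(bad)) {
      parse_errors[[col]] <- tibble::tibble(
        table = table_name,
        record_id = df[[id_col]][bad],
        rule = sprintf("%s_numeric", col),
        message = sprintf("unparseable value `%s`", df[[col]][bad])
      )
    }
    df[[col]] <- val
  }
  list(data = df, parse_errors = dplyr::bind_rows(parse_errors))
}

#' Load a survey extract into the canonical data model
#'
#' Reads the four delimited files named by a [survey_paths()] config, applies
#' the column mapping and state recoding, and coerces declared-numeric
#' columns. Unknown columns are preserved but ignored by the pipeline; row
#' order is preserved. Cells that fail numeric parsing become `NA` and are
#' reported by [validate_survey()] rather than aborting the load.
#'
#' @param config A `survey_paths` object or the path to its JSON file.
#' @return A `survey_dataset`.
#' @export
load_survey <- function(config) {
  if (is.character(config)) config <- read_survey_paths(config)
  stopifnot(inherits(config, "survey_paths"))
  id_cols <- c(
    households = "household_id", individuals = "person_id",
    inpatient = "episode_id", outpatient = "spell_id"
  )
  parse_errors <- list()
  tabs <- list()
  for (nm in names(config$paths)) {
    raw <- read_one_table(config$paths[[nm]], nm, config$column_map)
    out <- coerce_numeric_cols(raw, nm, id_cols[[nm]])
    tabs[[nm]] <- out$data
    parse_errors[[nm]] <- out$parse_errors
    inform(sprintf("Loaded `%s`: %d rows", nm, nrow(out$data)))
  }
  if (!is.null(config$state_recode)) {
    st <- tabs$households$state
    hit <- st %in% names(config$state_recode)
    tabs$households$state[hit] <-
      unname(config$state_recode[st[hit]])
    inform(sprintf("State recoding applied to %d household(s)", sum(hit)))
  }
  ds <- survey_dataset(
    tabs$households, tabs$individuals, tabs$inpatient, tabs$outpatient
  )
  attr(ds, "parse_errors") <- dplyr::bind_rows(parse_errors)
  ds
}

rule_check <- function(df, table, id_col, rule, bad, message) {
  if (!any(bad)) {
    return(NULL)
  }
  tibble::tibble(
    table = table, record_id = as.character(df[[id_col]][bad]),
    rule = rule, message = message
  )
}

#' Validate a survey dataset against the schema invariants
#'
#' Every type-invariant violation is reported exactly once, with record id
#' and rule name; the dataset itself is never mutated. Violations are data,
#' not exceptions: a report with an empty error table means the dataset
#' satisfies all invariants.
#'
#' @param dataset A `survey_dataset`.
#' @return A `validation_report`: list with `errors` and `warnings` tibbles
#'   (`table`, `record_id`, `rule`, `message`) and per-table row `counts`.
#' @export
validate_survey <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  hh <- dataset$households
  ind <- dataset$individuals
  ip <- dataset$inpatient
  op <- dataset$outpatient
  errors <- list(attr(dataset, "parse_errors"))

  num_ok <- function(x) !is.na(x) # parse failures already reported separately
  chk <- function(...) errors[[length(errors) + 1L]] <<- rule_check(...)

  chk(hh, "households", "household_id", "total_expenditure>=0",
    num_ok(hh$total_monthly_expenditure) & hh$total_monthly_expenditure < 0,
    "negative total monthly expenditure")
  chk(hh, "households", "household_id", "household_size>=1",
    num_ok(hh$household_size) &
      (hh$household_size < 1 | hh$household_size %% 1 != 0),
    "household size must be a positive integer")
  chk(hh, "households", "household_id", "weight>0",
    num_ok(hh$weight) & hh$weight <= 0, "nonpositive survey weight")
  chk(hh, "households", "household_id", "state_nonmissing",
    is.na(hh$state) | hh$state == "", "missing state")
  chk(hh, "households", "household_id", "sector_valid",
    !(hh$sector %in% SECTORS), "sector must be rural or urban")

  chk(ind, "individuals", "person_id", "household_id_resolves",
    !(ind$household_id %in% hh$household_id), "orphan individual")
  chk(ind, "individuals", "person_id", "age>=0",
    num_ok(ind$age) & ind$age < 0, "negative age")
  chk(ind, "individuals", "person_id", "weight>0",
    num_ok(ind$weight) & ind$weight <= 0, "nonpositive survey weight")

  for (tab in c("inpatient", "outpatient")) {
    df <- dataset[[tab]]
    id_col <- if (tab == "inpatient") "episode_id" else "spell_id"
    chk(df, tab, id_col, "person_id_resolves",
      !(df$person_id %in% ind$person_id), "orphan episode")
    chk(df, tab, id_col, "facility_valid",
      !(df$facility %in% FACILITIES), "facility must be public or private")
    chk(df, tab, id_col, "weight>0",
      num_ok(df$weight) & df$weight <= 0, "nonpositive survey weight")
    for (comp in OOPE_COMPONENTS) {
      chk(df, tab, id_col, sprintf("%s>=0", comp),
        num_ok(df[[comp]]) & df[[comp]] < 0, "negative OOPE component")
    }
  }
  chk(ip, "inpatient", "episode_id", "stay_days>=1",
    num_ok(ip$stay_days) & ip$stay_days < 1, "stay must last at least 1 day")
  chk(op, "outpatient", "spell_id", "visits>=1",
    is.na(op$visit_ailment_codes) |
      trimws(op$visit_ailment_codes) == "", "spell must record >= 1 visit")
  chk(op, "outpatient", "spell_id", "ailment_duration>=0",
    num_ok(op$ailment_duration_days) & op$ailment_duration_days < 0,
    "negative ailment duration")

  structure(
    list(
      errors = dplyr::bind_rows(errors),
      warnings = tibble::tibble(
        table = character(), record_id = character(),
        rule = character(), message = character()
      ),
      counts = vapply(dataset, nrow, integer(1))
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf(
    "  rows: %s\n",
    paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", ")
  ))
  cat(sprintf("  errors: %d, warnings: %d\n", nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors) > 0) print(head(x$errors, 10))
  invisible(x)
}

#' Write a result table to CSV or JSON
#'
#' Column order is as stored and stable; re-reading with [read_result()]
#' reproduces the values to full precision. An empty table yields a
#' header-only CSV (or empty JSON array) without error.
#'
#' @param x A data frame (any pipeline result table).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  x <- tibble::as_tibble(x)
  if (format == "csv") {
    readr::write_csv(x, path, progress = FALSE)
  } else {
    jsonlite::write_json(x, path, digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a result table written by [write_result()]
#'
#' @param path File path; format inferred from the extension.
#' @return A tibble.
#' @export
read_result <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}
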