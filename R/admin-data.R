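#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Schema registry for the six administrative tables. Dates are ISO-8601;
# identifiers are opaque strings and never parsed.
.admin_schemas <- list(
  claims = list(
    cols  = c("patient_id", "provider_id", "service_date", "service_code", "setting"),
    dates = "service_date",
    enums = list(setting = c("office", "emergency_department", "nursing_home", "other")),
    ids   = c("patient_id", "provider_id")
  ),
  roster = list(
    cols       = c("patient_id", "provider_id", "start_date", "end_date"),
    dates      = "start_date",
    open_dates = "end_date",     # empty string means an open interval
    enums      = list(),
    ids        = c("patient_id", "provider_id")
  ),
  chc = list(
    cols  = c("patient_id", "visit_date"),
    dates = "visit_date",
    enums = list(),
    ids   = "patient_id"
  ),
  hospital = list(
    cols  = c("patient_id", "encounter_date", "encounter_type"),
    dates = "encounter_date",
    enums = list(encounter_type = c("ed_visit", "admission")),
    ids   = "patient_id"
  ),
  survey = list(
    cols     = c("respondent_id", "survey_date", "has_pcp", "age_years"),
    dates    = "survey_date",
    logicals = "has_pcp",
    integers = "age_years",
    enums    = list(),
    ids      = "respondent_id"
  ),
  persons = list(
    cols  = c("patient_id", "birth_date", "sex"),
    dates = "birth_date",
    enums = list(sex = c("F", "M")),
    ids   = "patient_id"
  )
)

#' Names of the administrative table schemas
#'
#' @return Character vector of the recognised schema names.
#' @export
admin_schema_names <- function() names(.admin_schemas)

.get_schema <- function(schema) {
  schema <- match.arg(schema, names(.admin_schemas))
  c(.admin_schemas[[schema]], list(name = schema))
}

.iso_date_re <- "^\\d{4}-\\d{2}-\\d{2}$"

# Strict ISO-8601 parse: returns NA where the string is not a real calendar date.
.parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl(.iso_date_re, x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

.parse_logical <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "1", "t")] <- TRUE
  out[lx %in% c("false", "0", "f")] <- FALSE
  out
}

.stop_parse <- function(path, problems) {
  rows <- paste0("  row ", problems$row, ": ", problems$problem, collapse = "\n")
  stop(
    structure(
      class = c("pcattach_parse_error", "error", "condition"),
      list(
        message  = paste0("invalid rows in '", path, "':\n", rows),
        call     = sys.call(-1),
        problems = problems
      )
    )
  )
}

#' Read one administrative table from delimited text
#'
#' Reads a comma-separated UTF-8 file with a header row and validates every
#' row against one of the six administrative schemas (`claims`, `roster`,
#' `chc`, `hospital`, `survey`, `persons`). Validation is total: every input
#' row either becomes a typed record or contributes a row-indexed diagnostic,
#' and any diagnostic aborts the read with an error naming the offending data
#' rows (row 1 is the first row after the header).
#'
#' @param path Path to the CSV file.
#' @param schema Schema name, one of [admin_schema_names()].
#' @return A tibble of validated records with typed columns (`Date` for
#'   dates, logical for flags, integer for counts). An empty `end_date` in a
#'   roster file becomes `NA`, meaning an open interval.
#' @seealso [write_admin_table()] for the inverse, [check_integrity()] for
#'   cross-table checks.
#' @export
read_admin_table <- function(path, schema) {
  sc <- .get_schema(schema)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL, fileEncoding = "UTF-8")
  missing_cols <- setdiff(sc$cols, names(raw))
  extra_cols <- setdiff(names(raw), sc$cols)
  if (length(missing_cols) || length(extra_cols)) {
    stop("header of '", path, "' does not match schema '", sc$name, "'",
         if (length(missing_cols)) paste0("; missing: ", paste(missing_cols, collapse = ", ")),
         if (length(extra_cols)) paste0("; unexpected: ", paste(extra_cols, collapse = ", ")))
  }
  raw <- raw[, sc$cols, drop = FALSE]
  n <- nrow(raw)
  out <- as_tibble(raw)
  problems <- list()
  note <- function(rows, what) {
    if (length(rows)) problems[[length(problems) + 1L]] <<- tibble(row = rows, problem = what)
  }

  for (col in sc$ids) {
    note(which(is.na(raw[[col]]) | trimws(raw[[col]]) == ""),
         paste0("empty identifier in '", col, "'"))
  }
  for (col in sc$dates) {
    parsed <- .parse_iso_date(raw[[col]])
    note(which(is.na(parsed)), paste0("unparseable date in '", col, "'"))
    out[[col]] <- parsed
  }
  for (col in sc$open_dates) {
    blank <- !is.na(raw[[col]]) & trimws(raw[[col]]) == ""
    parsed <- .parse_iso_date(raw[[col]])
    note(which(is.na(parsed) & !blank), paste0("unparseable date in '", col, "'"))
    out[[col]] <- parsed
  }
  for (col in names(sc$enums)) {
    bad <- !(raw[[col]] %in% sc$enums[[col]])
    note(which(bad), paste0("invalid value in '", col, "' (allowed: ",
                            paste(sc$enums[[col]], collapse = ", "), ")"))
  }
  for (col in sc$logicals) {
    parsed <- .parse_logical(raw[[col]])
    note(which(is.na(parsed)), paste0("invalid logical in '", col, "'"))
    out[[col]] <- parsed
  }
  for (col in sc$integers) {
    ok <- grepl("^\\d+$", raw[[col]])
    note(which(!ok), paste0("invalid non-negative integer in '", col, "'"))
    parsed <- rep(NA_integer_, n)
    parsed[ok] <- as.integer(raw[[col]][ok])
    out[[col]] <- parsed
  }
  if (length(problems)) {
    .stop_parse(path, dplyr::arrange(dplyr::bind_rows(problems), .data$row))
  }
  # roster interval sanity: start must not exceed a closed end
  if (identical(sc$name, "roster")) {
    bad <- which(!is.na(out$end_date) & out$start_date > out$end_date)
    if (length(bad)) {
      .stop_parse(path, tibble(row = bad, problem = "start_date after end_date"))
    }
  }
  out
}

#' Write one administrative table to delimited text
#'
#' Inverse of [read_admin_table()]: dates are written as ISO-8601, logicals
#' as `true`/`false`, and an `NA` roster `end_date` as the empty string
#' (open interval), so that a write/read round trip is the identity.
#'
#' @param x Tibble of records matching the schema.
#' @param path Output file path.
#' @param schema Schema name, one of [admin_schema_names()].
#' @return `path`, invisibly.
#' @export
write_admin_table <- function(x, path, schema) {
  sc <- .get_schema(schema)
  missing_cols <- setdiff(sc$cols, names(x))
  if (length(missing_cols)) {
    stop("missing columns for schema '", sc$name, "': ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[, sc$cols, drop = FALSE]
  for (col in c(sc$dates, sc$open_dates)) {
    x[[col]] <- ifelse(is.na(x[[col]]), "", format(as.Date(x[[col]]), "%Y-%m-%d"))
  }
  for (col in sc$logicals) x[[col]] <- ifelse(x[[col]], "true", "false")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Cross-table referential-integrity report
#'
#' Checks the loaded bundle for (1) patient identifiers appearing in any
#' event table but absent from the persons registry, (2) exactly duplicated
#' roster intervals, and (3) overlapping roster intervals for the same
#' patient (a patient may hold at most one active interval on any date).
#' This is a reporting operation: it never throws.
#'
#' @param claims,roster,chc,hospital,survey,persons The six tables, as read
#'   by [read_admin_table()] or produced by [generate_scenario()]. A full
#'   bundle list may be passed as the first argument instead.
#' @return An object of class `pcattach_integrity`: a list with tibbles
#'   `orphans` (table, patient_id), `roster_duplicates` and `roster_overlaps`,
#'   plus a logical `clean`.
#' @export
check_integrity <- function(claims, roster, chc, hospital, survey, persons) {
  if (is.list(claims) && !is.data.frame(claims) && missing(roster)) {
    b <- claims
    claims <- b$claims; roster <- b$roster; chc <- b$chc
    hospital <- b$hospital; survey <- b$survey; persons <- b$persons
  }
  known <- unique(persons$patient_id)
  orphan_tbl <- function(tbl, name, id_col = "patient_id") {
    ids <- unique(tbl[[id_col]])
    miss <- setdiff(ids, known)
    tibble(table = rep(name, length(miss)), patient_id = miss)
  }
  orphans <- dplyr::bind_rows(
    orphan_tbl(claims, "claims"),
    orphan_tbl(roster, "roster"),
    orphan_tbl(chc, "chc"),
    orphan_tbl(hospital, "hospital"),
    orphan_tbl(survey, "survey", "respondent_id")
  )

  dup <- roster |>
    dplyr::count(.data$patient_id, .data$provider_id, .data$start_date,
                 .data$end_date, name = "n_copies") |>
    dplyr::filter(.data$n_copies > 1L)

  overlaps <- .roster_overlaps(roster)

  structure(
    list(orphans = orphans, roster_duplicates = dup, roster_overlaps = overlaps,
         clean = nrow(orphans) == 0L && nrow(dup) == 0L && nrow(overlaps) == 0L),
    class = "pcattach_integrity"
  )
}

# Pairwise interval overlap per patient; open end_date is treated as +Inf.
.roster_overlaps <- function(roster) {
  if (nrow(roster) == 0L) {
    return(tibble(patient_id = character(), start_date_1 = as.Date(character()),
                  end_date_1 = as.Date(character()), start_date_2 = as.Date(character()),
                  end_date_2 = as.Date(character())))
  }
  roster |>
    dplyr::distinct(.data$patient_id, .data$start_date, .data$end_date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$start_date, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      k <- nrow(df)
      if (k < 2L) {
        return(tibble(start_date_1 = as.Date(character()), end_date_1 = as.Date(character()),
                      start_date_2 = as.Date(character()), end_date_2 = as.Date(character())))
      }
      pairs <- utils::combn(k, 2L)
      hit <- apply(pairs, 2L, function(ij) {
        e1 <- df$end_date[ij[1]]
        df$start_date[ij[2]] <= (if (is.na(e1)) as.Date("9999-12-31") else e1)
      })
      keep <- pairs[, hit, drop = FALSE]
      tibble(
        start_date_1 = df$start_date[keep[1, ]], end_date_1 = df$end_date[keep[1, ]],
        start_date_2 = df$start_date[keep[2, ]], end_date_2 = df$end_date[keep[2, ]]
      )
    }) |>
    dplyr::ungroup()
}

#' @export
print.pcattach_integrity <- function(x, ...) {
  cat("<integrity report>\n")
  cat("  orphan event ids:        ", nrow(x$orphans), "\n")
  cat("  duplicate roster rows:   ", nrow(x$roster_duplicates), "\n")
  cat("  overlapping roster rows: ", nrow(x$roster_overlaps), "\n")
  cat(if (x$clean) "  clean\n" else "  NOT clean\n")
  invisible(x)
}

#' Provider formally enrolled at a date, per patient
#'
#' Resolves the roster to the single active enrollment on each patient's
#' index date. When a patient holds several intervals covering the date
#' (an integrity error upstream), the interval with the latest
#' `start_date` wins, with the provider identifier as a deterministic
#' final tie-break.
#'
#' @param roster Roster tibble.
#' @param index Tibble with columns `patient_id` and `index_date`.
#' @return Tibble `patient_id`, `index_date`, `pem_provider_id` (`NA` when
#'   no interval covers the date).
#' @export
pem_provider_at <- function(roster, index) {
  active <- index |>
    dplyr::inner_join(roster, by = "patient_id", relationship = "many-to-many") |>
    dplyr::filter(.data$start_date <= .data$index_date,
                  is.na(.data$end_date) | .data$end_date >= .data$index_date) |>
    dplyr::arrange(.data$patient_id, dplyr::desc(.data$start_date), .data$provider_id) |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::select("patient_id", pem_provider_id = "provider_id")
  index |>
    dplyr::left_join(active, by = "patient_id") |>
    dplyr::select("patient_id", "index_date", "pem_provider_id")
}
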