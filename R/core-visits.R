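#' Default core primary-care service-code list
#'
#' The set of billing codes counted as comprehensive primary-care services.
#' The code list is pure configuration: jurisdictions maintain their own.
#' This default is a small illustrative list used by the synthetic generator
#' and the test-suite; production runs should supply the local list.
#'
#' @return Character vector of service codes.
#' @export
default_core_codes <- function() {
  c("A001", "A003", "A004", "A007", "A888", "K005", "K013", "K017")
}

#' Restrict claims to core primary-care visits
#'
#' Keeps exactly the claims whose service code is on the core list and whose
#' setting is `office`. Claims billed in emergency departments or nursing
#' homes carry setting-specific encounter codes and do not attribute the
#' patient to the provider, so they are excluded here.
#'
#' @param claims Claims tibble.
#' @param core_codes Non-empty character vector of core service codes.
#' @return The filtered claims tibble.
#' @export
filter_core <- function(claims, core_codes = default_core_codes()) {
  if (length(core_codes) == 0L) stop("core_codes must be non-empty")
  dplyr::filter(claims,
                .data$service_code %in% core_codes,
                .data$setting == "office")
}

#' Deduplicate claims to one core visit per patient-provider-day
#'
#' Several claims may be billed for one encounter; only one claim per patient
#' per provider per day is counted as a core visit. Idempotent.
#'
#' @param claims Core-filtered claims tibble.
#' @return Tibble of core visits, unique on
#'   (`patient_id`, `provider_id`, `service_date`), sorted.
#' @export
dedup_daily <- function(claims) {
  claims |>
    dplyr::distinct(.data$patient_id, .data$provider_id, .data$service_date) |>
    dplyr::arrange(.data$patient_id, .data$provider_id, .data$service_date)
}

#' Lookback window specification
#'
#' @param index_date Anchor date (a `Date` or ISO-8601 string).
#' @param lookback_days Positive integer; 730 days stands in for the
#'   two-year lookback (leap-day drift accepted).
#' @return A `window_spec` list.
#' @export
window_spec <- function(index_date, lookback_days = 730L) {
  index_date <- as.Date(index_date)
  if (length(index_date) != 1L || is.na(index_date)) stop("index_date must be a single valid date")
  lookback_days <- as.integer(lookback_days)
  if (is.na(lookback_days) || lookback_days <= 0L) stop("lookback_days must be a positive integer")
  structure(list(index_date = index_date, lookback_days = lookback_days),
            class = "window_spec")
}

#' Restrict visits to a lookback window
#'
#' Retains visits with `index_date - lookback_days < service_date <=
#' index_date`: the lower bound is exclusive and the upper bound (the index
#' date itself) inclusive, so a window of 730 days contains exactly 730
#' candidate dates.
#'
#' @param visits Core-visit tibble (or any tibble with `service_date`).
#' @param window A [window_spec()].
#' @return The windowed tibble.
#' @seealso [in_window_by()] for per-person anchor dates.
#' @export
in_window <- function(visits, window) {
  stopifnot(inherits(window, "window_spec"))
  lo <- window$index_date - window$lookback_days
  dplyr::filter(visits, .data$service_date > lo, .data$service_date <= window$index_date)
}

#' Restrict visits to per-person lookback windows
#'
#' As [in_window()], but each patient is anchored at their own index date
#' (for survey validation, the respondent's survey date). Patients absent
#' from `index` contribute no windowed visits.
#'
#' @param visits Core-visit tibble.
#' @param index Tibble with columns `patient_id`, `index_date`.
#' @param lookback_days Positive integer window length.
#' @param date_col Name of the date column in `visits`.
#' @return The windowed tibble (without the `index_date` column).
#' @export
in_window_by <- function(visits, index, lookback_days = 730L, date_col = "service_date") {
  lookback_days <- as.integer(lookback_days)
  if (is.na(lookback_days) || lookback_days <= 0L) stop("lookback_days must be a positive integer")
  visits |>
    dplyr::inner_join(dplyr::select(index, "patient_id", "index_date"), by = "patient_id") |>
    dplyr::filter(.data[[date_col]] > .data$index_date - lookback_days,
                  .data[[date_col]] <= .data$index_date) |>
    dplyr::select(-"index_date")
}
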