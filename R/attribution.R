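#' Virtually enroll one patient by plurality of core visits
#'
#' Attributes a patient to the provider receiving the plurality of their
#' windowed core visits. Ties on visit count are broken by the most recent
#' visit date to each tied provider, then by the lexicographically smallest
#' provider identifier, so the result is deterministic and independent of
#' input row order. A patient with no visits is enrolled to no one.
#'
#' @param visits Windowed core visits of a single patient.
#' @param patient_id Identifier, required when `visits` is empty (it cannot
#'   be inferred); if supplied alongside non-empty visits it must agree.
#' @return One-row tibble: `patient_id`, `provider_id` (`NA` when no
#'   visits), `visit_count_to_provider`, `total_core_visits`.
#' @seealso [virtual_enroll_all()] for the whole-population version.
#' @export
virtual_enroll <- function(visits, patient_id = NULL) {
  ids <- unique(visits$patient_id)
  if (length(ids) > 1L) {
    stop("virtual_enroll() expects visits of a single patient; got ",
         length(ids), " patient ids")
  }
  if (length(ids) == 1L) {
    if (!is.null(patient_id) && !identical(patient_id, ids)) {
      stop("patient_id does not match the visits supplied")
    }
    patient_id <- ids
  }
  if (nrow(visits) == 0L) {
    if (is.null(patient_id)) stop("patient_id required for a patient with no visits")
    return(tibble(patient_id = patient_id, provider_id = NA_character_,
                  visit_count_to_provider = 0L, total_core_visits = 0L))
  }
  virtual_enroll_all(visits)
}

#' Virtually enroll every patient with at least one windowed core visit
#'
#' Vectorised plurality attribution over all patients (see
#' [virtual_enroll()] for the selection and tie-break rules). Patients with
#' zero windowed visits do not appear; callers that need them (e.g. the
#' attachment engine) add unenrolled rows themselves.
#'
#' @param visits Windowed core visits, any number of patients.
#' @return Tibble with one row per patient present in `visits`.
#' @export
virtual_enroll_all <- function(visits) {
  if (nrow(visits) == 0L) {
    return(tibble(patient_id = character(), provider_id = character(),
                  visit_count_to_provider = integer(), total_core_visits = integer()))
  }
  per_provider <- visits |>
    dplyr::group_by(.data$patient_id, .data$provider_id) |>
    dplyr::summarise(n_visits = dplyr::n(),
                     last_visit = max(.data$service_date), .groups = "drop_last") |>
    dplyr::mutate(total_core_visits = sum(.data$n_visits)) |>
    dplyr::ungroup()
  per_provider |>
    dplyr::arrange(.data$patient_id, dplyr::desc(.data$n_visits),
                   dplyr::desc(.data$last_visit), .data$provider_id) |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::transmute(.data$patient_id, .data$provider_id,
                     visit_count_to_provider = as.integer(.data$n_visits),
                     total_core_visits = as.integer(.data$total_core_visits))
}

#' Provider continuity-of-care (CoC) index
#'
#' For each provider with at least one windowed core visit, computes the
#' CoC index that flags walk-in-style episodic practice. In the primary
#' `patient` mode this is the number of patients virtually enrolled to the
#' provider divided by all unique patients the provider saw over the window.
#' The alternative `visit` mode (for sensitivity analysis) divides the
#' visits made by the provider's virtually enrolled patients by all visits
#' to the provider.
#'
#' @param enrollments Output of [virtual_enroll_all()] on the same windowed
#'   visit set (rows with `NA` provider are ignored).
#' @param visits The windowed core visits of the full population.
#' @param mode `"patient"` (default) or `"visit"`.
#' @return Tibble `provider_id`, `n_virtual`, `n_unique_patients`,
#'   `coc_index` in \[0, 1\]. Providers seen by nobody do not appear.
#' @export
compute_coc <- function(enrollments, visits, mode = c("patient", "visit")) {
  mode <- match.arg(mode)
  enrollments <- dplyr::filter(enrollments, !is.na(.data$provider_id))
  unknown <- setdiff(enrollments$provider_id, visits$provider_id)
  if (length(unknown)) {
    stop("enrollment references provider(s) absent from the visit set: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  denom <- visits |>
    dplyr::group_by(.data$provider_id) |>
    dplyr::summarise(n_unique_patients = dplyr::n_distinct(.data$patient_id),
                     n_visits = dplyr::n(), .groups = "drop")
  numer <- enrollments |>
    dplyr::count(.data$provider_id, name = "n_virtual")
  out <- denom |>
    dplyr::left_join(numer, by = "provider_id") |>
    dplyr::mutate(n_virtual = dplyr::coalesce(.data$n_virtual, 0L))
  if (mode == "patient") {
    out <- dplyr::mutate(out, coc_index = .data$n_virtual / .data$n_unique_patients)
  } else {
    own_visits <- visits |>
      dplyr::semi_join(enrollments, by = c("patient_id", "provider_id")) |>
      dplyr::count(.data$provider_id, name = "n_own_visits")
    out <- out |>
      dplyr::left_join(own_visits, by = "provider_id") |>
      dplyr::mutate(coc_index = dplyr::coalesce(.data$n_own_visits, 0L) / .data$n_visits) |>
      dplyr::select(-"n_own_visits")
  }
  out |>
    dplyr::select("provider_id", "n_virtual", "n_unique_patients", "coc_index") |>
    dplyr::arrange(.data$provider_id)
}

#' Classify provider CoC as low or adequate
#'
#' With the default `strict_greater` comparator a provider is `adequate`
#' exactly when `coc_index > threshold`; a CoC index at or below the
#' threshold (e.g. exactly 10%) is `low`, and patients virtually enrolled
#' to such providers are not deemed attached. The `greater_equal`
#' comparator instead treats an exact tie as adequate; the two differ only
#' on exact ties.
#'
#' @param coc_index Numeric vector of CoC indices in \[0, 1\].
#' @param threshold Fraction strictly between 0 and 1 (default 0.10).
#' @param comparator `"strict_greater"` (default) or `"greater_equal"`;
#'   the abbreviations `"gt"` / `"ge"` are accepted.
#' @return Character vector, `"adequate"` or `"low"`.
#' @export
classify_coc <- function(coc_index, threshold = 0.10,
                         comparator = c("strict_greater", "greater_equal", "gt", "ge")) {
  comparator <- match.arg(comparator)
  comparator <- switch(comparator, gt = "strict_greater", ge = "greater_equal", comparator)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single fraction in (0, 1)")
  }
  adequate <- if (comparator == "strict_greater") coc_index > threshold else coc_index >= threshold
  ifelse(adequate, "adequate", "low")
}
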