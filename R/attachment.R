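#' Configuration for the attachment engine
#'
#' Collects the tunable constants of the hierarchical attachment algorithm.
#'
#' @param lookback_days Length of the visit lookback window in days
#'   (default 730, the two-year window).
#' @param coc_threshold Provider CoC cut-point as a fraction in (0, 1);
#'   default 0.10. The sensitivity analysis in [compare_thresholds()]
#'   contrasts this with 0.25.
#' @param coc_comparator `"strict_greater"` (default: a provider at exactly
#'   the threshold is low-CoC) or `"greater_equal"`; see [classify_coc()].
#' @param coc_mode `"patient"` (patient-count CoC ratio, the primary
#'   definition) or `"visit"`; see [compute_coc()].
#' @param core_codes Core primary-care service-code list.
#' @param index_policy `"survey"` anchors each cohort member's window at
#'   their own survey date (validation runs); `"fixed"` anchors everyone at
#'   `index_date` (population application).
#' @param index_date Anchor date for the `"fixed"` policy; under the
#'   `"survey"` policy it optionally anchors patients without a survey
#'   record (default: the latest survey date in the data).
#' @param pediatric_hook Optional function (`person`, `result`) applied to
#'   uncertainly attached children under `pediatric_age_limit`; see
#'   [apply_pediatric_hook()].
#' @param pediatric_age_limit Age in years below which the hook applies
#'   (default 19).
#' @return A validated `pcattach_config` list.
#' @export
attachment_config <- function(lookback_days = 730L,
                              coc_threshold = 0.10,
                              coc_comparator = c("strict_greater", "greater_equal", "gt", "ge"),
                              coc_mode = c("patient", "visit"),
                              core_codes = default_core_codes(),
                              index_policy = c("survey", "fixed"),
                              index_date = NULL,
                              pediatric_hook = NULL,
                              pediatric_age_limit = 19L) {
  coc_comparator <- match.arg(coc_comparator)
  coc_comparator <- switch(coc_comparator, gt = "strict_greater",
                           ge = "greater_equal", coc_comparator)
  coc_mode <- match.arg(coc_mode)
  index_policy <- match.arg(index_policy)
  lookback_days <- as.integer(lookback_days)
  if (is.na(lookback_days) || lookback_days <= 0L) stop("lookback_days must be positive")
  if (!is.numeric(coc_threshold) || coc_threshold <= 0 || coc_threshold >= 1) {
    stop("coc_threshold must be a fraction in (0, 1)")
  }
  if (length(core_codes) == 0L) stop("core_codes must be non-empty")
  if (index_policy == "fixed" && is.null(index_date)) {
    stop("index_date is required under the fixed index policy")
  }
  if (!is.null(index_date)) index_date <- as.Date(index_date)
  if (!is.null(pediatric_hook) && !is.function(pediatric_hook)) {
    stop("pediatric_hook must be a function or NULL")
  }
  structure(
    list(lookback_days = lookback_days, coc_threshold = coc_threshold,
         coc_comparator = coc_comparator, coc_mode = coc_mode,
         core_codes = core_codes, index_policy = index_policy,
         index_date = index_date, pediatric_hook = pediatric_hook,
         pediatric_age_limit = as.integer(pediatric_age_limit)),
    class = "pcattach_config"
  )
}

# Steps of the hierarchy, in evaluation order.
.attachment_steps <- c("PEM", "CHC", "VIRTUAL", "PEDIATRIC", "NONE")

#' Classify a single person through the attachment hierarchy
#'
#' Reference single-case path through the three hierarchical rules,
#' evaluated strictly in order: (1) PEM — a roster interval covers the
#' index date; (2) CHC — at least one community-health-centre visit in the
#' window; (3) VIRTUAL — the plurality provider has adequate CoC. The first
#' rule that fires decides; otherwise the person is uncertainly attached.
#' [run_attachment()] applies the same rules vectorised over a cohort.
#'
#' @param patient_id Identifier of the person.
#' @param index_date Anchor date of the person's window.
#' @param roster Roster tibble (full, unwindowed).
#' @param chc_visits CHC visit tibble (full; windowed internally).
#' @param enrollment One-row virtual-enrollment tibble for this person from
#'   [virtual_enroll()], or `NULL` if the person has no windowed visits.
#' @param coc_lookup Provider CoC table from [compute_coc()] over the full
#'   population.
#' @param config An [attachment_config()].
#' @return One-row tibble: `patient_id`, `index_date`, `category`
#'   (`attached` / `uncertainly_attached`), `step`, `provider_id`,
#'   `provider_coc`.
#' @export
attach_one <- function(patient_id, index_date, roster, chc_visits,
                       enrollment, coc_lookup, config = attachment_config()) {
  index_date <- as.Date(index_date)
  res <- function(category, step, provider = NA_character_, coc = NA_real_) {
    tibble(patient_id = patient_id, index_date = index_date,
           category = category, step = step,
           provider_id = provider, provider_coc = coc)
  }
  idx <- tibble(patient_id = patient_id, index_date = index_date)
  pem <- pem_provider_at(roster, idx)$pem_provider_id
  if (!is.na(pem)) return(res("attached", "PEM", pem))
  chc_w <- in_window_by(chc_visits, idx, config$lookback_days, date_col = "visit_date")
  if (nrow(chc_w) > 0L) return(res("attached", "CHC"))
  if (!is.null(enrollment) && nrow(enrollment) == 1L && !is.na(enrollment$provider_id)) {
    hit <- coc_lookup[coc_lookup$provider_id == enrollment$provider_id, ]
    if (nrow(hit) == 0L) {
      stop("provider '", enrollment$provider_id, "' missing from the CoC lookup")
    }
    cls <- classify_coc(hit$coc_index, config$coc_threshold, config$coc_comparator)
    if (cls == "adequate") {
      return(res("attached", "VIRTUAL", enrollment$provider_id, hit$coc_index))
    }
  }
  res("uncertainly_attached", "NONE")
}

#' Run the hierarchical attachment algorithm over a cohort
#'
#' Three-pass execution: (1) reduce claims to windowed core visits and
#' virtually enroll the full population by plurality; (2) compute the
#' provider CoC index over the full population; (3) classify every cohort
#' member through the PEM, CHC and VIRTUAL steps in strict order. Under the
#' `"survey"` index policy the cohort is the survey respondents, each
#' anchored at their own survey date; under `"fixed"` it is every person in
#' the registry (or `cohort_ids`), anchored at `config$index_date`. When a
#' `pediatric_hook` is configured it is applied to uncertainly attached
#' children after the three steps.
#'
#' @param data Bundle list with `claims`, `roster`, `chc`, `survey`,
#'   `persons` (and optionally `hospital`), as produced by
#'   [generate_scenario()] or assembled from [read_admin_table()] calls.
#' @param config An [attachment_config()].
#' @param cohort_ids Optional character vector restricting the cohort.
#' @return Object of class `pcattach_attachment`: list with `results` (one
#'   row per cohort member), `flow` (counts entering and attached at each
#'   step), `coc` (provider CoC table), `n_cohort` and `config`.
#' @export
run_attachment <- function(data, config = attachment_config(), cohort_ids = NULL) {
  stopifnot(inherits(config, "pcattach_config"))
  survey <- data$survey
  persons <- data$persons

  if (config$index_policy == "survey") {
    if (is.null(survey) || nrow(survey) == 0L) {
      cohort_index <- tibble(patient_id = character(), index_date = as.Date(character()))
    } else {
      cohort_index <- tibble(patient_id = survey$respondent_id,
                             index_date = survey$survey_date)
    }
    fallback <- config$index_date %||%
      (if (!is.null(survey) && nrow(survey) > 0L) max(survey$survey_date) else NULL)
  } else {
    base_ids <- cohort_ids %||% persons$patient_id
    cohort_index <- tibble(patient_id = base_ids, index_date = config$index_date)
    fallback <- config$index_date
  }
  if (!is.null(cohort_ids)) {
    cohort_index <- dplyr::filter(cohort_index, .data$patient_id %in% cohort_ids)
  }
  cohort_index <- dplyr::distinct(cohort_index, .data$patient_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$patient_id)

  if (nrow(cohort_index) == 0L) {
    empty <- tibble(patient_id = character(), index_date = as.Date(character()),
                    category = character(), step = character(),
                    provider_id = character(), provider_coc = numeric())
    return(structure(
      list(results = empty, flow = .flow_report(empty),
           coc = tibble(provider_id = character(), n_virtual = integer(),
                        n_unique_patients = integer(), coc_index = numeric(),
                        coc_class = character()),
           n_cohort = 0L, config = config),
      class = "pcattach_attachment"
    ))
  }

  # windows for the full population (drives virtual enrollment and CoC)
  pop_ids <- unique(c(persons$patient_id, cohort_index$patient_id))
  pop_index <- tibble(patient_id = pop_ids) |>
    dplyr::left_join(cohort_index, by = "patient_id")
  if (anyNA(pop_index$index_date)) {
    if (is.null(fallback)) stop("no index date available for non-cohort patients; ",
                                "set index_date in the config")
    pop_index$index_date[is.na(pop_index$index_date)] <- fallback
  }

  core <- data$claims |>
    filter_core(config$core_codes) |>
    dedup_daily()
  windowed <- in_window_by(core, pop_index, config$lookback_days)
  enrollments <- virtual_enroll_all(windowed)
  coc <- compute_coc(enrollments, windowed, mode = config$coc_mode)
  coc$coc_class <- classify_coc(coc$coc_index, config$coc_threshold, config$coc_comparator)

  # step 1: formal enrollment at the index date
  pem <- pem_provider_at(data$roster, cohort_index)
  # step 2: any CHC visit in the window
  chc_ids <- in_window_by(data$chc, cohort_index, config$lookback_days,
                          date_col = "visit_date")$patient_id |> unique()
  # step 3: plurality provider with adequate CoC
  virt <- enrollments |>
    dplyr::left_join(dplyr::select(coc, "provider_id", "coc_index", "coc_class"),
                     by = "provider_id")

  results <- cohort_index |>
    dplyr::left_join(dplyr::select(pem, "patient_id", "pem_provider_id"), by = "patient_id") |>
    dplyr::left_join(dplyr::select(virt, "patient_id", virt_provider = "provider_id",
                                   "coc_index", "coc_class"), by = "patient_id") |>
    dplyr::mutate(
      step = dplyr::case_when(
        !is.na(.data$pem_provider_id) ~ "PEM",
        .data$patient_id %in% chc_ids ~ "CHC",
        !is.na(.data$virt_provider) & .data$coc_class == "adequate" ~ "VIRTUAL",
        TRUE ~ "NONE"
      ),
      category = ifelse(.data$step == "NONE", "uncertainly_attached", "attached"),
      provider_id = dplyr::case_when(
        .data$step == "PEM" ~ .data$pem_provider_id,
        .data$step == "VIRTUAL" ~ .data$virt_provider,
        TRUE ~ NA_character_
      ),
      provider_coc = ifelse(.data$step == "VIRTUAL", .data$coc_index, NA_real_)
    ) |>
    dplyr::select("patient_id", "index_date", "category", "step",
                  "provider_id", "provider_coc")

  if (!is.null(config$pediatric_hook)) {
    results <- .apply_pediatric_pass(results, persons, config)
  }

  structure(
    list(results = results,
         flow = .flow_report(results),
         coc = coc,
         n_cohort = nrow(results),
         config = config),
    class = "pcattach_attachment"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.age_at <- function(birth_date, index_date) {
  as.integer(floor(as.numeric(index_date - birth_date) / 365.25))
}

.apply_pediatric_pass <- function(results, persons, config) {
  ages <- results |>
    dplyr::left_join(dplyr::select(persons, "patient_id", "birth_date"), by = "patient_id") |>
    dplyr::mutate(age = .age_at(.data$birth_date, .data$index_date))
  idx <- which(ages$category == "uncertainly_attached" &
                 !is.na(ages$age) & ages$age < config$pediatric_age_limit)
  for (i in idx) {
    person <- persons[persons$patient_id == results$patient_id[i], ]
    results[i, ] <- apply_pediatric_hook(person, results[i, ], config$pediatric_hook,
                                         age_limit = config$pediatric_age_limit)
  }
  results
}

#' Delegate an uncertainly attached child to the pediatric access hook
#'
#' The pediatric access algorithm for children under 19 is jurisdictional
#' prior work and is not reproduced here; population application exposes it
#' as a pluggable hook. With no hook the default result passes through
#' unchanged. A hook that attaches the child is recorded as step
#' `PEDIATRIC`.
#'
#' @param person One-row persons tibble (must include `birth_date`).
#' @param result One-row attachment result, category `uncertainly_attached`.
#' @param hook Function (`person`, `result`) returning a one-row result, or
#'   `NULL` for the identity.
#' @param age_limit The hook applies below this age at the index date.
#' @return A one-row attachment result tibble.
#' @export
apply_pediatric_hook <- function(person, result, hook = NULL, age_limit = 19L) {
  age <- .age_at(person$birth_date, result$index_date)
  if (is.na(age) || age >= age_limit) {
    stop("pediatric hook applies only to persons under ", age_limit,
         " at the index date (patient ", result$patient_id, " is ", age, ")")
  }
  if (result$category != "uncertainly_attached") {
    stop("pediatric hook applies only to uncertainly attached persons")
  }
  if (is.null(hook)) return(result)
  out <- tryCatch(hook(person, result), error = function(e) {
    stop("pediatric hook failed for patient ", result$patient_id, ": ",
         conditionMessage(e))
  })
  if (out$category == "attached") out$step <- "PEDIATRIC"
  out
}

.flow_report <- function(results) {
  n <- nrow(results)
  steps <- c("PEM", "CHC", "VIRTUAL", "PEDIATRIC")
  entering <- n
  rows <- lapply(steps, function(s) {
    att <- sum(results$step == s)
    row <- tibble(step = s, n_entering = entering, n_attached = att,
                  pct_of_cohort = if (n > 0) 100 * att / n else 0,
                  pct_of_entering = if (entering > 0) 100 * att / entering else 0)
    entering <<- entering - att
    row
  })
  unc <- sum(results$category == "uncertainly_attached")
  dplyr::bind_rows(
    dplyr::bind_rows(rows),
    tibble(step = "UNCERTAIN", n_entering = entering, n_attached = unc,
           pct_of_cohort = if (n > 0) 100 * unc / n else 0,
           pct_of_entering = if (entering > 0) 100 * unc / entering else 0)
  )
}

#' @export
print.pcattach_attachment <- function(x, ...) {
  cat("<patient attachment run>\n")
  cat("  cohort size:", x$n_cohort, "\n")
  att <- sum(x$results$category == "attached")
  cat(sprintf("  attached: %d (%.1f%%)  uncertainly attached: %d (%.1f%%)\n",
              att, if (x$n_cohort) 100 * att / x$n_cohort else 0,
              x$n_cohort - att,
              if (x$n_cohort) 100 * (x$n_cohort - att) / x$n_cohort else 0))
  cat("  flow by step:\n")
  f <- x$flow
  for (i in seq_len(nrow(f))) {
    cat(sprintf("    %-9s entering %6d  classified %6d  (%.1f%% of cohort)\n",
                f$step[i], f$n_entering[i], f$n_attached[i], f$pct_of_cohort[i]))
  }
  invisible(x)
}

#' Healthcare-use audit of the uncertainly attached
#'
#' For every uncertainly attached person, flags whether they had at least
#' one core primary-care visit (episodic access still happens, e.g. in
#' walk-in clinics) and at least one hospital-based encounter (ED visit or
#' admission) within the same lookback window used by the attachment run.
#'
#' @param results Results tibble from [run_attachment()] (or the fit object
#'   itself), carrying `patient_id`, `category` and `index_date`.
#' @param core_visits Core-visit tibble (windowing is applied here, so the
#'   full set is fine).
#' @param hospital Hospital-encounter tibble.
#' @param lookback_days Window length; defaults to the fit's configuration
#'   when a fit object is supplied, else 730.
#' @return Tibble `patient_id`, `any_core_visit`, `any_hospital_use`, one
#'   row per uncertainly attached person.
#' @export
audit_uncertain <- function(results, core_visits, hospital, lookback_days = NULL) {
  if (inherits(results, "pcattach_attachment")) {
    lookback_days <- lookback_days %||% results$config$lookback_days
    results <- results$results
  }
  lookback_days <- lookback_days %||% 730L
  unc <- dplyr::filter(results, .data$category == "uncertainly_attached")
  idx <- dplyr::select(unc, "patient_id", "index_date")
  core_ids <- unique(in_window_by(core_visits, idx, lookback_days)$patient_id)
  hosp_ids <- unique(in_window_by(hospital, idx, lookback_days,
                                  date_col = "encounter_date")$patient_id)
  tibble(patient_id = unc$patient_id,
         any_core_visit = unc$patient_id %in% core_ids,
         any_hospital_use = unc$patient_id %in% hosp_ids)
}
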