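# Small in-code fixture builders shared across the suite.

d <- function(x) as.Date(x)

make_claims <- function(patient_id, provider_id, service_date,
                        service_code = "A001", setting = "office") {
  tibble::tibble(
    patient_id = patient_id, provider_id = provider_id,
    service_date = as.Date(service_date),
    service_code = service_code, setting = setting
  )
}

make_visits <- function(patient_id, provider_id, service_date) {
  tibble::tibble(patient_id = patient_id, provider_id = provider_id,
                 service_date = as.Date(service_date))
}

make_roster <- function(patient_id, provider_id, start_date, end_date = NA) {
  tibble::tibble(patient_id = patient_id, provider_id = provider_id,
                 start_date = as.Date(start_date), end_date = as.Date(end_date))
}

empty_chc <- function() {
  tibble::tibble(patient_id = character(), visit_date = as.Date(character()))
}

empty_hospital <- function() {
  tibble::tibble(patient_id = character(), encounter_date = as.Date(character()),
                 encounter_type = character())
}

make_persons <- function(patient_id, birth_date = "1970-06-15", sex = "F") {
  tibble::tibble(patient_id = patient_id, birth_date = as.Date(birth_date), sex = sex)
}

# A minimal consistent bundle: every patient rostered to one provider, one
# office visit each, surveyed on the same day.
toy_rostered_bundle <- function(n = 10L, index_date = "2018-06-01") {
  ids <- sprintf("P%03d", seq_len(n))
  index_date <- as.Date(index_date)
  list(
    persons = make_persons(ids),
    claims = make_claims(ids, "D01", index_date - 30L),
    roster = make_roster(ids, "D01", index_date - 900L),
    chc = empty_chc(),
    hospital = empty_hospital(),
    survey = tibble::tibble(respondent_id = ids, survey_date = index_date,
                            has_pcp = TRUE, age_years = 40L)
  )
}

# Random claims over small id/date spaces, for brute-force oracle tests.
random_claims <- function(n, n_patients = 6L, n_providers = 4L,
                          codes = c("A001", "Z999"),
                          settings = c("office", "emergency_department")) {
  make_claims(
    patient_id = sample(sprintf("P%02d", seq_len(n_patients)), n, replace = TRUE),
    provider_id = sample(sprintf("D%02d", seq_len(n_providers)), n, replace = TRUE),
    service_date = as.Date("2018-01-01") + sample.int(900L, n, replace = TRUE),
    service_code = sample(codes, n, replace = TRUE),
    setting = sample(settings, n, replace = TRUE)
  )
}

# Independent exact-rational percentage with half-up rounding to one
# decimal, done entirely in integer arithmetic.
rational_pct <- function(num, den) {
  if (den == 0L) return(NA_real_)
  scaled <- 1000L * num
  q <- scaled %/% den
  r <- scaled %% den
  (q + as.integer(2L * r >= den)) / 10
}
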