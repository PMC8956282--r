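# Straight-line re-implementation of the three hierarchical rules for one
# person, used as an end-to-end oracle against run_attachment().
oracle_attach <- function(pid, index_date, bundle, coc, config) {
  r <- bundle$roster
  covered <- r$patient_id == pid & r$start_date <= index_date &
    (is.na(r$end_date) | r$end_date >= index_date)
  if (any(covered)) return("PEM")
  ch <- bundle$chc
  in_w <- ch$patient_id == pid & ch$visit_date > index_date - config$lookback_days &
    ch$visit_date <= index_date
  if (any(in_w)) return("CHC")
  cl <- bundle$claims
  core <- cl[cl$patient_id == pid & cl$service_code %in% config$core_codes &
               cl$setting == "office" &
               cl$service_date > index_date - config$lookback_days &
               cl$service_date <= index_date, ]
  core <- unique(core[, c("patient_id", "provider_id", "service_date")])
  if (nrow(core) > 0) {
    e <- virtual_enroll(tibble::as_tibble(core))
    cx <- coc$coc_index[coc$provider_id == e$provider_id]
    if (length(cx) == 1 && cx > config$coc_threshold) return("VIRTUAL")
  }
  "NONE"
}

test_that("a rostered patient with zero visits is attached at the PEM step", {
  cfg <- attachment_config()
  res <- attach_one("P1", "2018-06-01",
                    roster = make_roster("P1", "D1", "2015-01-01"),
                    chc_visits = empty_chc(),
                    enrollment = NULL,
                    coc_lookup = tibble::tibble(provider_id = character(),
                                                coc_index = numeric()),
                    config = cfg)
  expect_identical(res$category, "attached")
  expect_identical(res$step, "PEM")
  expect_identical(res$provider_id, "D1")
})

test_that("a low-CoC plurality provider leaves the patient uncertainly attached", {
  cfg <- attachment_config(coc_threshold = 0.10)
  enr <- tibble::tibble(patient_id = "P1", provider_id = "DW",
                        visit_count_to_provider = 2L, total_core_visits = 2L)
  coc <- tibble::tibble(provider_id = "DW", coc_index = 0.05)
  res <- attach_one("P1", "2018-06-01", make_roster(character(), character(),
                                                    as.Date(character())),
                    empty_chc(), enr, coc, cfg)
  expect_identical(res$category, "uncertainly_attached")
  expect_identical(res$step, "NONE")
  expect_true(is.na(res$provider_id))
})

test_that("the hierarchy fires CHC before an adequate virtual enrollment", {
  cfg <- attachment_config()
  enr <- tibble::tibble(patient_id = "P1", provider_id = "DR",
                        visit_count_to_provider = 5L, total_core_visits = 5L)
  coc <- tibble::tibble(provider_id = "DR", coc_index = 0.9)
  chc <- tibble::tibble(patient_id = "P1", visit_date = d("2018-05-01"))
  res <- attach_one("P1", "2018-06-01",
                    make_roster(character(), character(), as.Date(character())),
                    chc, enr, coc, cfg)
  expect_identical(res$step, "CHC")

  expect_error(
    attach_one("P1", "2018-06-01",
               make_roster(character(), character(), as.Date(character())),
               empty_chc(), enr,
               tibble::tibble(provider_id = "OTHER", coc_index = 0.5), cfg),
    "missing from the CoC lookup")
})

test_that("an all-rostered cohort attaches 100% at the PEM step", {
  b <- toy_rostered_bundle(25)
  fit <- run_attachment(b, attachment_config())
  expect_identical(sum(fit$results$step == "PEM"), 25L)
  f <- fit$flow
  expect_equal(f$pct_of_cohort[f$step == "PEM"], 100)
  expect_identical(f$n_entering[f$step == "CHC"], 0L)
})

test_that("an empty cohort yields empty results and an all-zero flow", {
  b <- toy_rostered_bundle(3)
  b$survey <- b$survey[0, ]
  fit <- run_attachment(b, attachment_config())
  expect_identical(fit$n_cohort, 0L)
  expect_true(all(fit$flow$n_attached == 0L))
})

test_that("flow counts equal a straight-line re-implementation on 500 people", {
  b <- generate_scenario(scenario_config(n_patients = 500, n_providers = 12, seed = 202))
  cfg <- attachment_config()
  fit <- run_attachment(b, cfg)
  expected_steps <- vapply(seq_len(nrow(b$survey)), function(i) {
    oracle_attach(b$survey$respondent_id[i], b$survey$survey_date[i], b, fit$coc, cfg)
  }, character(1))
  got <- fit$results$step[match(b$survey$respondent_id, fit$results$patient_id)]
  expect_identical(got, expected_steps)
  expect_identical(as.integer(table(factor(expected_steps,
                                           c("PEM", "CHC", "VIRTUAL", "PEDIATRIC")))),
                   fit$flow$n_attached[1:4])
})

test_that("categories and steps partition the cohort", {
  b <- generate_scenario(scenario_config(n_patients = 300, n_providers = 10, seed = 7))
  fit <- run_attachment(b)
  res <- fit$results
  expect_identical(nrow(res), 300L)
  expect_identical(anyDuplicated(res$patient_id), 0L)
  expect_identical(sum(res$category == "attached") +
                     sum(res$category == "uncertainly_attached"), 300L)
  expect_identical(sum(fit$flow$n_attached), 300L)
  expect_true(all((res$category == "attached") ==
                    (res$step %in% c("PEM", "CHC", "VIRTUAL", "PEDIATRIC"))))
  # VIRTUAL implies an adequate CoC value is recorded
  virt <- res[res$step == "VIRTUAL", ]
  expect_true(all(!is.na(virt$provider_coc) & virt$provider_coc > 0.10))
})

test_that("results are identical regardless of input row order", {
  b <- generate_scenario(scenario_config(n_patients = 200, n_providers = 8, seed = 55))
  fit1 <- run_attachment(b)
  set.seed(1)
  b2 <- b
  b2$claims <- b$claims[sample.int(nrow(b$claims)), ]
  b2$roster <- b$roster[sample.int(nrow(b$roster)), ]
  b2$survey <- b$survey[sample.int(nrow(b$survey)), ]
  fit2 <- run_attachment(b2)
  expect_identical(fit1$results, fit2$results)
  expect_identical(fit1$flow, fit2$flow)
})

test_that("the attached set shrinks as the CoC threshold rises", {
  b <- generate_scenario(scenario_config(n_patients = 400, n_providers = 12, seed = 88))
  attached_at <- function(th) {
    r <- run_attachment(b, attachment_config(coc_threshold = th))$results
    r$patient_id[r$category == "attached"]
  }
  a10 <- attached_at(0.10)
  a25 <- attached_at(0.25)
  a60 <- attached_at(0.60)
  expect_true(all(a25 %in% a10))
  expect_true(all(a60 %in% a25))
})

test_that("hierarchy dominance: claims cannot dislodge a PEM attachment", {
  b <- toy_rostered_bundle(4)
  fit1 <- run_attachment(b)
  b$claims <- dplyr::bind_rows(
    b$claims,
    make_claims(rep("P001", 5), "D99", paste0("2018-0", 1:5, "-15")))
  fit2 <- run_attachment(b)
  expect_identical(fit1$results[fit1$results$patient_id == "P001", ],
                   fit2$results[fit2$results$patient_id == "P001", ])
  # removing the roster record can only move the person down the hierarchy
  b$roster <- b$roster[b$roster$patient_id != "P001", ]
  fit3 <- run_attachment(b)
  step3 <- fit3$results$step[fit3$results$patient_id == "P001"]
  expect_true(step3 %in% c("CHC", "VIRTUAL", "NONE"))
})

test_that("the usage audit flags match brute-force per-person scans", {
  b <- generate_scenario(scenario_config(n_patients = 300, n_providers = 10, seed = 17))
  cfg <- attachment_config()
  fit <- run_attachment(b, cfg)
  core <- dedup_daily(filter_core(b$claims, cfg$core_codes))
  audit <- audit_uncertain(fit, core, b$hospital)
  unc <- fit$results[fit$results$category == "uncertainly_attached", ]
  expect_identical(nrow(audit), nrow(unc))
  for (i in seq_len(nrow(unc))) {
    pid <- unc$patient_id[i]; idx <- unc$index_date[i]
    cw <- core$patient_id == pid & core$service_date > idx - 730 & core$service_date <= idx
    hw <- b$hospital$patient_id == pid &
      b$hospital$encounter_date > idx - 730 & b$hospital$encounter_date <= idx
    expect_identical(audit$any_core_visit[audit$patient_id == pid], any(cw))
    expect_identical(audit$any_hospital_use[audit$patient_id == pid], any(hw))
  }
})

test_that("an uncertainly attached walk-in user audits as having core visits", {
  idx <- d("2018-06-01")
  res <- tibble::tibble(patient_id = c("P1", "P2"), index_date = idx,
                        category = "uncertainly_attached", step = "NONE",
                        provider_id = NA_character_, provider_coc = NA_real_)
  core <- make_visits(c("P1", "P1"), c("DW1", "DW2"), c("2018-01-10", "2018-03-04"))
  audit <- audit_uncertain(res, core, empty_hospital())
  expect_true(audit$any_core_visit[audit$patient_id == "P1"])
  expect_false(audit$any_core_visit[audit$patient_id == "P2"])
  expect_false(any(audit$any_hospital_use))
})

test_that("the pediatric hook is identity when absent and labels when it attaches", {
  person <- make_persons("K1", birth_date = "2005-01-01")
  res <- tibble::tibble(patient_id = "K1", index_date = d("2018-06-01"),
                        category = "uncertainly_attached", step = "NONE",
                        provider_id = NA_character_, provider_coc = NA_real_)
  expect_identical(apply_pediatric_hook(person, res, NULL), res)

  always <- function(person, result) {
    result$category <- "attached"
    result$provider_id <- "DPED"
    result
  }
  out <- apply_pediatric_hook(person, res, always)
  expect_identical(out$step, "PEDIATRIC")
  expect_identical(out$provider_id, "DPED")

  adult <- make_persons("A1", birth_date = "1980-01-01")
  res_a <- res; res_a$patient_id <- "A1"
  expect_error(apply_pediatric_hook(adult, res_a, always), "under 19")
})

test_that("a configured hook attaches uncertain children during a population run", {
  b <- toy_rostered_bundle(6)
  b$persons$birth_date[1:2] <- d("2003-06-02")   # under 19 at the 2018 index
  b$roster <- b$roster[-(1:2), ]                 # make the children un-rostered
  b$claims <- b$claims[-(1:2), ]
  hook <- function(person, result) { result$category <- "attached"; result }
  cfg <- attachment_config(index_policy = "fixed", index_date = "2018-06-01",
                           pediatric_hook = hook)
  fit <- run_attachment(b, cfg)
  kids <- fit$results[fit$results$patient_id %in% c("P001", "P002"), ]
  expect_identical(kids$step, c("PEDIATRIC", "PEDIATRIC"))
  others <- fit$results[!fit$results$patient_id %in% c("P001", "P002"), ]
  expect_true(all(others$step == "PEM"))
})
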