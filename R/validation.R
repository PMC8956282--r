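#' Build a 2x2 confusion table from pre-tabulated cell counts
#'
#' Positive means the algorithm classified the person as attached; the
#' reference standard is the survey self-report of having a PCP.
#'
#' @param tp Attached and self-reported PCP.
#' @param fp Attached and self-reported no PCP.
#' @param fn Uncertainly attached and self-reported PCP.
#' @param tn Uncertainly attached and self-reported no PCP.
#' @param n_unlinked Respondents excluded for failed linkage (metadata).
#' @return Object of class `pcattach_confusion`.
#' @seealso [confusion()] to cross-tabulate from results, and
#'   [diagnostic_metrics()] for the derived metrics.
#' @export
confusion_table <- function(tp, fp, fn, tn, n_unlinked = 0L) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("confusion cells must be non-negative integers")
  }
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp),
         fn = as.integer(fn), tn = as.integer(tn),
         n = as.integer(tp + fp + fn + tn),
         n_unlinked = as.integer(n_unlinked)),
    class = "pcattach_confusion"
  )
}

#' Cross-tabulate attachment results against survey self-report
#'
#' Joins the algorithm's verdicts to the survey reference standard by
#' respondent identifier. Respondents without an attachment result fail
#' linkage: they are excluded from the table, counted in `n_unlinked`, and
#' the linkage rate is reported via a message.
#'
#' @param results Results tibble from [run_attachment()] (or the fit
#'   object).
#' @param survey Survey tibble with `respondent_id` and `has_pcp`.
#' @param quiet Suppress the linkage message.
#' @return A `pcattach_confusion` object.
#' @export
confusion <- function(results, survey, quiet = FALSE) {
  if (inherits(results, "pcattach_attachment")) results <- results$results
  linked <- survey |>
    dplyr::inner_join(dplyr::select(results, "patient_id", "category"),
                      by = c(respondent_id = "patient_id"))
  n_unlinked <- nrow(survey) - nrow(linked)
  if (!quiet && nrow(survey) > 0L) {
    message(sprintf("linked %d of %d respondents (%.1f%%)",
                    nrow(linked), nrow(survey), 100 * nrow(linked) / nrow(survey)))
  }
  att <- linked$category == "attached"
  confusion_table(
    tp = sum(att & linked$has_pcp),
    fp = sum(att & !linked$has_pcp),
    fn = sum(!att & linked$has_pcp),
    tn = sum(!att & !linked$has_pcp),
    n_unlinked = n_unlinked
  )
}

#' @export
print.pcattach_confusion <- function(x, ...) {
  cat("<2x2 confusion table> (rows: algorithm, cols: self-report)\n")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("attached", "uncertain"), c("has PCP", "no PCP")))
  print(stats::addmargins(as.table(m)))
  if (x$n_unlinked > 0L) cat("unlinked respondents excluded:", x$n_unlinked, "\n")
  invisible(x)
}

#' Round half away from zero
#'
#' Printed percentages use half-up rounding to one decimal, unlike base
#' `round()`'s round-half-to-even. Internal arithmetic stays in double
#' precision with rounding applied only at the end.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Diagnostic metrics of the attachment algorithm
#'
#' Sensitivity `100*tp/(tp+fn)`, specificity `100*tn/(fp+tn)`, positive
#' predictive value `100*tp/(tp+fp)` and negative predictive value
#' `100*tn/(fn+tn)`, each as a percentage rounded half-up to one decimal.
#' A metric whose denominator is zero is undefined and reported as `NA`,
#' never as 0.
#'
#' @param table A `pcattach_confusion` object.
#' @return Named list with `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
diagnostic_metrics <- function(table) {
  stopifnot(inherits(table, "pcattach_confusion"))
  ratio <- function(num, den) if (den == 0L) NA_real_ else round_half_up(100 * num / den, 1L)
  list(
    sensitivity = ratio(table$tp, table$tp + table$fn),
    specificity = ratio(table$tn, table$fp + table$tn),
    ppv         = ratio(table$tp, table$tp + table$fp),
    npv         = ratio(table$tn, table$fn + table$tn)
  )
}

#' Split the survey cohort into development and validation sets
#'
#' The development set contains respondents surveyed strictly before the
#' cutoff date; the validation set contains those surveyed on or after it.
#' The two sets are disjoint and exhaustive.
#'
#' @param survey Survey tibble.
#' @param cutoff_date Split date (`Date` or ISO-8601 string).
#' @return List with tibbles `development` and `validation`.
#' @export
split_cohort <- function(survey, cutoff_date) {
  cutoff_date <- as.Date(cutoff_date)
  list(
    development = dplyr::filter(survey, .data$survey_date < cutoff_date),
    validation  = dplyr::filter(survey, .data$survey_date >= cutoff_date)
  )
}

#' Compare two provider-CoC cut-points
#'
#' Reruns the attachment algorithm at each cut-point and reports, per
#' cut-point, the proportion of respondents reporting no PCP who are
#' classified uncertainly attached (true-negative proportion) and the
#' proportion of respondents reporting a PCP who are classified attached
#' (true-positive proportion). Each pair of proportions is compared with a
#' two-sample proportion z-test (normal approximation, no continuity
#' correction), significant at `alpha`.
#'
#' @param data Bundle list as for [run_attachment()].
#' @param survey Survey tibble (defaults to `data$survey`).
#' @param thresholds Two distinct CoC cut-points (default `c(0.10, 0.25)`).
#' @param config Base [attachment_config()]; its `coc_threshold` is
#'   overridden by each cut-point in turn.
#' @param alpha Significance level (default 0.001).
#' @return Object of class `pcattach_threshold_comparison`: a list with
#'   `by_threshold` (one row per cut-point with both proportions),
#'   `tests` (z statistic and p-value per proportion), and `alpha`.
#' @export
compare_thresholds <- function(data, survey = data$survey,
                               thresholds = c(0.10, 0.25),
                               config = attachment_config(),
                               alpha = 0.001) {
  if (length(thresholds) != 2L) stop("exactly two thresholds are required")
  fits <- lapply(thresholds, function(th) {
    cfg <- config
    cfg$coc_threshold <- th
    run_attachment(data, cfg)
  })
  one <- function(fit, th) {
    ct <- confusion(fit, survey, quiet = TRUE)
    tibble(
      threshold = th,
      n_no_pcp = ct$tn + ct$fp,
      true_negative_prop = if (ct$tn + ct$fp > 0) ct$tn / (ct$tn + ct$fp) else NA_real_,
      n_has_pcp = ct$tp + ct$fn,
      true_positive_prop = if (ct$tp + ct$fn > 0) ct$tp / (ct$tp + ct$fn) else NA_real_
    )
  }
  by_threshold <- dplyr::bind_rows(Map(one, fits, thresholds))

  ztest <- function(x, n) {
    if (any(n == 0L)) return(tibble(z = NA_real_, p_value = NA_real_))
    p1 <- x[1] / n[1]; p2 <- x[2] / n[2]
    pool <- sum(x) / sum(n)
    se <- sqrt(pool * (1 - pool) * (1 / n[1] + 1 / n[2]))
    z <- if (se == 0) 0 else (p1 - p2) / se
    tibble(z = z, p_value = 2 * stats::pnorm(-abs(z)))
  }
  tn_counts <- round(by_threshold$true_negative_prop * by_threshold$n_no_pcp)
  tp_counts <- round(by_threshold$true_positive_prop * by_threshold$n_has_pcp)
  tests <- dplyr::bind_rows(
    dplyr::mutate(ztest(tn_counts, by_threshold$n_no_pcp), proportion = "true_negative"),
    dplyr::mutate(ztest(tp_counts, by_threshold$n_has_pcp), proportion = "true_positive")
  ) |>
    dplyr::mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha) |>
    dplyr::select("proportion", "z", "p_value", "significant")

  structure(list(by_threshold = by_threshold, tests = tests, alpha = alpha),
            class = "pcattach_threshold_comparison")
}

#' @export
print.pcattach_threshold_comparison <- function(x, ...) {
  cat("<CoC cut-point comparison>\n")
  print(as.data.frame(x$by_threshold), row.names = FALSE)
  cat(sprintf("two-sample proportion z-tests (alpha = %g):\n", x$alpha))
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}
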