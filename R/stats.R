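#' @name validation-stats
#' @title Agreement, validity and screening-performance statistics
#'
#' @description
#' The statistics used to evaluate a trigger tool: paired-rater confusion
#' matrices over the record x trigger grid with observed agreement, Cohen's
#' kappa and the prevalence-adjusted bias-adjusted kappa (PABAK); per-trigger
#' positive predictive values split by incident class; the item-level content
#' validity index (I-CVI) over expert Likert ratings; and cohort frequency
#' reports (WHO classes, NCC MERP categories, per-trigger positives,
#' demographics).
#'
#' Trigger review grids are dominated by negative cells, which depresses
#' Cohen's kappa through its chance-agreement term even when raters almost
#' always agree; PABAK (`2 * observed agreement - 1`) is reported alongside
#' kappa for that reason.
NULL

#' A 2x2 paired-rater confusion matrix
#'
#' @param a both raters positive.
#' @param b rater 1 negative, rater 2 positive.
#' @param c rater 1 positive, rater 2 negative.
#' @param d both raters negative.
#' @return an `att_confusion` object.
#' @export
confusion_matrix <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0))
    abort("confusion-matrix counts must be non-negative")
  if (sum(counts) == 0) abort("confusion matrix must contain at least one cell")
  structure(as.list(counts), n = sum(counts), class = "att_confusion")
}

#' @export
print.att_confusion <- function(x, ...) {
  cat("Paired-rater confusion matrix (n =", attr(x, "n"), "cells)\n")
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(paste("rater2", c("positive", "negative")),
                              paste("rater1", c("positive", "negative"))))
  # a = both positive, b = r1 neg/r2 pos, c = r1 pos/r2 neg, d = both negative
  m["rater2 negative", "rater1 positive"] <- x$c
  m["rater2 positive", "rater1 negative"] <- x$b
  print(m)
  invisible(x)
}

#' Build the confusion matrix from two assessment grids
#'
#' Both raters must cover the identical record x trigger grid; the unit of
#' analysis is the single grid cell (one trigger on one record, positive or
#' not).
#'
#' @param assessments1,assessments2 tibbles `record_id`, `trigger_id`,
#'   `positive` (logical) covering the same cells.
#' @return an `att_confusion` matrix whose counts tally to
#'   `records x triggers`.
#' @export
build_confusion_matrix <- function(assessments1, assessments2) {
  key1 <- paste(assessments1$record_id, assessments1$trigger_id)
  key2 <- paste(assessments2$record_id, assessments2$trigger_id)
  if (anyDuplicated(key1) || anyDuplicated(key2))
    abort("assessment grids contain duplicate record x trigger cells")
  if (!setequal(key1, key2))
    abort("raters must assess the identical record x trigger grid")
  p1 <- assessments1$positive
  p2 <- assessments2$positive[match(key1, key2)]
  if (any(is.na(p1)) || any(is.na(p2)))
    abort("assessment grids must be fully filled (no NA cells)")
  confusion_matrix(a = sum(p1 & p2), b = sum(!p1 & p2),
                   c = sum(p1 & !p2), d = sum(!p1 & !p2))
}

#' Observed agreement (accuracy)
#'
#' @param cm an `att_confusion` matrix.
#' @return `(a + d) / n`.
#' @export
observed_agreement <- function(cm) {
  (cm$a + cm$d) / attr(cm, "n")
}

#' Cohen's kappa for two raters on a binary judgement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with the expected agreement `p_e` taken
#' from the product of the marginal proportions. When both raters' marginals
#' are fully concentrated (`p_e = 1`) chance agreement saturates and kappa is
#' undefined; the function then returns `NA` with a warning rather than
#' propagating a silent `NaN`.
#'
#' @param cm an `att_confusion` matrix.
#' @return the kappa coefficient in `[-1, 1]`, or `NA` when undefined.
#' @export
cohens_kappa <- function(cm) {
  n <- attr(cm, "n")
  po <- observed_agreement(cm)
  pe <- ((cm$a + cm$b) * (cm$a + cm$c) + (cm$c + cm$d) * (cm$b + cm$d)) / n^2
  if (isTRUE(all.equal(pe, 1))) {
    warn("chance agreement p_e = 1: Cohen's kappa is undefined for this matrix")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Prevalence-adjusted bias-adjusted kappa (PABAK)
#'
#' `PABAK = 2 * p_o - 1`, robust when one category dominates the grid (the
#' usual situation in trigger review, where almost all cells are negative).
#'
#' @param cm an `att_confusion` matrix.
#' @return the PABAK coefficient in `[-1, 1]`.
#' @export
pabak <- function(cm) {
  2 * observed_agreement(cm) - 1
}

#' Interpretation band for a kappa-type coefficient
#'
#' Bands: 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial,
#' 0.81-1.00 almost perfect; anything below 0.21 is labelled `below_fair`.
#'
#' @param value kappa or PABAK value in `[-1, 1]`.
#' @return one of `"below_fair"`, `"fair"`, `"moderate"`, `"substantial"`,
#'   `"almost_perfect"`.
#' @export
interpret_kappa <- function(value) {
  if (is.na(value) || value < -1 || value > 1)
    abort("kappa value must lie in [-1, 1]")
  if (value < 0.21) "below_fair"
  else if (value < 0.41) "fair"
  else if (value < 0.61) "moderate"
  else if (value < 0.81) "substantial"
  else "almost_perfect"
}

#' Full agreement report for one rater pair
#'
#' @param cm an `att_confusion` matrix.
#' @param digits decimals for the presented values.
#' @param mode presentation mode passed to [att_round()].
#' @return list with the matrix, `observed_agreement`, `kappa`, `pabak`, their
#'   interpretation bands, and presentation-rounded values.
#' @export
agreement_report <- function(cm, digits = 2, mode = "round") {
  k <- cohens_kappa(cm)
  pb <- pabak(cm)
  po <- observed_agreement(cm)
  list(matrix = cm,
       observed_agreement = po, kappa = k, pabak = pb,
       kappa_band = if (!is.na(k)) interpret_kappa(k) else NA_character_,
       pabak_band = interpret_kappa(pb),
       presented = c(observed_agreement = att_round(po, digits, mode),
                     kappa = if (is.na(k)) NA_real_ else att_round(k, 1, mode),
                     pabak = att_round(pb, digits, mode)))
}

#' Per-trigger positive predictive values by incident class
#'
#' For each trigger, the PPV of an incident class is the number of the
#' trigger's positives linked to that class divided by the trigger's total
#' positives, times 100. A trigger with zero positives has undefined PPVs
#' (`NA`), never silent zeros.
#'
#' @param tallies tibble `trigger_id`, `positives`, `near_miss`, `no_harm`,
#'   `harmful` (counts).
#' @return the input with `ppv_near_miss`, `ppv_no_harm`, `ppv_harmful` added
#'   (full precision percentages).
#' @export
trigger_ppv <- function(tallies) {
  need <- c("trigger_id", "positives", "near_miss", "no_harm", "harmful")
  if (!all(need %in% names(tallies)))
    abort(paste0("tallies need columns: ", paste(need, collapse = ", ")))
  over <- with(tallies, near_miss + no_harm + harmful > positives)
  if (any(over))
    abort(paste0("incident-class counts exceed positives for: ",
                 paste(tallies$trigger_id[over], collapse = ", ")))
  ppv1 <- function(k, n) ifelse(n > 0, k / n * 100, NA_real_)
  tallies |>
    mutate(ppv_near_miss = ppv1(.data$near_miss, .data$positives),
           ppv_no_harm = ppv1(.data$no_harm, .data$positives),
           ppv_harmful = ppv1(.data$harmful, .data$positives))
}

#' Item-level content validity index
#'
#' Share of expert raters scoring the item 3 or 4 on the 4-point relevance
#' scale (1 = not relevant ... 4 = highly relevant). An I-CVI of 0.80 or
#' higher flags the item as highly relevant.
#'
#' @param ratings integer vector of Likert ratings in 1-4, one per rater.
#' @param threshold relevance threshold, default 0.80.
#' @return list `icvi` (full precision), `presented` (two decimals),
#'   `highly_relevant` (logical at the threshold), `n_raters`.
#' @export
icvi <- function(ratings, threshold = 0.80) {
  if (!length(ratings)) abort("I-CVI needs at least one rating")
  if (any(is.na(ratings)) || any(!ratings %in% 1:4))
    abort("Likert ratings must be integers 1-4")
  value <- sum(ratings >= 3) / length(ratings)
  list(icvi = value, presented = att_round(value, 2),
       highly_relevant = value >= threshold, n_raters = length(ratings))
}

# ---- cohort frequency reporting --------------------------------------------

pct <- function(k, n, digits = 1, mode = "round") att_round(k / n * 100, digits, mode)

#' Frequency report over a reviewed cohort
#'
#' Emits the standard result tables of a trigger-tool review: WHO-class counts
#' and percentages of the cohort, NCC MERP category counts, per-trigger
#' positive counts with class-specific PPVs, and a demographic summary (sex,
#' dispatch priority, triage colour, conveyance mode).
#'
#' @param classifications [merge_reviews()] output covering the cohort.
#' @param screening `att_screening` tibble for the same cohort.
#' @param records the cohort's `ems_records` tibble.
#' @param digits decimals for percentages.
#' @param mode `"round"` or `"truncate"` presentation.
#' @return list of tibbles: `who`, `merp`, `triggers`, `demographics`, plus
#'   `n` (cohort size).
#' @export
frequency_report <- function(classifications, screening, records,
                             digits = 1, mode = "round") {
  n <- nrow(records)
  missing_cls <- setdiff(records$record_id, classifications$record_id)
  if (length(missing_cls))
    abort(paste0("classification missing for cohort records: ",
                 paste(head(missing_cls, 5), collapse = ", ")))
  classifications <- classifications[classifications$record_id %in% records$record_id, ]

  who <- tibble(who_class = .att_who_levels) |>
    left_join(count(classifications, who_class = .data$who_class), by = "who_class") |>
    mutate(n = coalesce(.data$n, 0L), pct = pct(.data$n, !!n, digits, mode))

  merp <- tibble(category = c("none", .att_merp_levels)) |>
    left_join(classifications |>
                mutate(category = coalesce(.data$final_category, "none")) |>
                count(.data$category), by = "category") |>
    mutate(n = coalesce(.data$n, 0L), pct = pct(.data$n, !!n, digits, mode))

  class_by_record <- classifications |>
    select("record_id", "who_class")
  trig <- screening |>
    filter(.data$record_id %in% records$record_id) |>
    left_join(class_by_record, by = "record_id") |>
    group_by(.data$trigger_id) |>
    summarise(
      positives = sum(.data$status == "positive"),
      near_miss = sum(.data$status == "positive" & .data$who_class == "near_miss"),
      no_harm = sum(.data$status == "positive" & .data$who_class == "no_harm_incident"),
      harmful = sum(.data$status == "positive" & .data$who_class == "harmful_incident"),
      .groups = "drop") |>
    mutate(pct_of_cohort = pct(.data$positives, !!n, digits, mode)) |>
    trigger_ppv()

  demo_counts <- function(field) {
    records |>
      count(value = as.character(.data[[field]])) |>
      mutate(variable = field, pct = pct(.data$n, !!n, digits, mode)) |>
      select("variable", "value", "n", "pct")
  }
  demographics <- bind_rows(
    tibble(variable = "patient_age", value = "median (IQR)",
           n = NA_integer_,
           pct = NA_real_) |>
      mutate(summary = paste0(stats::median(records$patient_age, na.rm = TRUE), " (",
                              stats::quantile(records$patient_age, 0.25, na.rm = TRUE),
                              "-",
                              stats::quantile(records$patient_age, 0.75, na.rm = TRUE),
                              ")")),
    demo_counts("patient_sex"),
    demo_counts("dispatch_priority"),
    demo_counts("triage_colour"),
    demo_counts("conveyance_mode"))

  list(n = n, who = who, merp = merp, triggers = trig, demographics = demographics)
}
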