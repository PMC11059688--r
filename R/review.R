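#' @name review-workflow
#' @title Two-stage incident review
#'
#' @description
#' Records screening positive on at least one trigger undergo a primary review
#' by a registered nurse, and — depending on the workflow version — a
#' secondary review by a physician:
#'
#' * **original** workflow: the primary reviewer classifies the incident into
#'   NCC MERP categories AB, C or D; records graded C or D are routed to the
#'   secondary reviewer, who looks for a harmful incident and, if found,
#'   grades it E-I.
#' * **revised** workflow (after the final consensus round): the primary
#'   reviewer decides whether positive triggers contributed to an incident and
#'   whether it put the patient at risk of harm. Incidents without risk of
#'   harm are classified AB or C by the primary reviewer; incidents with risk
#'   of harm carry no primary category and go to the secondary reviewer, who
#'   decides harm (not harmed: AB/C/D; harmed: E-I plus harm type and
#'   preventability).
#'
#' Human judgement is always an explicit input (a judgement table or the
#' simulated reviewer from the synthetic-data module); the engine never infers
#' clinical judgement from record content.
NULL

#' Map an NCC MERP category to a WHO incident class
#'
#' `NA`/absent maps to `no_incident`, AB to `near_miss`, C and D to
#' `no_harm_incident`, E through I to `harmful_incident`.
#'
#' @param category character vector of NCC MERP categories (`"AB"`, `"C"` ...
#'   `"I"`) or `NA` for no incident.
#' @return character vector of WHO classes.
#' @export
merp_to_who <- function(category) {
  out <- rep(NA_character_, length(category))
  out[is.na(category)] <- "no_incident"
  out[category %in% "AB"] <- "near_miss"
  out[category %in% c("C", "D")] <- "no_harm_incident"
  out[category %in% c("E", "F", "G", "H", "I")] <- "harmful_incident"
  bad <- is.na(out)
  if (any(bad))
    abort(paste0("unknown NCC MERP category: ",
                 paste(unique(category[bad]), collapse = ", ")))
  out
}

#' Primary review of screened records
#'
#' Joins the screening outcome with the primary reviewer's judgement. Records
#' with zero positive triggers are resolved to `incident_present = FALSE`
#' regardless of the judgement table (they were never reviewable). The
#' judgement's category must belong to the configured workflow's allowed set
#' (AB/C/D for the original workflow, AB/C for the revised one, and no
#' category at all for revised-workflow incidents with risk of harm).
#'
#' @param screening an `att_screening` tibble from [screen_records()].
#' @param judgement tibble with columns `record_id`, `incident_present`
#'   (logical), `risk_of_harm` (logical), `category` (character or `NA`),
#'   and optionally `incident_count`.
#' @param workflow `"revised"` (default) or `"original"`.
#' @return tibble `record_id`, `positive_count`, `incident_present`,
#'   `risk_of_harm`, `category`, `incident_count`.
#' @export
classify_primary <- function(screening, judgement, workflow = c("revised", "original")) {
  workflow <- match.arg(workflow)
  summ <- screening_summary(screening)
  if (!all(c("record_id", "incident_present", "risk_of_harm", "category")
           %in% names(judgement)))
    abort("judgement table must have record_id, incident_present, risk_of_harm, category")
  extra <- setdiff(judgement$record_id, summ$record_id)
  if (length(extra))
    abort(paste0("judgement refers to unscreened records: ",
                 paste(head(extra, 5), collapse = ", ")))
  out <- summ |>
    left_join(judgement, by = "record_id") |>
    mutate(
      incident_present = ifelse(.data$positive_count == 0, FALSE,
                                coalesce(.data$incident_present, FALSE)),
      risk_of_harm = .data$incident_present & coalesce(.data$risk_of_harm, FALSE),
      category = ifelse(.data$incident_present, .data$category, NA_character_))
  if (!"incident_count" %in% names(out)) out$incident_count <- NA_integer_
  out$incident_count <- ifelse(out$incident_present,
                               coalesce(out$incident_count, 1L), 0L)
  allowed <- if (workflow == "revised") c("AB", "C") else c("AB", "C", "D")
  bad <- out$incident_present & !is.na(out$category) & !out$category %in% allowed
  if (any(bad))
    abort(paste0("primary category outside the ", workflow, " workflow's set (",
                 paste(allowed, collapse = "/"), "): ",
                 paste(unique(out$category[bad]), collapse = ", ")))
  if (workflow == "revised") {
    # incidents flagged risk-of-harm carry no primary category
    out$category[out$risk_of_harm] <- NA_character_
  }
  no_cat <- out$incident_present & !out$risk_of_harm & is.na(out$category)
  if (any(no_cat))
    abort(paste0("primary incidents without risk of harm need a category: ",
                 paste(head(out$record_id[no_cat], 5), collapse = ", ")))
  select(out, "record_id", "positive_count", "incident_present",
         "risk_of_harm", "category", "incident_count")
}

#' Does a primary review require a secondary (physician) review?
#'
#' Original workflow: categories C and D are routed onward. Revised workflow:
#' any incident with risk of harm is routed onward.
#'
#' @param primary output of [classify_primary()].
#' @param workflow `"revised"` (default) or `"original"`.
#' @return logical vector, one element per primary-review row.
#' @export
requires_secondary_review <- function(primary, workflow = c("revised", "original")) {
  workflow <- match.arg(workflow)
  if (workflow == "original")
    primary$incident_present & !is.na(primary$category) &
      primary$category %in% c("C", "D")
  else
    primary$incident_present & primary$risk_of_harm
}

#' Merge primary and secondary reviews into final incident classifications
#'
#' The secondary reviewer's category overrides the primary one where a
#' secondary review exists; a harmed patient must be graded E-I, a not-harmed
#' patient AB/C/D, and preventability is required exactly when the patient was
#' harmed. Every record routed to secondary review must appear in `secondary`.
#'
#' @param primary output of [classify_primary()].
#' @param secondary tibble `record_id`, `harmed` (logical), `category`,
#'   `harm_type`, `preventability` (1-4); may be empty when nothing was routed.
#' @param workflow `"revised"` (default) or `"original"`.
#' @return tibble `record_id`, `final_category` (`NA` = no incident),
#'   `who_class`, `source` (`primary_only`/`secondary`), `harm_type`,
#'   `preventability`, `incident_count`.
#' @export
merge_reviews <- function(primary, secondary = NULL,
                          workflow = c("revised", "original")) {
  workflow <- match.arg(workflow)
  needs <- requires_secondary_review(primary, workflow)
  if (is.null(secondary))
    secondary <- tibble(record_id = character(), harmed = logical(),
                        category = character(), harm_type = character(),
                        preventability = integer())
  missing_sec <- setdiff(primary$record_id[needs], secondary$record_id)
  if (length(missing_sec))
    abort(paste0("secondary review required but missing for: ",
                 paste(head(missing_sec, 5), collapse = ", ")))
  harmed_bad <- secondary$harmed & !secondary$category %in% c("E", "F", "G", "H", "I")
  nharm_bad <- !secondary$harmed & !secondary$category %in% c("AB", "C", "D")
  if (any(harmed_bad) || any(nharm_bad))
    abort("secondary category inconsistent with harm decision (harmed: E-I; not harmed: AB/C/D)")
  prev_bad <- secondary$harmed & (is.na(secondary$preventability) |
                                    !secondary$preventability %in% 1:4)
  if (any(prev_bad))
    abort("harmed incidents require a preventability grade 1-4")

  sec_idx <- match(primary$record_id, secondary$record_id)
  use_sec <- needs & !is.na(sec_idx)
  final_category <- ifelse(use_sec, secondary$category[sec_idx], primary$category)
  final_category[!primary$incident_present] <- NA_character_
  tibble(
    record_id = primary$record_id,
    final_category = final_category,
    who_class = merp_to_who(final_category),
    source = ifelse(use_sec, "secondary", "primary_only"),
    harm_type = ifelse(use_sec, secondary$harm_type[sec_idx], NA_character_),
    preventability = ifelse(use_sec, secondary$preventability[sec_idx], NA_integer_),
    incident_count = primary$incident_count)
}

#' Run the whole two-stage review over a screened cohort
#'
#' Convenience wrapper: primary classification, secondary routing and merge in
#' one call.
#'
#' @param screening an `att_screening` tibble.
#' @param primary_judgement primary judgement table (see [classify_primary()]).
#' @param secondary_judgement secondary judgement table (see [merge_reviews()]).
#' @param workflow `"revised"` (default) or `"original"`.
#' @return the [merge_reviews()] classification table.
#' @export
classify_cohort <- function(screening, primary_judgement,
                            secondary_judgement = NULL,
                            workflow = c("revised", "original")) {
  workflow <- match.arg(workflow)
  primary <- classify_primary(screening, primary_judgement, workflow)
  merge_reviews(primary, secondary_judgement, workflow)
}
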