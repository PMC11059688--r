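#' @name trigger-engine
#' @title Trigger rule engine
#'
#' @description
#' Each trigger of the ambulance trigger tool is encoded as a rule over one
#' mission record. A rule returns one of three statuses: `positive` (criteria
#' met), `negative` (criteria assessable and not met) or `not_applicable`
#' (the record is outside the trigger's domain, e.g. a non-priority-1 mission
#' for the response-time trigger). A positive result always carries evidence:
#' the criterion/criteria met together with the observed value.
#'
#' Judgement-dependent triggers (B1B, B3, B8, L1) additionally honour a
#' per-record manual override column (`override_b1b` etc.): reviewers reading
#' the free-text narrative can force a positive or negative that the
#' structured rules cannot see. A missing override leaves the rule outcome
#' untouched.
NULL

tr_result <- function(status, evidence = character()) {
  if (status == "positive" && !length(evidence))
    abort("internal: positive trigger result requires evidence")
  list(status = status,
       evidence = if (length(evidence)) paste(evidence, collapse = "; ") else NA_character_)
}

field1 <- function(rec, nm) rec[[nm]][[1L]]

# A1 — incomplete documentation: positive when any configured documentation
# criterion is unmet; evidence lists every unmet criterion
eval_a1 <- function(rec, config) {
  criteria <- config$vocabulary$documentation_criteria
  if (!length(criteria)) abort("A1 requires at least one configured documentation criterion")
  cols <- paste0("doc_", criteria)
  missing_cols <- setdiff(cols, names(rec))
  if (length(missing_cols))
    abort(paste0("A1 documentation criteria without record columns: ",
                 paste(missing_cols, collapse = ", ")))
  present <- map_lgl(cols, function(cl) isTRUE(rec[[cl]]))
  if (all(present)) return(tr_result("negative"))
  tr_result("positive", paste0("documentation criterion unmet: ", criteria[!present]))
}

# A2 — response time > 20 min on a priority-1 (lights and sirens) dispatch;
# strict inequality, whole minutes rounded down
eval_a2 <- function(rec, config) {
  limit <- config$vocabulary$thresholds$response_time_min
  if (is.na(rec$dispatch_priority) || rec$dispatch_priority != 1L)
    return(tr_result("not_applicable"))
  mins <- minutes_between(rec$mission_start, rec$on_scene_arrival)
  if (is.na(mins)) return(tr_result("not_applicable"))
  if (mins > limit)
    return(tr_result("positive", paste0("response time ", mins, " min > ", limit,
                                        " min at priority 1")))
  tr_result("negative")
}

# A3 — time on site > 10 min with a life-threatening condition (configured as
# RETTS-A red triage); strict inequality
eval_a3 <- function(rec, config) {
  limit <- config$vocabulary$thresholds$time_on_site_min
  life_threat <- config$vocabulary$thresholds$life_threatening_triage
  if (is.na(rec$triage_colour) || !rec$triage_colour %in% life_threat)
    return(tr_result("not_applicable"))
  mins <- minutes_between(rec$on_scene_arrival, rec$scene_departure)
  if (is.na(mins)) return(tr_result("not_applicable"))
  if (mins > limit)
    return(tr_result("positive", paste0("time on site ", mins, " min > ", limit,
                                        " min with ", rec$triage_colour, " triage")))
  tr_result("negative")
}

# A4/A5/A6/B2/L2/L3 — environment-flag triggers: positive iff the flag is set
eval_flag <- function(rec, config, flag) {
  if (isTRUE(rec[[flag]]))
    return(tr_result("positive", paste0(flag, " = TRUE")))
  tr_result("negative")
}

# A7 — "other": a manual annotation passthrough, never auto-positive
eval_manual <- function(rec, config) {
  if (isTRUE(rec$a7_flag))
    return(tr_result("positive", "manual annotation"))
  tr_result("negative")
}

# B1A — SX-ABCDE: positive when any step was not assessed, or assessed but the
# identified issue not addressed
eval_b1a <- function(rec, config) {
  steps <- c(scene_safety = "sx_scene_safety", X = "sx_x", A = "sx_a",
             B = "sx_b", C = "sx_c", D = "sx_d", E = "sx_e")
  status <- map_chr(steps, function(cl) as.character(rec[[cl]]))
  offending <- status %in% c("not_assessed", "assessed_not_addressed")
  offending[is.na(status)] <- FALSE
  if (!any(offending)) return(tr_result("negative"))
  tr_result("positive", paste0("step ", names(steps)[offending], ": ",
                               status[offending]))
}

op_holds <- function(observed, op, value) {
  if (is.na(observed)) return(FALSE)
  switch(op,
         lt = observed < value, le = observed <= value,
         gt = observed > value, ge = observed >= value,
         eq = observed == value,
         abort(paste0("unknown comparator in B1B rule: ", op)))
}

# B1B — condition-specific assessment/intervention rules from the vocabulary:
# each rule names a chief complaint, a vital-sign condition and a required
# intervention (drug); positive when the condition holds and the intervention
# is absent. not_applicable when no rule's condition is triggered.
eval_b1b <- function(rec, config) {
  if (!is.na(rec$override_b1b))
    return(if (isTRUE(rec$override_b1b))
      tr_result("positive", "manual override") else tr_result("negative"))
  rules <- config$vocabulary$b1b_rules
  drugs <- field1(rec, "drugs")
  given <- if (is.data.frame(drugs)) drugs$drug_code else character()
  evidence <- character(); applicable <- FALSE
  for (rule in rules) {
    if (is.na(rec$chief_complaint) || rec$chief_complaint != rule$complaint) next
    cond <- rule$when
    if (!op_holds(rec[[cond$field]], cond$op, cond$value)) next
    applicable <- TRUE
    if (!rule$requires_drug %in% given)
      evidence <- c(evidence, paste0(rule$id, ": ", cond$field, " ",
                                     rec[[cond$field]], " without ", rule$requires_drug))
  }
  if (length(evidence)) return(tr_result("positive", evidence))
  if (applicable) return(tr_result("negative"))
  tr_result("not_applicable")
}

# B1C — absence of measured vital signs: the five core vitals, plus blood
# glucose when indicated (loss of consciousness, seizure)
eval_b1c <- function(rec, config) {
  voc <- config$vocabulary
  required <- voc$core_vitals
  if (!is.na(rec$chief_complaint) &&
      rec$chief_complaint %in% voc$glucose_indicated_complaints)
    required <- c(required, "blood_glucose")
  absent <- required[map_lgl(required, function(v) is.na(rec[[v]]))]
  if (!length(absent)) return(tr_result("negative"))
  tr_result("positive", paste0("vital sign not documented: ", absent))
}

# B1D — absence of relevant clinical examination for the chief complaint;
# complaints without a configured examination requirement are not applicable
eval_b1d <- function(rec, config) {
  exam_map <- config$vocabulary$exam_map
  cc <- rec$chief_complaint
  if (is.na(cc) || !cc %in% names(exam_map)) return(tr_result("not_applicable"))
  required <- unlist(exam_map[[cc]])
  done <- field1(rec, "examinations")
  missing <- setdiff(required, done)
  if (!length(missing)) return(tr_result("negative"))
  tr_result("positive", paste0("examination missing for ", cc, ": ", missing))
}

# B3 — deterioration during transport: a vital crossing into its configured
# red zone between the first and last panel, having started outside it; an
# explicit deterioration annotation also counts. Fewer than two panels:
# not applicable.
eval_b3 <- function(rec, config) {
  if (!is.na(rec$override_b3))
    return(if (isTRUE(rec$override_b3))
      tr_result("positive", "manual override") else tr_result("negative"))
  if (isTRUE(rec$deterioration_noted))
    return(tr_result("positive", "deterioration noted during transport"))
  panels <- field1(rec, "panels")
  if (!is.data.frame(panels) || nrow(panels) < 2)
    return(tr_result("not_applicable"))
  panels <- panels[order(panels$minute), ]
  first <- panels[1, ]; last <- panels[nrow(panels), ]
  bounds <- config$vocabulary$deterioration_red_bounds
  evidence <- character()
  for (vital in names(bounds)) {
    b <- bounds[[vital]]
    in_red <- function(x) {
      if (is.na(x)) return(NA)
      (!is.null(b$low) && x < b$low) || (!is.null(b$high) && x > b$high)
    }
    started <- in_red(first[[vital]]); ended <- in_red(last[[vital]])
    if (isTRUE(ended) && identical(started, FALSE))
      evidence <- c(evidence, paste0(vital, " ", first[[vital]], " -> ",
                                     last[[vital]], " (red zone)"))
  }
  if (length(evidence)) return(tr_result("positive", evidence))
  tr_result("negative")
}

# B4 — telephone interpreter not used despite a language barrier
eval_b4 <- function(rec, config) {
  if (!isTRUE(rec$language_barrier_present)) return(tr_result("not_applicable"))
  if (isTRUE(rec$interpreter_used)) return(tr_result("negative"))
  tr_result("positive", "language barrier without interpreter use")
}

# B5 — triage inconsistency: the patient went from the ED directly to
# definitive care (thrombolysis, PCI, intensive care) after the physician's
# assessment
eval_b5 <- function(rec, config) {
  if (!isTRUE(rec$conveyed)) return(tr_result("not_applicable"))
  if (is.na(rec$ed_direct_to_definitive_care)) return(tr_result("not_applicable"))
  definitive <- c("thrombolysis", "pci", "intensive_care")
  if (isTRUE(rec$ed_direct_to_definitive_care) &&
      !is.na(rec$ed_definitive_care_type) &&
      rec$ed_definitive_care_type %in% definitive)
    return(tr_result("positive", paste0("direct to definitive care: ",
                                        rec$ed_definitive_care_type)))
  tr_result("negative")
}

# B6 — non-conveyance after EMS assessment
eval_b6 <- function(rec, config) {
  if (is.na(rec$conveyed)) return(tr_result("not_applicable"))
  if (!rec$conveyed)
    return(tr_result("positive", "patient not conveyed after EMS assessment"))
  tr_result("negative")
}

# B6 subtrigger — return within 72 h, only assessable for non-conveyed records
eval_b6_return <- function(rec, config, returns_map) {
  if (is.na(rec$conveyed) || rec$conveyed) return(tr_result("not_applicable"))
  hit <- returns_map$return_within_window[match(rec$record_id, returns_map$record_id)]
  if (is.na(hit))
    abort(paste0("record ", rec$record_id, " absent from the return linkage map"))
  if (hit)
    return(tr_result("positive", "same patient returned within 72 h of non-conveyance"))
  tr_result("negative")
}

# B7 — alternative mode of transport to definitive care
eval_b7 <- function(rec, config) {
  if (!isTRUE(rec$conveyed)) return(tr_result("not_applicable"))
  alternative <- c("patient_transport", "seated_transport", "single_responder",
                   "own_transportation")
  if (!is.na(rec$conveyance_mode) && rec$conveyance_mode %in% alternative)
    return(tr_result("positive", paste0("alternative transport mode: ",
                                        rec$conveyance_mode)))
  tr_result("negative")
}

# B8 — destination deviates from local guidelines
eval_b8 <- function(rec, config) {
  if (!is.na(rec$override_b8))
    return(if (isTRUE(rec$override_b8))
      tr_result("positive", "manual override") else tr_result("negative"))
  if (!isTRUE(rec$conveyed) || is.na(rec$destination_per_guideline))
    return(tr_result("not_applicable"))
  if (!rec$destination_per_guideline)
    return(tr_result("positive", paste0("destination outside guideline: ",
                                        rec$destination %||% "unknown")))
  tr_result("negative")
}

# L1 — unfavourable/inappropriate drug treatment against the configured
# formulary (dose range, listed indications) or an explicit non-conform mark;
# drugs absent from the formulary are logged as not evaluable, never positive
eval_l1 <- function(rec, config) {
  if (!is.na(rec$override_l1))
    return(if (isTRUE(rec$override_l1))
      tr_result("positive", "manual override") else tr_result("negative"))
  drugs <- field1(rec, "drugs")
  if (!is.data.frame(drugs) || nrow(drugs) == 0) return(tr_result("not_applicable"))
  formulary <- config$vocabulary$formulary
  evidence <- character(); evaluable <- FALSE
  for (i in seq_len(nrow(drugs))) {
    d <- drugs[i, ]
    if (identical(d$guideline_conform, FALSE)) {
      evaluable <- TRUE
      evidence <- c(evidence, paste0(d$drug_code, ": marked not guideline-conform"))
      next
    }
    rule <- formulary[[d$drug_code]]
    if (is.null(rule)) next  # outside formulary: not evaluable
    evaluable <- TRUE
    if (!is.na(d$dose) && (d$dose < rule$min_dose || d$dose > rule$max_dose))
      evidence <- c(evidence, paste0(d$drug_code, ": dose ", d$dose, " ", d$unit,
                                     " outside [", rule$min_dose, ", ",
                                     rule$max_dose, "]"))
    if (!is.na(d$indication) && !d$indication %in% unlist(rule$indications))
      evidence <- c(evidence, paste0(d$drug_code, ": indication '", d$indication,
                                     "' not listed"))
  }
  if (length(evidence)) return(tr_result("positive", evidence))
  if (evaluable) return(tr_result("negative"))
  tr_result("not_applicable")
}

evaluate_one <- function(rec, entry, config, returns_map) {
  switch(entry$kind,
    documentation = eval_a1(rec, config),
    response_time = eval_a2(rec, config),
    time_on_site = eval_a3(rec, config),
    flag = eval_flag(rec, config, entry$flag),
    manual = eval_manual(rec, config),
    sxabcde = eval_b1a(rec, config),
    condition_rules = eval_b1b(rec, config),
    absent_vitals = eval_b1c(rec, config),
    absent_examination = eval_b1d(rec, config),
    deterioration = eval_b3(rec, config),
    interpreter = eval_b4(rec, config),
    triage_inconsistency = eval_b5(rec, config),
    nonconveyance = eval_b6(rec, config),
    return_72h = eval_b6_return(rec, config, returns_map),
    alternative_transport = eval_b7(rec, config),
    destination = eval_b8(rec, config),
    drug = eval_l1(rec, config),
    abort(paste0("no evaluator for trigger kind: ", entry$kind))
  )
}

#' Screen one record against the active trigger registry
#'
#' Applies every active trigger rule to the record, then resolves aggregate
#' triggers (B1 is positive when any of its B1A-B1D subtriggers is positive,
#' not applicable when every subtrigger is not applicable). Screening is a
#' pure function of the record and configuration: repeated runs are identical.
#'
#' @param record a one-row `ems_records` tibble.
#' @param config an [att_config()].
#' @param returns_map return-linkage map from [link_returns()]; required when
#'   the B6 72-h return subtrigger is active.
#' @return tibble with one row per active trigger: `record_id`, `trigger_id`,
#'   `status` (`positive`/`negative`/`not_applicable`), `evidence`.
#' @export
screen_record <- function(record, config = att_config(), returns_map = NULL) {
  registry <- config$registry
  active <- registry[registry$active, ]
  rec <- as.list(record[1, ])
  rec$record_id <- record$record_id[1]
  is_agg <- active$kind == "aggregate"
  ids <- active$trigger_id
  status <- character(length(ids))
  evidence <- rep(NA_character_, length(ids))
  for (i in which(!is_agg)) {
    entry <- list(trigger_id = ids[i], kind = active$kind[i], flag = active$flag[i])
    r <- evaluate_one(rec, entry, config, returns_map)
    status[i] <- r$status
    evidence[i] <- r$evidence
  }
  for (i in which(is_agg)) {
    sub_i <- match(active$subtriggers[[i]], ids)
    sub_status <- status[sub_i]
    status[i] <- if (any(sub_status == "positive")) "positive"
      else if (all(sub_status == "not_applicable")) "not_applicable"
      else "negative"
    if (status[i] == "positive")
      evidence[i] <- paste0("subtrigger positive: ",
                            paste(ids[sub_i][sub_status == "positive"], collapse = ", "))
  }
  tibble(record_id = rec$record_id, trigger_id = ids,
         status = status, evidence = evidence)
}

#' Screen a record set
#'
#' Runs [screen_record()] over every record. When the 72-h return subtrigger is
#' active and no `returns_map` is supplied, the map is computed from the full
#' record set with [link_returns()] before screening.
#'
#' @param records an `ems_records` tibble.
#' @param config an [att_config()].
#' @param returns_map optional precomputed [link_returns()] output.
#' @return an `att_screening` tibble (`record_id`, `trigger_id`, `status`,
#'   `evidence`), one row per record x active trigger.
#' @export
screen_records <- function(records, config = att_config(), returns_map = NULL) {
  needs_returns <- any(config$registry$kind == "return_72h" & config$registry$active)
  if (needs_returns && is.null(returns_map)) returns_map <- link_returns(records)
  out <- bind_rows(lapply(seq_len(nrow(records)), function(i)
    screen_record(records[i, ], config, returns_map)))
  class(out) <- unique(c("att_screening", class(out)))
  out
}

#' Per-record positive-trigger counts
#'
#' @param screening an `att_screening` tibble from [screen_records()].
#' @return tibble `record_id`, `positive_count`, `positive_triggers`
#'   (comma-separated ids).
#' @export
screening_summary <- function(screening) {
  screening |>
    group_by(.data$record_id) |>
    summarise(
      positive_count = sum(.data$status == "positive"),
      positive_triggers = paste(.data$trigger_id[.data$status == "positive"],
                                collapse = ","),
      .groups = "drop")
}
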