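#' @name synthetic-data
#' @title Synthetic EMS cohorts with known ground truth
#'
#' @description
#' Generates schema-valid ambulance mission records in which every trigger
#' condition is planted deliberately: a planted trigger's record fields are
#' set so the rule fires, a non-planted trigger's fields so it does not. The
#' generator therefore produces, alongside the records, a ground-truth
#' manifest of planted trigger positives, per-trigger incident classes and
#' 72-hour return flags, against which the whole pipeline (screening,
#' classification, sampling, statistics) can be checked exactly.
#'
#' Default prevalences, incident-class mixes and demographic margins emulate
#' the frequencies observed when the trigger tool was applied to 900 reviewed
#' ambulance records from three Swedish EMS organisations. Triggers are
#' planted independently except for structural couplings (a response-time
#' violation needs a priority-1 dispatch, an on-scene-time violation a red
#' triage, a 72-h return a non-conveyance, and so on), which are enforced by
#' conditional planting so the marginal rates still meet their targets.
NULL

default_trigger_prevalence <- function() {
  c(A1 = 128, A2 = 26, A3 = 19, A4 = 0, A5 = 6, A6 = 3, A7 = 0,
    B1A = 96, B1B = 24, B1C = 70, B1D = 144, B2 = 0, B3 = 1, B4 = 12,
    B5 = 8, B6 = 185, B7 = 32, B8 = 2, L1 = 2, L2 = 0, L3 = 0) / 891
}

default_incident_model <- function() {
  list(
    A1  = c(near_miss = 118, no_harm = 7,  harmful = 0) / 128,
    A2  = c(near_miss = 21,  no_harm = 1,  harmful = 1) / 26,
    A3  = c(near_miss = 16,  no_harm = 0,  harmful = 0) / 19,
    A4  = c(near_miss = 0,   no_harm = 0,  harmful = 0),
    A5  = c(near_miss = 1,   no_harm = 0,  harmful = 0),
    A6  = c(near_miss = 1,   no_harm = 0,  harmful = 0),
    A7  = c(near_miss = 0,   no_harm = 0,  harmful = 0),
    B1A = c(near_miss = 84,  no_harm = 11, harmful = 1) / 96,
    B1B = c(near_miss = 16,  no_harm = 8,  harmful = 0) / 24,
    B1C = c(near_miss = 60,  no_harm = 6,  harmful = 0) / 70,
    B1D = c(near_miss = 131, no_harm = 9,  harmful = 0) / 144,
    B2  = c(near_miss = 0,   no_harm = 0,  harmful = 0),
    B3  = c(near_miss = 1,   no_harm = 0,  harmful = 0),
    B4  = c(near_miss = 10,  no_harm = 1,  harmful = 0) / 12,
    B5  = c(near_miss = 4,   no_harm = 4,  harmful = 0) / 8,
    B6  = c(near_miss = 102, no_harm = 5,  harmful = 1) / 185,
    B6_RETURN_72H = c(near_miss = 19, no_harm = 4, harmful = 1) / 28,
    B7  = c(near_miss = 13,  no_harm = 0,  harmful = 0) / 32,
    B8  = c(near_miss = 1,   no_harm = 1,  harmful = 0) / 2,
    L1  = c(near_miss = 0,   no_harm = 2,  harmful = 0) / 2,
    L2  = c(near_miss = 0,   no_harm = 0,  harmful = 0),
    L3  = c(near_miss = 0,   no_harm = 0,  harmful = 0))
}

default_demographics <- function() {
  list(
    sex_female = 0.517,
    priority = c(`1` = 362, `2` = 485, `3` = 43) / 890,
    triage = c(red = 84, orange = 273, yellow = 310, green = 159, blue = 5,
               missing = 60) / 891,
    complaint = c(chest_pain = 0.0999, abdominal_pain = 0.0707, dyspnoea = 0.0976,
                  head_trauma = 0.0483, infection = 0.0685, dizziness = 0.0438,
                  loss_of_consciousness = 0.030, seizure = 0.020, other = 0.5212),
    # beta(2.2, 1.3) over 18-96 years puts the median near 68 with quartiles
    # near 55 and 82, matching the adult, elderly-skewed review case mix
    age_beta = c(2.2, 1.3), age_range = c(18, 96))
}

#' Specification of a synthetic cohort
#'
#' @param n_records number of candidate primary missions (default 900).
#' @param seed master seed; all generator randomness derives from it.
#' @param start_month first calendar month, `"YYYY-MM"`.
#' @param n_months number of months spanned (default 12).
#' @param exclusion_rate share of records planted to violate the review's
#'   inclusion criteria (paediatric age or non-primary mission); exactly
#'   `round(n_records * exclusion_rate)` records are planted. Default 1%,
#'   which at the default `n_records` leaves 891 included records.
#' @param trigger_prevalence named vector of target marginal planting rates
#'   per trigger id (defaults emulate the observed review frequencies).
#' @param return_rate_72h probability of a 72-h return among non-conveyed
#'   records (default 0.151).
#' @param incident_model named list; per trigger, probabilities that a planted
#'   positive is linked to a near miss / no-harm / harmful incident (the
#'   remainder is "no incident"). Defaults emulate the observed per-trigger
#'   class mixes.
#' @param demographics list of demographic margins (sex, priority, triage,
#'   chief complaint, age distribution); see `default_demographics()`.
#' @return a list of class `att_cohort_spec`.
#' @export
cohort_spec <- function(n_records = 900, seed = 1, start_month = "2022-01",
                        n_months = 12, exclusion_rate = 0.01,
                        trigger_prevalence = default_trigger_prevalence(),
                        return_rate_72h = 28 / 185,
                        incident_model = default_incident_model(),
                        demographics = default_demographics()) {
  if (n_records < 1) abort("n_records must be >= 1")
  if (any(trigger_prevalence < 0 | trigger_prevalence > 1))
    abort("trigger prevalences must lie in [0, 1]")
  if (return_rate_72h < 0 || return_rate_72h > 1)
    abort("return_rate_72h must lie in [0, 1]")
  sums <- map_dbl(incident_model, sum)
  if (any(sums > 1 + 1e-9))
    abort("incident-class probabilities must sum to <= 1 per trigger")
  no_model <- setdiff(c(names(trigger_prevalence), "B6_RETURN_72H"),
                      names(incident_model))
  if (length(no_model))
    abort(paste0("incident_model missing triggers: ",
                 paste(no_model, collapse = ", ")))
  # structural feasibility: conditional planting probabilities must be <= 1
  dem <- demographics
  p <- trigger_prevalence
  checks <- c(
    "A2 prevalence exceeds the priority-1 share" =
      p[["A2"]] <= dem$priority[["1"]],
    "A3 prevalence exceeds the red-triage share" =
      p[["A3"]] <= dem$triage[["red"]],
    "B1B prevalence exceeds the share of complaints with condition rules" =
      p[["B1B"]] <= dem$complaint[["loss_of_consciousness"]] + dem$complaint[["infection"]],
    "B1D prevalence exceeds the share of complaints with examination requirements" =
      p[["B1D"]] <= sum(dem$complaint[c("chest_pain", "abdominal_pain", "dyspnoea",
                                        "head_trauma", "dizziness",
                                        "loss_of_consciousness", "seizure")]),
    "B5/B7/B8 prevalences exceed the conveyed share" =
      max(p[["B5"]], p[["B7"]], p[["B8"]]) <= 1 - p[["B6"]])
  if (!all(checks))
    abort(paste0("infeasible cohort spec: ",
                 paste(names(checks)[!checks], collapse = "; ")))
  structure(list(n_records = as.integer(n_records), seed = as.integer(seed),
                 start_month = start_month, n_months = as.integer(n_months),
                 exclusion_rate = exclusion_rate,
                 trigger_prevalence = trigger_prevalence,
                 return_rate_72h = return_rate_72h,
                 incident_model = incident_model, demographics = demographics),
            class = "att_cohort_spec")
}

draw_class <- function(probs) {
  classes <- c("near_miss", "no_harm_incident", "harmful_incident", "none")
  sample(classes, 1, prob = c(probs, max(0, 1 - sum(probs))))
}

severity_max <- function(classes) {
  lv <- c(no_incident = 0, near_miss = 1, no_harm_incident = 2, harmful_incident = 3)
  names(lv)[max(lv[classes]) + 1]
}

assemble_records <- function(rows) {
  template <- rows[[1]]
  cols <- lapply(names(template), function(nm) {
    vals <- lapply(rows, `[[`, nm)
    if (nm %in% c("panels", "examinations", "drugs")) {
      lapply(vals, `[[`, 1L)
    } else if (inherits(template[[nm]], "POSIXct")) {
      do.call(c, vals)
    } else {
      unlist(vals, use.names = FALSE)
    }
  })
  out <- tibble::new_tibble(setNames(cols, names(template)), nrow = length(rows))
  class(out) <- unique(c("ems_records", class(out)))
  out
}

#' Generate a synthetic cohort with its ground-truth manifest
#'
#' Every record starts from the complete, guideline-conform template of
#' [new_ems_record()]; trigger conditions are then planted according to the
#' spec. Planted 72-h returns are materialised as additional return-contact
#' records (same patient key, mission start within the window, mission type
#' `other` so they never enter the analysis cohort). The output is
#' deterministic for a fixed spec and seed.
#'
#' @param spec an [cohort_spec()].
#' @return list of class `att_cohort`: `records` (including return contacts),
#'   `manifest` (per generated record: inclusion flag, planted trigger flags,
#'   planted WHO class and NCC MERP category, incident count), `incidents`
#'   (long table of per-trigger planted incident classes), `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "att_cohort_spec")) abort("spec must be a cohort_spec()")
  p <- spec$trigger_prevalence
  dem <- spec$demographics
  month_starts <- seq(as.POSIXct(paste0(spec$start_month, "-01 00:00:00"), tz = "UTC"),
                      by = "1 month", length.out = spec$n_months + 1)
  template <- as.list(new_ems_record())
  leaf_triggers <- names(p)
  alt_modes <- c(patient_transport = 0.39, seated_transport = 0.32,
                 own_transportation = 0.21, single_responder = 0.08)

  with_mt_seed(spec$seed, {
    n <- spec$n_records
    n_excl <- round(n * spec$exclusion_rate)
    excl_idx <- if (n_excl > 0) sample(n, n_excl) else integer()
    rows <- vector("list", n)
    manifest_rows <- vector("list", n)
    incident_rows <- list()
    return_rows <- list()

    for (i in seq_len(n)) {
      row <- template
      row$record_id <- sprintf("R%05d", i)
      row$patient_key <- sprintf("P%05d", i)
      excluded <- i %in% excl_idx
      row$patient_age <- 18L + as.integer(floor(rbeta(1, dem$age_beta[1], dem$age_beta[2]) *
                                                  diff(dem$age_range)))
      if (excluded) {
        if (runif(1) < 0.5) row$patient_age <- sample(8:17, 1)
        else row$mission_type <- "other"
      }
      row$patient_sex <- if (runif(1) < dem$sex_female) "female" else "male"
      row$dispatch_priority <- as.integer(sample(names(dem$priority), 1, prob = dem$priority))
      row$triage_colour <- sample(names(dem$triage), 1, prob = dem$triage)
      row$chief_complaint <- sample(names(dem$complaint), 1, prob = dem$complaint)

      m <- sample(spec$n_months, 1)
      span <- as.integer(difftime(month_starts[m + 1], month_starts[m], units = "mins"))
      row$mission_start <- month_starts[m] + 60 * sample.int(span - 180L, 1)

      plant <- function(id, eligible = TRUE, share = 1) {
        !excluded && eligible && runif(1) < min(1, p[[id]] / share)
      }
      planted <- setNames(logical(length(leaf_triggers)), leaf_triggers)

      # timeline: response time (A2 applies at priority 1 only), time on site
      # (A3 applies at red triage only); whole minutes, strict thresholds
      planted["A2"] <- plant("A2", row$dispatch_priority == 1L,
                             dem$priority[["1"]])
      resp_min <- if (planted[["A2"]]) sample(21:45, 1)
        else if (row$dispatch_priority == 1L) sample(6:20, 1) else sample(10:40, 1)
      planted["A3"] <- plant("A3", row$triage_colour == "red", dem$triage[["red"]])
      onsite_min <- if (planted[["A3"]]) sample(11:40, 1)
        else if (row$triage_colour == "red") sample(3:10, 1) else sample(5:40, 1)
      row$on_scene_arrival <- row$mission_start + 60 * resp_min
      row$scene_departure <- row$on_scene_arrival + 60 * onsite_min

      # conveyance decision: B6 non-conveyance, else possibly an alternative
      # transport mode (B7), triage inconsistency at the ED (B5) or an
      # off-guideline destination (B8)
      planted["B6"] <- plant("B6")
      planted_return <- FALSE
      if (planted[["B6"]]) {
        row$conveyed <- FALSE; row$conveyance_mode <- "none"
        row$destination <- NA_character_; row$destination_per_guideline <- NA
        row$ed_physician_triage <- NA_character_
        row$ed_direct_to_definitive_care <- NA
        row$ed_definitive_care_type <- NA_character_
        planted_return <- !excluded && runif(1) < spec$return_rate_72h
      } else {
        conveyed_share <- 1 - p[["B6"]]
        planted["B7"] <- plant("B7", share = conveyed_share)
        if (planted[["B7"]])
          row$conveyance_mode <- sample(names(alt_modes), 1, prob = alt_modes)
        planted["B5"] <- plant("B5", share = conveyed_share)
        if (planted[["B5"]]) {
          row$ed_direct_to_definitive_care <- TRUE
          row$ed_definitive_care_type <- sample(c("pci", "thrombolysis", "intensive_care"),
                                                1, prob = c(0.5, 0.25, 0.25))
        }
        planted["B8"] <- plant("B8", share = conveyed_share)
        if (planted[["B8"]]) {
          row$destination_per_guideline <- FALSE
          row$destination <- "district_hospital"
        }
      }

      # documentation (A1) and environment-flag triggers
      planted["A1"] <- plant("A1")
      if (planted[["A1"]]) {
        criteria <- c("doc_chief_complaint", "doc_vital_signs",
                      "doc_assessment_outcome", "doc_interventions",
                      "doc_conveyance_rationale")
        for (cl in sample(criteria, sample(1:2, 1))) row[[cl]] <- FALSE
      }
      flag_fields <- c(A4 = "weather_affected_care", A5 = "equipment_failure",
                       A6 = "resource_shortage", B2 = "physical_harm_in_transport",
                       L2 = "drug_mixup", L3 = "drug_shortage")
      for (id in names(flag_fields)) {
        planted[id] <- plant(id)
        if (planted[[id]]) row[[flag_fields[[id]]]] <- TRUE
      }
      planted["A7"] <- plant("A7")
      if (planted[["A7"]]) row$a7_flag <- TRUE

      # language barrier (B4): planted -> barrier without interpreter; a small
      # share of records has a barrier with interpreter use (negative, not NA)
      planted["B4"] <- plant("B4")
      if (planted[["B4"]]) {
        row$language_barrier_present <- TRUE; row$interpreter_used <- FALSE
      } else if (!excluded && runif(1) < 0.02) {
        row$language_barrier_present <- TRUE; row$interpreter_used <- TRUE
      }

      # SX-ABCDE (B1A)
      planted["B1A"] <- plant("B1A")
      if (planted[["B1A"]]) {
        step <- sample(c("sx_scene_safety", "sx_x", "sx_a", "sx_b", "sx_c",
                         "sx_d", "sx_e"), 1)
        row[[step]] <- sample(c("not_assessed", "assessed_not_addressed"), 1)
      }

      # baseline vitals, complete and out of every red zone
      row$respiratory_rate <- sample(12:20, 1)
      row$oxygen_saturation <- sample(94:99, 1)
      row$systolic_bp <- sample(105:160, 1)
      row$diastolic_bp <- sample(60:95, 1)
      row$pulse <- sample(55:110, 1)
      row$temperature <- round(runif(1, 36.0, 37.8), 1)
      glucose_indicated <- row$chief_complaint %in% c("loss_of_consciousness", "seizure")
      row$blood_glucose <- if (glucose_indicated) round(runif(1, 4.5, 8), 1) else NA_real_

      # condition-specific rules (B1B): condition made true and the required
      # intervention withheld; non-planted eligible records keep the condition
      # false so the rule cannot fire
      b1b_eligible <- row$chief_complaint %in% c("loss_of_consciousness", "infection")
      b1b_share <- dem$complaint[["loss_of_consciousness"]] + dem$complaint[["infection"]]
      planted["B1B"] <- plant("B1B", b1b_eligible, b1b_share)
      b1b_field <- NULL
      if (planted[["B1B"]]) {
        if (row$chief_complaint == "loss_of_consciousness") {
          row$blood_glucose <- round(runif(1, 1.5, 3.5), 1); b1b_field <- "blood_glucose"
        } else {
          row$oxygen_saturation <- sample(80:89, 1); b1b_field <- "oxygen_saturation"
        }
      }

      # deterioration during transport (B3): a second panel with the pulse
      # crossing into its red zone; ~10% of other records get a stable second
      # panel so the trigger also sees assessable negatives
      planted["B3"] <- plant("B3")
      # absent vitals (B1C): remove one required vital, avoiding fields other
      # planted rules depend on
      planted["B1C"] <- plant("B1C")
      if (planted[["B1C"]]) {
        candidates <- c("respiratory_rate", "oxygen_saturation", "systolic_bp",
                        "pulse", "temperature")
        if (glucose_indicated) candidates <- c(candidates, "blood_glucose")
        candidates <- setdiff(candidates, b1b_field)
        if (planted[["B3"]]) candidates <- setdiff(candidates, "pulse")
        row[[sample(candidates, 1)]] <- NA_real_
      }

      panel1 <- single_panel(row$respiratory_rate, row$oxygen_saturation,
                             row$systolic_bp, row$pulse)
      if (planted[["B3"]]) {
        panel2 <- panel1; panel2$minute <- 20; panel2$pulse <- 145
        row$panels <- list(bind_rows(panel1, panel2))
      } else if (!excluded && runif(1) < 0.10) {
        panel2 <- panel1; panel2$minute <- 20
        row$panels <- list(bind_rows(panel1, panel2))
      } else {
        row$panels <- list(panel1)
      }

      # relevant examinations (B1D): complaints with configured requirements
      # get the full set unless planted, in which case one is withheld
      exam_req <- list(chest_pain = "ecg",
                       abdominal_pain = c("abdominal_palpation", "abdominal_auscultation"),
                       dyspnoea = "lung_auscultation", head_trauma = "neurological_exam",
                       dizziness = "neurological_exam", loss_of_consciousness = "ecg",
                       seizure = "neurological_exam")
      required <- exam_req[[row$chief_complaint]]
      mapped_share <- sum(dem$complaint[names(exam_req)])
      planted["B1D"] <- plant("B1D", !is.null(required), mapped_share)
      if (is.null(required)) {
        row$examinations <- list(character())
      } else if (planted[["B1D"]]) {
        row$examinations <- list(setdiff(required, sample(required, 1)))
      } else {
        row$examinations <- list(required)
      }

      # drug treatment (L1): planted -> dose outside the formulary range;
      # otherwise either no drugs (not applicable) or one conform treatment
      planted["L1"] <- plant("L1")
      if (planted[["L1"]]) {
        row$drugs <- list(tibble(drug_code = "morphine", dose = 30, unit = "mg",
                                 route = "iv", indication = "pain",
                                 guideline_conform = NA))
      } else if (!excluded && runif(1) < 0.25) {
        row$drugs <- list(tibble(drug_code = "paracetamol", dose = 1000, unit = "mg",
                                 route = "po", indication = "pain",
                                 guideline_conform = TRUE))
      }

      # per-trigger incident classes and the record-level WHO class
      fired <- c(leaf_triggers[planted],
                 if (planted_return) "B6_RETURN_72H")
      classes <- map_chr(fired, function(id) draw_class(spec$incident_model[[id]]))
      keep <- classes != "none"
      if (any(keep))
        incident_rows[[length(incident_rows) + 1]] <-
          tibble(record_id = row$record_id, trigger_id = fired[keep],
                 incident_class = classes[keep])
      who <- if (any(keep)) severity_max(classes[keep]) else "no_incident"
      merp <- switch(who,
        no_incident = NA_character_,
        near_miss = "AB",
        no_harm_incident = sample(c("C", "D"), 1, prob = c(29, 4)),
        harmful_incident = sample(c("E", "G"), 1))

      if (planted_return) {
        ret <- template
        ret$record_id <- paste0(row$record_id, "_RET")
        ret$patient_key <- row$patient_key
        ret$patient_age <- row$patient_age
        ret$patient_sex <- row$patient_sex
        ret$mission_type <- "other"
        ret$mission_start <- row$mission_start + 60 * sample(60:4320, 1)
        ret$on_scene_arrival <- ret$mission_start + 60 * 12
        ret$scene_departure <- ret$on_scene_arrival + 60 * 18
        return_rows[[length(return_rows) + 1]] <- ret
      }

      rows[[i]] <- row
      manifest_rows[[i]] <- c(
        list(record_id = row$record_id, included = !excluded,
             is_return_visit = FALSE),
        as.list(setNames(unname(planted), paste0("planted_", leaf_triggers))),
        list(planted_B1 = any(planted[c("B1A", "B1B", "B1C", "B1D")]),
             planted_B6_RETURN_72H = planted_return,
             who_class = who, merp_category = merp,
             incident_count = sum(keep)))
    }

    records <- assemble_records(c(rows, return_rows))
    manifest <- bind_rows(lapply(manifest_rows, as_tibble))
    if (length(return_rows)) {
      ret_manifest <- tibble(record_id = map_chr(return_rows, "record_id"),
                             included = FALSE, is_return_visit = TRUE,
                             who_class = "no_incident",
                             merp_category = NA_character_, incident_count = 0L)
      for (cl in grep("^planted_", names(manifest), value = TRUE))
        ret_manifest[[cl]] <- FALSE
      manifest <- bind_rows(manifest, ret_manifest[, names(manifest)])
    }
    incidents <- if (length(incident_rows)) bind_rows(incident_rows)
      else tibble(record_id = character(), trigger_id = character(),
                  incident_class = character())
    structure(list(records = records, manifest = manifest,
                   incidents = incidents, spec = spec),
              class = "att_cohort")
  })
}

#' A simulated primary reviewer
#'
#' @param sensitivity probability that a truly positive trigger cell is marked
#'   positive.
#' @param specificity probability that a truly negative cell is marked
#'   negative.
#' @param seed seed for the reviewer's private randomness.
#' @return a list of class `att_rater_model`.
#' @export
rater_model <- function(sensitivity, specificity, seed) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1)
    abort("sensitivity and specificity must lie in [0, 1]")
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 seed = as.integer(seed)), class = "att_rater_model")
}

#' Binary truth grid from a screening result
#'
#' Collapses the three-valued screening statuses to the binary judgement an
#' inter-rater comparison uses: a cell is positive when the trigger fired,
#' negative otherwise (including not-applicable cells).
#'
#' @param screening an `att_screening` tibble.
#' @return tibble `record_id`, `trigger_id`, `positive`.
#' @export
screening_truth_grid <- function(screening) {
  tibble(record_id = screening$record_id, trigger_id = screening$trigger_id,
         positive = screening$status == "positive")
}

#' Simulate two independent raters over a truth grid
#'
#' Each cell of the truth grid is perturbed independently per rater: a true
#' positive is kept with the rater's sensitivity, a true negative with the
#' rater's specificity. Deterministic per rater seed.
#'
#' @param truth tibble `record_id`, `trigger_id`, `positive` (for example from
#'   [screening_truth_grid()]).
#' @param model1,model2 [rater_model()]s.
#' @return list of two assessment grids, same shape as `truth`.
#' @export
simulate_raters <- function(truth, model1, model2) {
  perturb <- function(model) {
    with_mt_seed(model$seed, {
      flip_pos <- runif(nrow(truth)) < model$sensitivity
      flip_neg <- runif(nrow(truth)) < model$specificity
      mutate(truth, positive = ifelse(.data$positive, flip_pos, !flip_neg))
    })
  }
  list(rater1 = perturb(model1), rater2 = perturb(model2))
}

#' Derive reviewer judgement tables from the ground-truth manifest
#'
#' Turns the planted incident classes into the primary/secondary judgement
#' files the review workflow consumes, deterministically: running the
#' workflow on these judgements reproduces the manifest's WHO classes exactly.
#'
#' @param cohort an `att_cohort` from [generate_cohort()].
#' @param workflow `"revised"` (default) or `"original"`.
#' @return list `primary`, `secondary` judgement tibbles.
#' @export
simulate_judgements <- function(cohort, workflow = c("revised", "original")) {
  workflow <- match.arg(workflow)
  man <- cohort$manifest[cohort$manifest$included, ]
  incident <- man$who_class != "no_incident"
  merp <- man$merp_category
  if (workflow == "revised") {
    risk <- incident & !merp %in% c("AB", "C")
    primary_cat <- ifelse(incident & !risk, merp, NA_character_)
  } else {
    risk <- incident & !merp %in% "AB"
    primary_cat <- ifelse(incident,
                          ifelse(merp %in% c("AB", "C", "D"), merp, "D"),
                          NA_character_)
  }
  primary <- tibble(record_id = man$record_id,
                    incident_present = incident,
                    risk_of_harm = risk,
                    category = primary_cat,
                    incident_count = as.integer(man$incident_count))
  routed <- if (workflow == "revised") risk else incident & primary_cat %in% c("C", "D")
  sec_harmed <- (merp %in% c("E", "F", "G", "H", "I"))[routed]
  secondary <- tibble(record_id = man$record_id[routed],
                      harmed = sec_harmed,
                      category = merp[routed],
                      harm_type = ifelse(sec_harmed, "delayed_treatment",
                                         NA_character_),
                      preventability = ifelse(sec_harmed, 3L, NA_integer_))
  list(primary = primary, secondary = secondary)
}
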