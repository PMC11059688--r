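# Each block drives one rule (or family) through its positive / negative /
# not-applicable cases, including the strict time boundaries.

expect_status <- function(record, id, status) {
  got <- screen_set(record)
  expect_equal(status_of(got, id), status,
               label = paste0(id, " on ", record$record_id))
  if (status == "positive")
    expect_false(is.na(got$evidence[got$trigger_id == id]))
  invisible(got)
}

test_that("A1 fires on any unmet documentation criterion and lists each one as evidence", {
  expect_status(new_ems_record(), "A1", "negative")
  got <- expect_status(new_ems_record(doc_vital_signs = FALSE), "A1", "positive")
  expect_match(got$evidence[got$trigger_id == "A1"], "vital_signs")
  two <- screen_set(new_ems_record(doc_vital_signs = FALSE, doc_interventions = FALSE))
  expect_match(two$evidence[two$trigger_id == "A1"], "vital_signs")
  expect_match(two$evidence[two$trigger_id == "A1"], "interventions")
})

test_that("A1 is monotone: removing further documentation never turns it negative", {
  doc_cols <- c("doc_chief_complaint", "doc_vital_signs", "doc_assessment_outcome",
                "doc_interventions", "doc_conveyance_rationale")
  set.seed(41)
  for (i in 1:25) {
    absent <- sample(doc_cols, sample(1:4, 1))
    args <- setNames(as.list(rep(FALSE, length(absent))), absent)
    rec <- do.call(new_ems_record, args)
    expect_equal(status_of(screen_set(rec), "A1"), "positive")
    more <- sample(setdiff(doc_cols, absent), 1)
    rec[[more]] <- FALSE
    expect_equal(status_of(screen_set(rec), "A1"), "positive")
  }
})

test_that("A2 response-time rule is strict at 20 min and restricted to priority 1", {
  expect_status(rec_with_times(priority = 1, resp_min = 25), "A2", "positive")
  expect_status(rec_with_times(priority = 1, resp_min = 20), "A2", "negative")
  expect_status(rec_with_times(priority = 2, resp_min = 25), "A2", "not_applicable")
  no_ts <- rec_with_times(priority = 1, resp_min = 25)
  no_ts$on_scene_arrival <- as.POSIXct(NA)
  expect_status(no_ts, "A2", "not_applicable")
})

test_that("A3 on-scene rule is strict at 10 min and applies to life-threatening (red) triage", {
  expect_status(rec_with_times(onsite_min = 15, triage_colour = "red"), "A3", "positive")
  expect_status(rec_with_times(onsite_min = 10, triage_colour = "red"), "A3", "negative")
  expect_status(rec_with_times(onsite_min = 40, triage_colour = "yellow"), "A3", "not_applicable")
})

test_that("environment-flag triggers mirror their record flags", {
  flags <- c(A4 = "weather_affected_care", A5 = "equipment_failure",
             A6 = "resource_shortage", B2 = "physical_harm_in_transport",
             L2 = "drug_mixup", L3 = "drug_shortage")
  base <- screen_set(new_ems_record())
  for (id in names(flags)) expect_equal(status_of(base, id), "negative")
  for (id in names(flags)) {
    rec <- do.call(new_ems_record, setNames(list(TRUE), flags[[id]]))
    expect_status(rec, id, "positive")
  }
})

test_that("B1A fires when any SX-ABCDE step is skipped or unaddressed", {
  expect_status(new_ems_record(), "B1A", "negative")
  got <- expect_status(new_ems_record(sx_b = "not_assessed"), "B1A", "positive")
  expect_match(got$evidence[got$trigger_id == "B1A"], "step B")
  expect_status(new_ems_record(sx_scene_safety = "assessed_not_addressed"),
                "B1A", "positive")
})

test_that("B1B condition rules fire only when the condition holds and the intervention is absent", {
  # hypoglycaemic loss of consciousness without glucose administration
  rec <- new_ems_record(chief_complaint = "loss_of_consciousness", blood_glucose = 2.5)
  expect_status(rec, "B1B", "positive")
  treated <- new_ems_record(
    chief_complaint = "loss_of_consciousness", blood_glucose = 2.5,
    drugs = tibble::tibble(drug_code = "glucose", dose = 30, unit = "g",
                           route = "iv", indication = "hypoglycaemia",
                           guideline_conform = TRUE))
  expect_status(treated, "B1B", "negative")
  normo <- new_ems_record(chief_complaint = "loss_of_consciousness", blood_glucose = 6)
  expect_status(normo, "B1B", "not_applicable")
  expect_status(new_ems_record(), "B1B", "not_applicable")
  # manual override wins over the rules
  forced <- new_ems_record(override_b1b = TRUE)
  expect_status(forced, "B1B", "positive")
})

test_that("B1C requires the five core vitals, plus glucose when indicated by the complaint", {
  expect_status(new_ems_record(), "B1C", "negative")   # glucose not indicated
  got <- expect_status(new_ems_record(temperature = NA_real_), "B1C", "positive")
  expect_match(got$evidence[got$trigger_id == "B1C"], "temperature")
  seizure <- new_ems_record(chief_complaint = "seizure",
                            examinations = "neurological_exam")
  expect_status(seizure, "B1C", "positive")            # glucose indicated, absent
  seizure$blood_glucose <- 5.5
  expect_status(seizure, "B1C", "negative")
})

test_that("B1D requires the complaint-specific examinations and skips unmapped complaints", {
  expect_status(new_ems_record(), "B1D", "negative")   # chest pain with ECG
  got <- expect_status(new_ems_record(examinations = character()), "B1D", "positive")
  expect_match(got$evidence[got$trigger_id == "B1D"], "ecg")
  abdo <- new_ems_record(chief_complaint = "abdominal_pain",
                         examinations = c("abdominal_palpation", "abdominal_auscultation"))
  expect_status(abdo, "B1D", "negative")
  partial <- new_ems_record(chief_complaint = "abdominal_pain",
                            examinations = "abdominal_palpation")
  expect_status(partial, "B1D", "positive")
  expect_status(new_ems_record(chief_complaint = "other", examinations = character()),
                "B1D", "not_applicable")
})

test_that("B1 aggregates its subtriggers as a disjunction and double counting is by design", {
  neg <- screen_set(new_ems_record())
  expect_equal(status_of(neg, "B1"), "negative")
  one <- screen_set(new_ems_record(temperature = NA_real_))
  expect_equal(status_of(one, "B1"), "positive")
  both <- screen_set(new_ems_record(temperature = NA_real_, examinations = character()))
  expect_equal(status_of(both, "B1C"), "positive")
  expect_equal(status_of(both, "B1D"), "positive")
  # one record still counts once for B1
  expect_equal(sum(both$trigger_id == "B1" & both$status == "positive"), 1L)
})

test_that("B3 needs repeated panels and detects a red-zone crossing or an explicit note", {
  expect_status(new_ems_record(), "B3", "not_applicable")  # single panel
  p1 <- tibble::tibble(minute = 0, respiratory_rate = 16, oxygen_saturation = 96,
                       systolic_bp = 130, pulse = 80)
  p2 <- p1; p2$minute <- 20; p2$oxygen_saturation <- 84
  worse <- new_ems_record(panels = dplyr::bind_rows(p1, p2))
  got <- expect_status(worse, "B3", "positive")
  expect_match(got$evidence[got$trigger_id == "B3"], "oxygen_saturation")
  stable <- new_ems_record(panels = dplyr::bind_rows(p1, p1))
  expect_status(stable, "B3", "negative")
  # starting inside the red zone is not a deterioration crossing
  p1b <- p1; p1b$oxygen_saturation <- 85
  p2b <- p1b; p2b$minute <- 20
  expect_status(new_ems_record(panels = dplyr::bind_rows(p1b, p2b)), "B3", "negative")
  expect_status(new_ems_record(deterioration_noted = TRUE), "B3", "positive")
})

test_that("B4 compares interpreter use against the documented language barrier", {
  expect_status(new_ems_record(language_barrier_present = TRUE), "B4", "positive")
  expect_status(new_ems_record(language_barrier_present = TRUE, interpreter_used = TRUE),
                "B4", "negative")
  expect_status(new_ems_record(), "B4", "not_applicable")
})

test_that("B5 fires when the ED sends the patient directly to definitive care", {
  pci <- new_ems_record(ed_direct_to_definitive_care = TRUE,
                        ed_definitive_care_type = "pci")
  expect_status(pci, "B5", "positive")
  expect_status(new_ems_record(), "B5", "negative")   # admitted via normal route
  nc <- new_ems_record(conveyed = FALSE, conveyance_mode = "none")
  expect_status(nc, "B5", "not_applicable")
})

test_that("B6 and its 72-h return subtrigger respect conveyance and the linkage map", {
  conveyed <- screen_set(new_ems_record())
  expect_equal(status_of(conveyed, "B6"), "negative")
  expect_equal(status_of(conveyed, "B6_RETURN_72H"), "not_applicable")

  t0 <- as.POSIXct("2022-05-01 12:00:00", tz = "UTC")
  nc <- new_ems_record(record_id = "NC", patient_key = "PX", conveyed = FALSE,
                       conveyance_mode = "none", mission_start = t0,
                       on_scene_arrival = t0 + 600, scene_departure = t0 + 1800)
  ret <- new_ems_record(record_id = "RET", patient_key = "PX",
                        mission_start = t0 + 48 * 3600,
                        on_scene_arrival = t0 + 48 * 3600 + 600,
                        scene_departure = t0 + 48 * 3600 + 1800)
  got <- screen_set(ems_records(nc, ret))
  expect_equal(status_of(got, "B6", "NC"), "positive")
  expect_equal(status_of(got, "B6_RETURN_72H", "NC"), "positive")
  # a record missing from the linkage map is a configuration error
  expect_error(screen_records(nc, att_cfg,
                              returns_map = tibble::tibble(record_id = "OTHER",
                                                           return_within_window = FALSE)),
               "return linkage map")
})

test_that("B7 flags alternative transport modes for conveyed patients", {
  expect_status(new_ems_record(), "B7", "negative")
  expect_status(new_ems_record(conveyance_mode = "own_transportation"), "B7", "positive")
  expect_status(new_ems_record(conveyed = FALSE, conveyance_mode = "none"),
                "B7", "not_applicable")
})

test_that("B8 uses the destination guideline flag with unknown as not applicable", {
  expect_status(new_ems_record(destination_per_guideline = FALSE), "B8", "positive")
  expect_status(new_ems_record(), "B8", "negative")
  expect_status(new_ems_record(destination_per_guideline = NA), "B8", "not_applicable")
})

test_that("L1 judges administrations against the formulary and ignores unknown drugs", {
  ok <- new_ems_record(drugs = tibble::tibble(
    drug_code = "morphine", dose = 10, unit = "mg", route = "iv",
    indication = "pain", guideline_conform = NA))
  expect_status(ok, "L1", "negative")
  over <- new_ems_record(drugs = tibble::tibble(
    drug_code = "morphine", dose = 30, unit = "mg", route = "iv",
    indication = "pain", guideline_conform = NA))
  expect_status(over, "L1", "positive")
  off_label <- new_ems_record(drugs = tibble::tibble(
    drug_code = "ondansetron", dose = 4, unit = "mg", route = "iv",
    indication = "pain", guideline_conform = NA))
  expect_status(off_label, "L1", "positive")
  expect_status(new_ems_record(), "L1", "not_applicable")   # no drugs given
  unknown <- new_ems_record(drugs = tibble::tibble(
    drug_code = "experimentine", dose = 1, unit = "mg", route = "iv",
    indication = "pain", guideline_conform = NA))
  expect_status(unknown, "L1", "not_applicable")            # not evaluable
})

test_that("screening is complete, deterministic and composes positives per record", {
  rec <- rec_with_times(priority = 1, resp_min = 25, temperature = NA_real_)
  got <- screen_set(rec)
  active <- att_cfg$registry$trigger_id[att_cfg$registry$active]
  expect_setequal(got$trigger_id, active)
  expect_true(all(got$status %in% c("positive", "negative", "not_applicable")))
  # A2 + B1C positive, and B1 through aggregation
  summ <- screening_summary(got)
  expect_equal(summ$positive_count, 3L)
  expect_identical(screen_set(rec), got)
  # positives always carry evidence
  expect_true(all(!is.na(got$evidence[got$status == "positive"])))
})

test_that("the registry profiles control the active trigger set", {
  rrr <- att_registry("rrr900")
  fin <- att_registry("final")
  expect_equal(sum(rrr$active), 23L)
  expect_lt(sum(fin$active), sum(rrr$active))
  expect_false(any(fin$trigger_id[fin$active] %in% c("A4", "B2", "L2", "L3")))
  expect_error(att_registry("nope"), "unknown registry profile")
  scr <- screen_records(new_ems_record(), att_config(registry = att_registry("final")))
  expect_setequal(scr$trigger_id, fin$trigger_id[fin$active])
})
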