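#' @name ems-records
#' @title Structured EMS mission records
#'
#' @description
#' One row per ambulance mission. The schema is reconstructed from the record
#' structure a trigger review needs: dispatch timeline, RETTS-A triage colour,
#' chief complaint, vital-sign panel (with repeated panels for deterioration
#' assessment), SX-ABCDE assessment steps, examinations, drug administrations,
#' conveyance decision, environment flags, documentation completeness flags,
#' emergency-department handover, and a pseudonymous `patient_key` used only
#' for 72-hour return linkage.
#'
#' Complex fields (`examinations`, `drugs`, `panels`) are list-columns; in the
#' CSV serialisation they are carried as JSON-encoded cells, in the JSON
#' serialisation as native arrays/objects.
NULL

# column order of the flat schema; list-columns noted where they occur
ems_schema_columns <- function() {
  c("record_id", "patient_key", "patient_age", "patient_sex",
    "dispatch_priority", "mission_start", "on_scene_arrival", "scene_departure",
    "triage_colour", "chief_complaint", "mission_type",
    "respiratory_rate", "oxygen_saturation", "systolic_bp", "diastolic_bp",
    "pulse", "temperature", "blood_glucose",
    "panels", "examinations",
    "sx_scene_safety", "sx_x", "sx_a", "sx_b", "sx_c", "sx_d", "sx_e",
    "drugs",
    "conveyed", "conveyance_mode", "destination", "destination_per_guideline",
    "weather_affected_care", "equipment_failure", "resource_shortage",
    "physical_harm_in_transport", "drug_mixup", "drug_shortage",
    "language_barrier_present", "interpreter_used",
    "doc_chief_complaint", "doc_vital_signs", "doc_assessment_outcome",
    "doc_interventions", "doc_conveyance_rationale",
    "ed_physician_triage", "ed_direct_to_definitive_care", "ed_definitive_care_type",
    "deterioration_noted", "a7_flag",
    "override_b1b", "override_b3", "override_b8", "override_l1")
}

empty_drugs <- function() {
  tibble(drug_code = character(), dose = double(), unit = character(),
         route = character(), indication = character(),
         guideline_conform = logical())
}

single_panel <- function(respiratory_rate, oxygen_saturation, systolic_bp, pulse) {
  tibble(minute = 0, respiratory_rate = as.double(respiratory_rate),
         oxygen_saturation = as.double(oxygen_saturation),
         systolic_bp = as.double(systolic_bp), pulse = as.double(pulse))
}

#' Build one EMS mission record
#'
#' Starts from a fully complete, guideline-conform template (all documentation
#' present, all SX-ABCDE steps assessed and addressed, required examinations
#' performed, conveyed by ambulance to an in-guideline destination) and applies
#' the overrides given in `...`. On the unmodified template every trigger is
#' negative or not applicable, which makes the template the natural null case
#' for rule tests and the starting point for the synthetic generator.
#'
#' @param ... named field overrides; list-columns (`panels`, `examinations`,
#'   `drugs`) may be given as the bare object (it is wrapped automatically).
#' @return a one-row `ems_records` tibble.
#' @export
new_ems_record <- function(...) {
  start <- as.POSIXct("2022-06-15 10:00:00", tz = "UTC")
  rec <- tibble(
    record_id = "R00001", patient_key = "P00001",
    patient_age = 60L, patient_sex = "female", dispatch_priority = 2L,
    mission_start = start,
    on_scene_arrival = start + 15 * 60,
    scene_departure = start + 35 * 60,
    triage_colour = "yellow", chief_complaint = "chest_pain",
    mission_type = "primary_with_assessment",
    respiratory_rate = 16, oxygen_saturation = 97, systolic_bp = 130,
    diastolic_bp = 80, pulse = 78, temperature = 36.8, blood_glucose = NA_real_,
    panels = list(single_panel(16, 97, 130, 78)),
    examinations = list("ecg"),
    sx_scene_safety = "assessed_and_addressed", sx_x = "assessed_and_addressed",
    sx_a = "assessed_and_addressed", sx_b = "assessed_and_addressed",
    sx_c = "assessed_and_addressed", sx_d = "assessed_and_addressed",
    sx_e = "assessed_and_addressed",
    drugs = list(empty_drugs()),
    conveyed = TRUE, conveyance_mode = "ambulance", destination = "regional_ed",
    destination_per_guideline = TRUE,
    weather_affected_care = FALSE, equipment_failure = FALSE,
    resource_shortage = FALSE, physical_harm_in_transport = FALSE,
    drug_mixup = FALSE, drug_shortage = FALSE,
    language_barrier_present = FALSE, interpreter_used = FALSE,
    doc_chief_complaint = TRUE, doc_vital_signs = TRUE,
    doc_assessment_outcome = TRUE, doc_interventions = TRUE,
    doc_conveyance_rationale = TRUE,
    ed_physician_triage = "yellow", ed_direct_to_definitive_care = FALSE,
    ed_definitive_care_type = "none",
    deterioration_noted = FALSE, a7_flag = FALSE,
    override_b1b = NA, override_b3 = NA, override_b8 = NA, override_l1 = NA
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(rec))
  if (length(unknown))
    abort(paste0("unknown record fields: ", paste(unknown, collapse = ", ")))
  for (nm in names(dots)) {
    value <- dots[[nm]]
    if (nm %in% c("panels", "drugs") && is.data.frame(value)) value <- list(value)
    if (nm == "examinations" && !is.list(value)) value <- list(as.character(value))
    rec[[nm]] <- value
  }
  class(rec) <- c("ems_records", class(rec))
  rec
}

#' Combine several records into one record set
#' @param ... one-row records from [new_ems_record()] or record tibbles.
#' @return an `ems_records` tibble.
#' @export
ems_records <- function(...) {
  out <- bind_rows(...)
  class(out) <- unique(c("ems_records", class(out)))
  out
}

# ---- validation -------------------------------------------------------------

check_enum <- function(tbl, field, allowed, problems, allow_na = FALSE) {
  vals <- as.character(tbl[[field]])
  bad <- which(!vals %in% as.character(allowed) & !(allow_na & is.na(vals)))
  if (length(bad))
    problems <- bind_rows(problems, tibble(
      row = bad, field = field,
      message = paste0("unknown value '", vals[bad], "' (allowed: ",
                       paste(allowed, collapse = ", "), ")")))
  problems
}

check_bounds <- function(tbl, field, lo, hi, problems) {
  v <- tbl[[field]]
  bad <- which(!is.na(v) & (v < lo | v > hi))
  if (length(bad))
    problems <- bind_rows(problems, tibble(
      row = bad, field = field,
      message = paste0("value ", v[bad], " outside physiologic bounds [",
                       lo, ", ", hi, "]")))
  problems
}

#' Validate a record set against the vocabulary
#'
#' Checks mandatory identifiers, enumerated code values, physiologic bounds,
#' timestamp ordering (`mission_start <= on_scene_arrival <= scene_departure`
#' where present), positivity of drug doses and consistency of the conveyance
#' decision (`conveyed = FALSE` implies mode `none`). Invalid rows are dropped;
#' every problem is reported with its row locus and field. No silent coercion
#' is performed.
#'
#' @param records a record tibble (for example from [read_ems_records()]).
#' @param vocabulary an [att_vocabulary()].
#' @return the valid rows as an `ems_records` tibble, with the collected
#'   problems in attribute `"problems"` (tibble `row`, `field`, `message`).
#' @export
validate_ems_records <- function(records, vocabulary = att_vocabulary()) {
  problems <- tibble(row = integer(), field = character(), message = character())
  missing_cols <- setdiff(ems_schema_columns(), names(records))
  if (length(missing_cols))
    abort(paste0("record set is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  records <- as_tibble(records)[, ems_schema_columns()]

  bad_id <- which(is.na(records$record_id) | records$record_id == "")
  if (length(bad_id))
    problems <- bind_rows(problems, tibble(
      row = bad_id, field = "record_id", message = "missing mandatory identifier"))

  cds <- vocabulary$codes
  problems <- check_enum(records, "patient_sex", cds$patient_sex, problems)
  problems <- check_enum(records, "dispatch_priority", cds$dispatch_priority, problems)
  problems <- check_enum(records, "triage_colour", cds$triage_colour, problems)
  problems <- check_enum(records, "conveyance_mode", cds$conveyance_mode, problems)
  problems <- check_enum(records, "mission_type", cds$mission_type, problems)
  problems <- check_enum(records, "chief_complaint", cds$chief_complaint, problems)
  problems <- check_enum(records, "ed_definitive_care_type", cds$definitive_care_type,
                         problems, allow_na = TRUE)
  for (sx in c("sx_scene_safety", "sx_x", "sx_a", "sx_b", "sx_c", "sx_d", "sx_e"))
    problems <- check_enum(records, sx, cds$sxabcde_status, problems)

  for (field in names(vocabulary$bounds)) {
    if (!field %in% names(records)) next
    b <- vocabulary$bounds[[field]]
    problems <- check_bounds(records, field, b[[1]], b[[2]], problems)
  }

  ts_bad <- which(
    (!is.na(records$mission_start) & !is.na(records$on_scene_arrival) &
       records$mission_start > records$on_scene_arrival) |
    (!is.na(records$on_scene_arrival) & !is.na(records$scene_departure) &
       records$on_scene_arrival > records$scene_departure))
  if (length(ts_bad))
    problems <- bind_rows(problems, tibble(
      row = ts_bad, field = "mission_start",
      message = "timestamps out of order (start <= on-scene <= departure required)"))

  conv_bad <- which(!is.na(records$conveyed) & !records$conveyed &
                      records$conveyance_mode != "none")
  if (length(conv_bad))
    problems <- bind_rows(problems, tibble(
      row = conv_bad, field = "conveyance_mode",
      message = "non-conveyed record must have conveyance_mode 'none'"))

  dose_bad <- which(map_lgl(records$drugs, function(d)
    is.data.frame(d) && nrow(d) > 0 && any(!is.na(d$dose) & d$dose <= 0)))
  if (length(dose_bad))
    problems <- bind_rows(problems, tibble(
      row = dose_bad, field = "drugs", message = "drug dose must be > 0"))

  keep_rows <- setdiff(seq_len(nrow(records)), unique(problems$row))
  out <- records[keep_rows, ]
  class(out) <- unique(c("ems_records", class(out)))
  attr(out, "problems") <- problems
  out
}

# ---- serialisation ----------------------------------------------------------

encode_json_cell <- function(x) {
  as.character(jsonlite::toJSON(x, dataframe = "rows", na = "null", digits = NA))
}

decode_examinations <- function(cell) {
  if (is.na(cell) || cell == "" || cell == "[]") return(character())
  as.character(jsonlite::fromJSON(cell))
}

decode_frame <- function(cell, empty) {
  if (is.na(cell) || cell == "" || cell == "[]") return(empty)
  out <- as_tibble(jsonlite::fromJSON(cell))
  for (nm in names(empty)) {
    if (!nm %in% names(out)) out[[nm]] <- empty[[nm]][NA_integer_][seq_len(nrow(out))]
    mode_target <- class(empty[[nm]])[1]
    out[[nm]] <- switch(mode_target,
      character = as.character(out[[nm]]),
      numeric = as.double(out[[nm]]),
      logical = as.logical(out[[nm]]),
      out[[nm]])
  }
  out[, names(empty)]
}

#' Write EMS records to CSV or JSON
#'
#' CSV is UTF-8, comma separated, with a mandatory header row and ISO-8601
#' timestamps; list-valued fields are JSON-encoded cells. A `.json` path writes
#' one array of record objects with native nested arrays.
#'
#' @param records an `ems_records` tibble.
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_ems_records <- function(records, path) {
  flat <- as_tibble(records)
  flat$mission_start <- fmt_timestamp(flat$mission_start)
  flat$on_scene_arrival <- fmt_timestamp(flat$on_scene_arrival)
  flat$scene_departure <- fmt_timestamp(flat$scene_departure)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    flat$panels <- map_chr(flat$panels, encode_json_cell)
    flat$examinations <- map_chr(flat$examinations, encode_json_cell)
    flat$drugs <- map_chr(flat$drugs, encode_json_cell)
    readr::write_csv(flat, path, na = "")
  }
  invisible(path)
}

coerce_flat_records <- function(flat) {
  int_cols <- c("patient_age", "dispatch_priority")
  dbl_cols <- c("respiratory_rate", "oxygen_saturation", "systolic_bp",
                "diastolic_bp", "pulse", "temperature", "blood_glucose")
  lgl_cols <- c("conveyed", "destination_per_guideline",
                "weather_affected_care", "equipment_failure", "resource_shortage",
                "physical_harm_in_transport", "drug_mixup", "drug_shortage",
                "language_barrier_present", "interpreter_used",
                "doc_chief_complaint", "doc_vital_signs", "doc_assessment_outcome",
                "doc_interventions", "doc_conveyance_rationale",
                "ed_direct_to_definitive_care", "deterioration_noted", "a7_flag",
                "override_b1b", "override_b3", "override_b8", "override_l1")
  chr_cols <- setdiff(ems_schema_columns(),
                      c(int_cols, dbl_cols, lgl_cols,
                        "mission_start", "on_scene_arrival", "scene_departure",
                        "panels", "examinations", "drugs"))
  for (nm in int_cols) flat[[nm]] <- as.integer(flat[[nm]])
  for (nm in dbl_cols) flat[[nm]] <- as.double(flat[[nm]])
  for (nm in lgl_cols) flat[[nm]] <- as.logical(flat[[nm]])
  for (nm in chr_cols) {
    v <- as.character(flat[[nm]])
    v[!is.na(v) & v == ""] <- NA_character_
    flat[[nm]] <- v
  }
  for (nm in c("mission_start", "on_scene_arrival", "scene_departure"))
    flat[[nm]] <- parse_timestamp(as.character(flat[[nm]]))
  flat
}

#' Read and validate EMS records from CSV or JSON
#'
#' The inverse of [write_ems_records()]. Rows failing validation are dropped
#' and reported in the `"problems"` attribute with row locus, field and
#' message; malformed timestamps and unknown enum values are never silently
#' coerced.
#'
#' @param path input path ending in `.csv` or `.json`.
#' @param vocabulary an [att_vocabulary()] used for validation.
#' @return a validated `ems_records` tibble (attribute `"problems"` collects
#'   parse/validation errors).
#' @export
read_ems_records <- function(path, vocabulary = att_vocabulary()) {
  if (!file.exists(path)) abort(paste0("record file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE, simplifyVector = TRUE)
    flat <- as_tibble(raw)
    flat$panels <- map(flat$panels, function(p)
      decode_frame(encode_json_cell(p), single_panel(NA, NA, NA, NA)[0, ]))
    flat$examinations <- map(flat$examinations, function(e) as.character(unlist(e)))
    flat$drugs <- map(flat$drugs, function(d)
      decode_frame(encode_json_cell(d), empty_drugs()))
  } else {
    flat <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                            progress = FALSE)
    flat$panels <- map(flat$panels, decode_frame,
                       empty = single_panel(NA, NA, NA, NA)[0, ])
    flat$examinations <- map(flat$examinations, decode_examinations)
    flat$drugs <- map(flat$drugs, decode_frame, empty = empty_drugs())
  }
  flat <- coerce_flat_records(flat)
  validate_ems_records(flat, vocabulary)
}

# ---- inclusion and linkage --------------------------------------------------

#' Review inclusion criteria
#'
#' A record enters the review when the patient is an adult (age >= 18) and the
#' mission is a primary mission with a patient assessment. Records with a
#' missing age are excluded (and counted in the `"n_missing_age"` attribute)
#' rather than guessed at.
#'
#' @param records an `ems_records` tibble.
#' @return logical vector, one element per record.
#' @export
apply_inclusion_criteria <- function(records) {
  ok <- !is.na(records$patient_age) & records$patient_age >= 18 &
    !is.na(records$mission_type) & records$mission_type == "primary_with_assessment"
  structure(ok, n_missing_age = sum(is.na(records$patient_age)))
}

#' Link 72-hour returns after non-conveyance
#'
#' For every non-conveyed record, looks for another mission by the same
#' pseudonymous patient within the half-open window
#' `(mission_start, mission_start + window_hours]`; the index contact itself
#' never counts as its own return. Conveyed records map to `FALSE`. Records
#' without a `patient_key` cannot be linked; they are excluded and reported
#' via a warning.
#'
#' @param records an `ems_records` tibble (the full record set, including any
#'   return contacts that are not part of the analysis cohort).
#' @param window_hours linkage window, default 72.
#' @return tibble `record_id`, `return_within_window` (logical), one row per
#'   input record that carries a patient key.
#' @export
link_returns <- function(records, window_hours = 72) {
  no_key <- is.na(records$patient_key) | records$patient_key == ""
  if (any(no_key))
    warn(paste0(sum(no_key), " record(s) without patient_key excluded from return linkage"))
  recs <- records[!no_key, c("record_id", "patient_key", "mission_start", "conveyed")]
  window_min <- window_hours * 60
  by_key <- split(seq_len(nrow(recs)), recs$patient_key)
  returned <- logical(nrow(recs))
  for (idx in by_key) {
    if (length(idx) < 2) next
    starts <- recs$mission_start[idx]
    for (j in seq_along(idx)) {
      gaps <- minutes_between(starts[j], starts[-j])
      returned[idx[j]] <- any(!is.na(gaps) & gaps > 0 & gaps <= window_min)
    }
  }
  tibble(record_id = recs$record_id,
         return_within_window = returned & !is.na(recs$conveyed) & !recs$conveyed) |>
    arrange(.data$record_id)
}
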