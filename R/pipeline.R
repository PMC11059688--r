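#' @name pipeline
#' @title End-to-end runs and report writers
#'
#' @description
#' Thin orchestration over the library: screen a record file, compute the
#' statistics reports, or run the whole synthetic study (generate, sample,
#' screen, classify, report) into an output directory together with a run
#' manifest (seed, configuration, package version) sufficient to reproduce the
#' run. A command-line wrapper over these functions ships in
#' `inst/cli/att.R`; diagnostics go to stderr, reports only to files.
NULL

#' Screen a record file against the trigger registry
#'
#' @param records_path CSV or JSON record file (see [read_ems_records()]).
#' @param out_path optional output CSV for the per-record, per-trigger results.
#' @param profile registry profile (`"rrr900"` or `"final"`).
#' @param vocabulary_path,registry_path optional configuration overrides.
#' @return the `att_screening` tibble, invisibly when `out_path` is given.
#' @export
run_screen <- function(records_path, out_path = NULL, profile = "rrr900",
                       vocabulary_path = NULL, registry_path = NULL) {
  voc <- att_vocabulary(vocabulary_path)
  config <- att_config(voc, att_registry(profile, registry_path))
  records <- read_ems_records(records_path, voc)
  problems <- attr(records, "problems")
  if (nrow(problems))
    warn(paste0(nrow(problems), " validation problem(s); invalid rows dropped"))
  if (nrow(records) == 0) warn("record file contains no valid records")
  returns_map <- link_returns(records)
  included <- apply_inclusion_criteria(records)
  screening <- screen_records(records[included, ], config, returns_map)
  if (!is.null(out_path)) {
    readr::write_csv(screening, out_path, na = "")
    return(invisible(screening))
  }
  screening
}

#' Compute and write the statistics reports
#'
#' @param classifications [merge_reviews()] output for the cohort.
#' @param screening `att_screening` tibble for the cohort.
#' @param records cohort `ems_records`.
#' @param raters optional list of two assessment grids (see
#'   [build_confusion_matrix()]); when omitted the agreement section is
#'   skipped with a notice.
#' @param out_dir output directory for CSV/JSON reports; `NULL` returns the
#'   reports without writing.
#' @param mode presentation mode, `"round"` or `"truncate"`.
#' @return list with the [frequency_report()] tables and, when raters are
#'   given, the [agreement_report()].
#' @export
run_stats <- function(classifications, screening, records, raters = NULL,
                      out_dir = NULL, mode = "round") {
  freq <- frequency_report(classifications, screening, records, mode = mode)
  agreement <- NULL
  if (!is.null(raters)) {
    cm <- build_confusion_matrix(raters[[1]], raters[[2]])
    agreement <- agreement_report(cm, mode = mode)
  } else {
    inform("no rater grids supplied; agreement section omitted")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(freq$who, file.path(out_dir, "who_classes.csv"))
    readr::write_csv(freq$merp, file.path(out_dir, "merp_categories.csv"))
    readr::write_csv(freq$triggers, file.path(out_dir, "trigger_performance.csv"))
    readr::write_csv(freq$demographics, file.path(out_dir, "demographics.csv"), na = "")
    if (!is.null(agreement))
      jsonlite::write_json(
        list(matrix = unclass(agreement$matrix),
             observed_agreement = agreement$observed_agreement,
             kappa = agreement$kappa, pabak = agreement$pabak,
             kappa_band = agreement$kappa_band, pabak_band = agreement$pabak_band),
        file.path(out_dir, "agreement.json"), auto_unbox = TRUE, digits = NA)
  }
  compact(list(frequency = freq, agreement = agreement))
}

#' Run the full synthetic study pipeline
#'
#' Generates a cohort, applies the inclusion criteria, draws the monthly
#' review sample, screens it, classifies incidents from the simulated
#' reviewers' judgements, and writes every artefact plus a reproducibility
#' manifest into `out_dir`. All randomness flows from `seed` through named
#' substreams (cohort, sampling, raters).
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param spec an [cohort_spec()]; its seed is overridden by the `cohort`
#'   substream of `seed`.
#' @param per_month records sampled per calendar month (default 25).
#' @param workflow review workflow version, `"revised"` or `"original"`.
#' @param profile registry profile.
#' @param sample_cohort when `FALSE` (default) the statistics cover the whole
#'   included cohort (the monthly sample is still drawn and written); when
#'   `TRUE` they cover the monthly sample only.
#' @return list with `records`, `manifest`, `sample`, `screening`,
#'   `classifications`, `reports`, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1, spec = NULL, per_month = 25,
                         workflow = c("revised", "original"),
                         profile = "rrr900", sample_cohort = FALSE) {
  workflow <- match.arg(workflow)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(spec)) spec <- cohort_spec(seed = substream_seed(seed, "cohort"))
  else spec$seed <- substream_seed(seed, "cohort")

  cohort <- generate_cohort(spec)
  write_ems_records(cohort$records, file.path(out_dir, "records.csv"))
  readr::write_csv(cohort$manifest, file.path(out_dir, "manifest.csv"), na = "")

  included <- cohort$records[apply_inclusion_criteria(cohort$records), ]
  returns_map <- link_returns(cohort$records)
  buckets <- stratify_by_month(included)
  plan <- sampling_plan(per_month, seed = substream_seed(seed, "sampling"))
  selection <- sample_monthly(buckets, plan)
  readr::write_csv(selection, file.path(out_dir, "sample.csv"))

  analysed <- if (sample_cohort)
    included[included$record_id %in% selection$record_id, ] else included
  config <- att_config(att_vocabulary(), att_registry(profile))
  screening <- screen_records(analysed, config, returns_map)
  readr::write_csv(screening, file.path(out_dir, "screening.csv"), na = "")

  judgements <- simulate_judgements(cohort, workflow)
  keep <- judgements$primary$record_id %in% analysed$record_id
  classifications <- classify_cohort(
    screening, judgements$primary[keep, ],
    judgements$secondary[judgements$secondary$record_id %in% analysed$record_id, ],
    workflow)
  readr::write_csv(classifications, file.path(out_dir, "classifications.csv"), na = "")

  reports <- run_stats(classifications, screening, analysed,
                       out_dir = file.path(out_dir, "reports"))

  run_manifest <- list(
    package = "emstrigger",
    version = as.character(utils::packageVersion("emstrigger")),
    seed = seed,
    substreams = list(cohort = spec$seed,
                      sampling = substream_seed(seed, "sampling")),
    workflow = workflow, profile = profile,
    n_records = spec$n_records, per_month = per_month,
    n_included = nrow(included), n_analysed = nrow(analysed))
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(records = cohort$records, manifest = cohort$manifest,
                 sample = selection, screening = screening,
                 classifications = classifications, reports = reports))
}
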