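#' @name sampling
#' @title Record selection for retrospective review
#'
#' @description
#' The review samples a fixed number of included records per calendar month
#' (default 25) using a seeded Mersenne-Twister stream, the generator R itself
#' uses: `sample()` performs the partial Fisher-Yates draw without
#' replacement. The seed is explicit so selections are reproducible across
#' runs and machines.
NULL

#' Stratify records by calendar month
#'
#' @param records an `ems_records` tibble with `mission_start`.
#' @return named list of record tibbles keyed `"YYYY-MM"`; every record with a
#'   mission start appears in exactly one bucket.
#' @export
stratify_by_month <- function(records) {
  has_ts <- !is.na(records$mission_start)
  if (!all(has_ts))
    warn(paste0(sum(!has_ts), " record(s) without mission_start left unstratified"))
  recs <- records[has_ts, ]
  key <- format(recs$mission_start, "%Y-%m", tz = "UTC")
  out <- split(recs, key)
  out[order(names(out))]
}

#' Sampling plan
#'
#' @param per_month_count records drawn per month bucket (default 25).
#' @param seed integer seed for the Mersenne-Twister stream (mandatory).
#' @param period optional character vector `c(from, to)` of `"YYYY-MM"` keys;
#'   buckets outside the period are skipped.
#' @return a list of class `att_sampling_plan`.
#' @export
sampling_plan <- function(per_month_count = 25, seed, period = NULL) {
  if (per_month_count < 1) abort("per_month_count must be >= 1")
  if (missing(seed) || is.null(seed)) abort("sampling requires an explicit seed")
  structure(list(per_month_count = as.integer(per_month_count),
                 seed = as.integer(seed), period = period),
            class = "att_sampling_plan")
}

#' Draw the monthly sample
#'
#' From each month bucket, draws `min(per_month_count, bucket size)` records
#' without replacement. Buckets smaller than the cap are fully included (a
#' month with few eligible missions is reviewed in full). Buckets are visited
#' in chronological order and record ids within a bucket are put in sorted
#' order before drawing, so the selection depends only on the record set and
#' the seed, never on input row order.
#'
#' @param buckets output of [stratify_by_month()].
#' @param plan an [sampling_plan()].
#' @return tibble `month`, `record_id` of the selected records.
#' @export
sample_monthly <- function(buckets, plan) {
  if (!inherits(plan, "att_sampling_plan")) abort("plan must be a sampling_plan()")
  keys <- sort(names(buckets))
  if (!is.null(plan$period))
    keys <- keys[keys >= plan$period[1] & keys <= plan$period[2]]
  with_mt_seed(plan$seed, {
    picks <- lapply(keys, function(k) {
      ids <- sort(unique(buckets[[k]]$record_id))
      if (!length(ids)) {
        warn(paste0("empty month bucket: ", k))
        return(tibble(month = character(), record_id = character()))
      }
      n_draw <- min(plan$per_month_count, length(ids))
      chosen <- if (length(ids) == 1) ids else sample(ids, n_draw)
      tibble(month = k, record_id = sort(chosen))
    })
    bind_rows(picks)
  })
}
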