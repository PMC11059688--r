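# shared fixtures: one config, light record builders, tiny cached cohort

att_cfg <- att_config()

# screen a (small) record set, computing the return map from the same set
screen_set <- function(records, cfg = att_cfg) {
  screen_records(records, cfg, link_returns(records))
}

status_of <- function(screening, id, record_id = NULL) {
  rows <- screening$trigger_id == id
  if (!is.null(record_id)) rows <- rows & screening$record_id == record_id
  screening$status[rows]
}

# record with a given dispatch priority / response and on-scene durations (min)
rec_with_times <- function(priority = 2L, resp_min = 15, onsite_min = 20, ...) {
  start <- as.POSIXct("2022-06-15 10:00:00", tz = "UTC")
  new_ems_record(dispatch_priority = as.integer(priority),
                 mission_start = start,
                 on_scene_arrival = start + 60 * resp_min,
                 scene_departure = start + 60 * (resp_min + onsite_min), ...)
}

# small study-scale cohort reused across tests (generated once per test run)
small_cohort <- local({
  value <- NULL
  function() {
    if (is.null(value))
      value <<- generate_cohort(cohort_spec(n_records = 150, seed = 2024))
    value
  }
})
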