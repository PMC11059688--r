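test_that("cohort generation is bit-identical under a fixed seed and changes with it", {
  s1 <- generate_cohort(cohort_spec(n_records = 80, seed = 3))
  s2 <- generate_cohort(cohort_spec(n_records = 80, seed = 3))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$incidents, s2$incidents)
  s3 <- generate_cohort(cohort_spec(n_records = 80, seed = 4))
  expect_false(identical(s1$records, s3$records))
})

test_that("a null spec plants nothing and an everything-spec plants everywhere", {
  prev <- default_trigger_prevalence()
  prev[] <- 0
  null_co <- generate_cohort(cohort_spec(n_records = 30, seed = 9, exclusion_rate = 0,
                                         trigger_prevalence = prev,
                                         return_rate_72h = 0))
  scr <- screen_records(null_co$records, att_cfg, link_returns(null_co$records))
  expect_equal(sum(scr$status == "positive"), 0L)

  prev["A2"] <- 1
  dem <- default_demographics()
  dem$priority <- c(`1` = 1, `2` = 0, `3` = 0)
  all_a2 <- generate_cohort(cohort_spec(n_records = 30, seed = 9, exclusion_rate = 0,
                                        trigger_prevalence = prev, return_rate_72h = 0,
                                        demographics = dem))
  scr2 <- screen_records(all_a2$records, att_cfg, link_returns(all_a2$records))
  expect_equal(sum(scr2$status == "positive" & scr2$trigger_id == "A2"), 30L)
})

test_that("structurally infeasible specs are rejected", {
  dem <- default_demographics()
  dem$triage["red"] <- 0.01
  prev <- default_trigger_prevalence()
  prev["A3"] <- 0.05
  expect_error(cohort_spec(trigger_prevalence = prev, demographics = dem),
               "red-triage share")
  bad_model <- default_incident_model()
  bad_model$A1 <- c(near_miss = 0.9, no_harm = 0.3, harmful = 0)
  expect_error(cohort_spec(incident_model = bad_model), "sum to <= 1")
})

test_that("planted inclusion violations are removed exactly by the inclusion filter", {
  co <- generate_cohort(cohort_spec(n_records = 200, seed = 31, exclusion_rate = 0.05))
  expect_equal(sum(!co$manifest$included & !co$manifest$is_return_visit), 10L)
  primaries <- co$records[!grepl("_RET$", co$records$record_id), ]
  keep <- apply_inclusion_criteria(primaries)
  expect_equal(sum(!keep), 10L)
  expect_setequal(primaries$record_id[keep],
                  co$manifest$record_id[co$manifest$included])
})

test_that("screening a generated cohort recovers the planted per-trigger positives exactly", {
  co <- small_cohort()
  inc <- co$records[apply_inclusion_criteria(co$records), ]
  scr <- screen_records(inc, att_cfg, link_returns(co$records))
  man <- co$manifest[co$manifest$included, ]
  for (id in unique(scr$trigger_id)) {
    found <- sort(scr$record_id[scr$trigger_id == id & scr$status == "positive"])
    planted <- sort(man$record_id[man[[paste0("planted_", id)]]])
    expect_equal(found, planted, label = paste0("positives for ", id))
  }
})

test_that("empirical planting rates converge to the specified rates (3-sigma binomial bands)", {
  n <- 4000
  co <- generate_cohort(cohort_spec(n_records = n, seed = 77, exclusion_rate = 0))
  man <- co$manifest[co$manifest$included, ]
  prev <- default_trigger_prevalence()
  for (id in c("A1", "B1A", "B1C", "B1D", "B6", "B7")) {
    p <- prev[[id]]
    k <- sum(man[[paste0("planted_", id)]])
    expect_lt(abs(k - n * p), 3 * sqrt(n * p * (1 - p)) + 1e-9,
              label = paste0("planting rate for ", id))
  }
  # conditional 72-h return rate among non-conveyed
  nb6 <- sum(man$planted_B6)
  kret <- sum(man$planted_B6_RETURN_72H)
  pr <- 28 / 185
  expect_lt(abs(kret - nb6 * pr), 3 * sqrt(nb6 * pr * (1 - pr)))
})

test_that("perfect raters agree exactly and a blind rater produces an empty positive-positive cell", {
  co <- small_cohort()
  inc <- co$records[apply_inclusion_criteria(co$records), ]
  scr <- screen_records(inc, att_cfg, link_returns(co$records))
  truth <- screening_truth_grid(scr)
  perfect <- simulate_raters(truth, rater_model(1, 1, 1), rater_model(1, 1, 2))
  cm <- build_confusion_matrix(perfect$rater1, perfect$rater2)
  expect_equal(cm$b + cm$c, 0)
  expect_equal(cohens_kappa(cm), 1)
  blind <- simulate_raters(truth, rater_model(0, 1, 3), rater_model(1, 1, 4))
  cm2 <- build_confusion_matrix(blind$rater1, blind$rater2)
  expect_equal(cm2$a, 0)
  # rater simulation is deterministic per seed
  again <- simulate_raters(truth, rater_model(0, 1, 3), rater_model(1, 1, 4))
  expect_identical(blind, again)
})

test_that("imperfect raters tuned to review-session marginals land near kappa 0.5 and PABAK 0.9", {
  co <- small_cohort()
  inc <- co$records[apply_inclusion_criteria(co$records), ]
  scr <- screen_records(inc, att_cfg, link_returns(co$records))
  truth <- screening_truth_grid(scr)
  kappas <- pabaks <- numeric(8)
  for (r in seq_along(kappas)) {
    pair <- simulate_raters(truth, rater_model(0.75, 0.985, 100 + r),
                            rater_model(0.75, 0.985, 200 + r))
    cm <- build_confusion_matrix(pair$rater1, pair$rater2)
    kappas[r] <- cohens_kappa(cm)
    pabaks[r] <- pabak(cm)
  }
  expect_lt(abs(mean(kappas) - 0.5), 0.15)
  expect_lt(abs(mean(pabaks) - 0.9), 0.05)
})

test_that("judgements derived from the manifest reproduce the planted classes exactly", {
  co <- small_cohort()
  inc <- co$records[apply_inclusion_criteria(co$records), ]
  scr <- screen_records(inc, att_cfg, link_returns(co$records))
  man <- co$manifest[co$manifest$included, ]
  for (wf in c("revised", "original")) {
    j <- simulate_judgements(co, wf)
    cls <- classify_cohort(scr, j$primary, j$secondary, wf)
    idx <- match(man$record_id, cls$record_id)
    expect_identical(cls$who_class[idx], man$who_class)
    expect_identical(cls$final_category[idx], man$merp_category)
  }
  # a planted harmful incident forces exactly one secondary review of that record
  harmful <- man$record_id[man$who_class == "harmful_incident"]
  j <- simulate_judgements(co, "revised")
  expect_true(all(harmful %in% j$secondary$record_id))
  expect_true(all(j$secondary$harmed[match(harmful, j$secondary$record_id)]))
})
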