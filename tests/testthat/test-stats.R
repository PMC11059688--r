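random_cm <- function() {
  confusion_matrix(sample(0:80, 1), sample(0:80, 1), sample(0:80, 1),
                   sample(1:500, 1))
}

test_that("observed agreement, kappa and PABAK match closed-form and an independent implementation", {
  cm <- confusion_matrix(5, 5, 5, 5)
  expect_equal(observed_agreement(cm), 0.5)
  expect_equal(pabak(cm), 0)
  expect_equal(observed_agreement(confusion_matrix(0, 0, 0, 10)), 1)
  # perfect agreement with mixed marginals
  expect_equal(cohens_kappa(confusion_matrix(20, 0, 0, 80)), 1)
  expect_equal(pabak(confusion_matrix(20, 0, 0, 80)), 1)
  skip_if_not_installed("e1071")
  set.seed(7)
  for (i in 1:50) {
    cm <- random_cm()
    tab <- matrix(c(cm$a, cm$b, cm$c, cm$d), 2)
    expect_equal(cohens_kappa(cm), e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-12)
    expect_equal(observed_agreement(cm), e1071::classAgreement(tab)$diag,
                 tolerance = 1e-12)
  }
})

test_that("degenerate marginals give an explicit undefined kappa, not NaN", {
  expect_warning(k <- cohens_kappa(confusion_matrix(0, 0, 0, 50)), "undefined")
  expect_true(is.na(k))
  expect_equal(pabak(confusion_matrix(0, 0, 0, 50)), 1)  # PABAK still defined
})

test_that("kappa-type coefficients are symmetric under rater swap and bounded", {
  set.seed(11)
  for (i in 1:50) {
    cm <- random_cm()
    sw <- confusion_matrix(cm$a, cm$c, cm$b, cm$d)
    expect_equal(cohens_kappa(cm), cohens_kappa(sw))
    expect_equal(pabak(cm), pabak(sw))
    expect_equal(observed_agreement(cm), observed_agreement(sw))
    expect_true(cohens_kappa(cm) >= -1 && cohens_kappa(cm) <= 1)
    expect_true(pabak(cm) >= -1 && pabak(cm) <= 1)
  }
})

test_that("kappa equals PABAK at balanced marginals and cannot exceed it under dominant negatives", {
  set.seed(13)
  for (i in 1:30) {
    a <- sample(1:50, 1); b <- sample(0:30, 1)
    balanced <- confusion_matrix(a, b, b, a)   # both marginals 0.5
    expect_equal(cohens_kappa(balanced), pabak(balanced), tolerance = 1e-12)
    # unbalanced prevalence, small bias: the chance term depresses kappa
    d <- sample(200:2000, 1); a2 <- sample(0:20, 1); b2 <- sample(0:20, 1)
    skew <- confusion_matrix(a2, b2, b2, d)
    expect_lte(cohens_kappa(skew), pabak(skew) + 1e-12)
  }
})

test_that("kappa interpretation bands follow the published cut points", {
  expect_equal(interpret_kappa(0.10), "below_fair")
  expect_equal(interpret_kappa(0.21), "fair")
  expect_equal(interpret_kappa(0.40), "fair")
  expect_equal(interpret_kappa(0.41), "moderate")
  expect_equal(interpret_kappa(0.5), "moderate")
  expect_equal(interpret_kappa(0.61), "substantial")
  expect_equal(interpret_kappa(0.80), "substantial")
  expect_equal(interpret_kappa(0.89), "almost_perfect")
  expect_equal(interpret_kappa(1), "almost_perfect")
  expect_error(interpret_kappa(1.2), "lie in")
})

test_that("the paired grid builds the confusion matrix cell-exactly", {
  grid <- tidyr::expand_grid(record_id = sprintf("R%02d", 1:90),
                             trigger_id = sprintf("T%02d", 1:22))
  r1 <- dplyr::mutate(grid, positive = FALSE)
  r2 <- r1
  cm <- build_confusion_matrix(r1, r2)
  expect_equal(unlist(cm[c("a", "b", "c", "d")], use.names = FALSE),
               c(0, 0, 0, 1980))
  # planted disagreements land in the right cells regardless of row order
  r1$positive[1:93] <- TRUE
  r2$positive[35:162] <- TRUE
  cm2 <- build_confusion_matrix(r1[sample(nrow(r1)), ], r2)
  expect_equal(cm2$a, 59); expect_equal(cm2$c, 34)
  expect_equal(cm2$b, 69); expect_equal(cm2$d, 1818)
  expect_error(build_confusion_matrix(r1[-1, ], r2), "identical")
})

test_that("per-trigger PPVs divide class counts by positives and stay undefined at zero positives", {
  tal <- tibble::tibble(trigger_id = c("B1", "A3", "B6", "X0", "ALL"),
                        positives = c(271L, 19L, 185L, 0L, 10L),
                        near_miss = c(238L, 16L, 102L, 0L, 0L),
                        no_harm = c(24L, 0L, 5L, 0L, 0L),
                        harmful = c(1L, 0L, 1L, 0L, 10L))
  got <- trigger_ppv(tal)
  expect_equal(att_round(got$ppv_near_miss[1:3], 1), c(87.8, 84.2, 55.1))
  expect_true(is.na(got$ppv_near_miss[4]))
  expect_equal(got$ppv_harmful[5], 100)
  # class shares of one trigger can never exceed 100%
  shares <- rowSums(cbind(got$ppv_near_miss, got$ppv_no_harm, got$ppv_harmful),
                    na.rm = TRUE)
  expect_true(all(shares <= 100 + 1e-9))
  bad <- tal; bad$near_miss[2] <- 20L
  expect_error(trigger_ppv(bad), "exceed positives")
})

test_that("I-CVI agrees with a brute-force count over every 6-rater rating vector", {
  ratings <- as.matrix(expand.grid(rep(list(1:4), 6)))
  brute <- apply(ratings, 1, function(r) {
    hits <- 0L
    for (x in r) if (x == 3L || x == 4L) hits <- hits + 1L
    hits / 6
  })
  ours <- apply(ratings, 1, function(r) icvi(r)$icvi)
  expect_equal(ours, brute)
  flags <- apply(ratings, 1, function(r) icvi(r)$highly_relevant)
  expect_equal(flags, brute >= 0.80)
  expect_error(icvi(integer()), "at least one")
  expect_error(icvi(c(3, 5)), "1-4")
})

test_that("frequency report percentages cover the cohort and sum to 100 up to rounding", {
  co <- small_cohort()
  inc <- co$records[apply_inclusion_criteria(co$records), ]
  scr <- screen_records(inc, att_cfg, link_returns(co$records))
  j <- simulate_judgements(co)
  cls <- classify_cohort(scr, j$primary, j$secondary)
  rep <- frequency_report(cls, scr, inc)
  expect_equal(rep$n, nrow(inc))
  expect_lt(abs(sum(rep$who$pct) - 100), 0.3)
  sexes <- rep$demographics[rep$demographics$variable == "patient_sex", ]
  expect_equal(sum(sexes$n), nrow(inc))
  expect_error(frequency_report(cls[-1, ], scr, inc), "classification missing")
})

test_that("presentation rounding and truncation differ exactly where printed tables do", {
  expect_equal(att_round(0.8959596, 2, "truncate"), 0.89)
  expect_equal(att_round(0.8959596, 2, "round"), 0.90)
  expect_equal(att_round(92.1875, 1, "truncate"), 92.1)
  expect_equal(att_round(92.1875, 1, "round"), 92.2)
  expect_equal(att_round(87.82288, 1), 87.8)
})
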