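test_that("diabetes diagnosis applies the four conditions at their thresholds", {
  # condition (a) at the exact boundary
  r <- recs(rec("A", 2014, PG = 120, HbA1c = 6.0),
            rec("A", 2015, PG = 126, HbA1c = 6.5),
            rec("A", 2016, PG = 130, HbA1c = 7.0))
  d <- diagnose_diabetes(r)
  expect_equal(d$onset_year, 2015L)
  expect_equal(d$condition, "a")

  # both thresholds required
  d2 <- diagnose_diabetes(rec("B", 2015, PG = 130, HbA1c = 6.4))
  expect_true(is.na(d2$onset_year))

  # (b) needs the non-fasting cutoff of 200
  d3 <- diagnose_diabetes(recs(
    rec("C", 2014, fasting = FALSE, PG = 150, HbA1c = 6.6),
    rec("C", 2015, fasting = FALSE, PG = 200, HbA1c = 6.5)))
  expect_equal(d3$onset_year, 2015L)
  expect_equal(d3$condition, "b")

  # (d) questionnaire treatment with normal labs
  d4 <- diagnose_diabetes(recs(
    rec("D", 2015, PG = 90, HbA1c = 5.5),
    rec("D", 2016, PG = 90, HbA1c = 5.5, treat = TRUE),
    rec("D", 2017, PG = 90, HbA1c = 5.5, treat = TRUE)))
  expect_equal(d4$onset_year, 2016L)
  expect_equal(d4$condition, "d")

  # missing labs and questionnaire throughout is "no onset", not an error
  d5 <- diagnose_diabetes(rec("E", 2015, PG = NA, HbA1c = NA))
  expect_true(is.na(d5$onset_year))

  # earliest qualifying year wins even if records arrive unsorted
  d6 <- diagnose_diabetes(recs(
    rec("F", 2018, treat = TRUE),
    rec("F", 2013, PG = 126, HbA1c = 6.5)))
  expect_equal(d6$onset_year, 2013L)
  expect_equal(d6$condition, "a")
})

test_that("obesity is fixed by BMI at the first measurement", {
  expect_equal(classify_obesity(rec("A", 2012, BMI = 25.0)), "obese")
  expect_equal(classify_obesity(rec("B", 2012, BMI = 24.9)), "non_obese")
  expect_equal(classify_obesity(recs(rec("C", 2012, BMI = 26),
                                     rec("C", 2013, BMI = 24))), "obese")
  # first *available* BMI governs when the earliest one is missing
  expect_equal(classify_obesity(recs(rec("D", 2012, BMI = NA),
                                     rec("D", 2013, BMI = 26))), "obese")
  expect_error(classify_obesity(rec("E", 2012, BMI = NA)), "BMI")
})

# A 20-record fixture with hand-enumerated violations:
#   - height column and a mostly-missing TG column (feature-level drops)
#   - HbA1c 40% missing but exempt from the step-1 rule
#   - 4 female records, 3 non-fasting male records,
#   - 2 male records at/after F01's 2015 onset,
#   - 2 male records with a missing retained feature,
#   - one male individual left with no records (step 4)
filter_fixture <- function() {
  males <- recs(
    rec("M01", 2012), rec("M01", 2013), rec("M01", 2014),
    rec("M02", 2012, fasting = FALSE), rec("M02", 2013),
    rec("M03", 2012, fasting = FALSE), rec("M03", 2013, fasting = FALSE),
    rec("F01", 2014, PG = 126, HbA1c = 6.5),  # onset 2015 via treat flag? no: labs
    rec("F01", 2015, treat = TRUE), rec("F01", 2016),
    rec("M04", 2012, BMI = NA), rec("M04", 2013, UA = NA),
    rec("M05", 2012), rec("M05", 2013), rec("M05", 2014), rec("M05", 2015))
  females <- recs(
    rec("W01", 2012, sex = "female"), rec("W01", 2013, sex = "female"),
    rec("W02", 2012, sex = "female"), rec("W02", 2013, sex = "female"))
  x <- recs(males, females)
  x$height <- 170
  x$TG <- NA_real_
  x$TG[1:5] <- 120           # 15/20 = 75% missing -> dropped in step 1
  x$HbA1c[seq(1, 20, by = 3)] <- NA  # 7/20 = 35% missing, kept regardless
  x
}

test_that("the exclusion pipeline matches hand-enumerated counts", {
  x <- filter_fixture()
  onset_map <- diagnose_cohort(x)
  expect_equal(onset_map$onset_year[onset_map$individual_id == "F01"], 2014L)

  out <- apply_filters(x, onset_map)
  rep <- out$report

  expect_setequal(rep$step1_features_dropped, c("height", "TG"))
  expect_true("HbA1c" %in% rep$retained_features)
  expect_equal(rep$step2_records, 4L)
  expect_equal(rep$step2_individuals, 2L)
  # of the 16 male records, 3 are non-fasting
  expect_equal(rep$step3a_records, 3L)
  # F01 onset 2014 (lab condition a): records 2014, 2015, 2016 at/after
  # onset; the 2015 and 2016 ones remain after step 3a -> but 2014 is
  # fasting too, so all 3 drop here
  expect_equal(rep$step3b_records, 3L)
  # remaining with a missing retained feature: M04 x2 plus any record with
  # missing HbA1c among survivors: hand count
  surv <- x[x$sex == "male" & x$fasting, ]
  surv <- surv[!(surv$individual_id == "F01" & surv$year >= 2014), ]
  hand3c <- sum(is.na(surv$BMI) | is.na(surv$UA) | is.na(surv$HbA1c))
  expect_equal(rep$step3c_records, hand3c)
  expect_equal(rep$step4_individuals,
               6L - length(unique(out$records$individual_id)))
  # conservation: every record is either kept or counted exactly once
  expect_equal(rep$final_records,
               rep$initial_records - rep$step2_records - rep$step3a_records -
                 rep$step3b_records - rep$step3c_records)
  # no surviving record at or after its individual's onset
  onset <- onset_map$onset_year[match(out$records$individual_id,
                                      onset_map$individual_id)]
  expect_false(any(!is.na(onset) & out$records$year >= onset))
})

test_that("filtering is idempotent and zero on empty input", {
  x <- filter_fixture()
  onset_map <- diagnose_cohort(x)
  once <- apply_filters(x, onset_map)
  twice <- apply_filters(once$records, onset_map)
  expect_equal(twice$records, once$records)
  expect_equal(twice$report$final_records, once$report$final_records)
  expect_equal(twice$report$step2_records + twice$report$step3a_records +
                 twice$report$step3b_records + twice$report$step3c_records, 0L)

  empty <- apply_filters(x[0, ], onset_map)
  expect_equal(nrow(empty$records), 0L)
  expect_equal(empty$report$final_records, 0L)
})

# Cohort where onset risk is carried only by PG: 3-year-ahead positives
# have elevated PG, every other biomarker is exchangeable noise.
pg_signal_cohort <- function(seed) {
  set.seed(seed)
  n <- 240
  ids <- sprintf("P%03d", 1:n)
  onset_ind <- rep(c(TRUE, FALSE), length.out = n)
  rows <- list()
  for (i in 1:n) {
    for (y in 2012:2013) {
      r <- rec(ids[i], y)
      for (f in checkup_features()) r[[f]] <- rnorm(1, 50, 10)
      r$PG <- rnorm(1, if (onset_ind[i]) 112 else 92, 6)
      rows[[length(rows) + 1]] <- r
    }
  }
  list(records = recs(do.call(rbind, rows)),
       onset_map = data.frame(
         individual_id = ids,
         onset_year = ifelse(onset_ind, 2015L, NA_integer_),
         condition = ifelse(onset_ind, "a", NA_character_)))
}

test_that("random-forest ranking recovers a planted PG signal", {
  co <- pg_signal_cohort(17)
  top1 <- vapply(1:5, function(s) {
    rank_features(co$records, co$onset_map, seed = s, n_trees = 150)$ranking[1]
  }, "")
  # majority vote over seeds
  expect_gte(sum(top1 == "PG"), 3)

  sel <- rank_features(co$records, co$onset_map, seed = 1, n_trees = 150)
  expect_true("HbA1c" %in% sel$selected)   # forced inclusion
  expect_false("HbA1c" %in% sel$ranking)   # never among ranked candidates
  expect_length(sel$selected, 6L)
})

test_that("ranking without positive labels is an error", {
  co <- pg_signal_cohort(1)
  no_onset <- co$onset_map
  no_onset$onset_year <- NA_integer_
  expect_error(rank_features(co$records, no_onset), "positive and negative")
})
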