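# Diagnosis and obesity labelling, the multi-step exclusion flow, and
# random-forest feature ranking.

#' Diagnose diabetes from one individual's checkup history
#'
#' An individual is diagnosed in the earliest year in which any of four
#' conditions holds: (a) fasting PG >= 126 mg/dL and HbA1c >= 6.5%,
#' (b) non-fasting PG >= 200 mg/dL and HbA1c >= 6.5%, (c) the
#' questionnaire reports a history of diabetes, (d) the questionnaire
#' reports ongoing diabetes treatment. That earliest year is the onset
#' year; if no condition is ever met (including when PG/HbA1c and the
#' questionnaire are missing throughout) the result is "no onset", not an
#' error. When several conditions first hold in the same year the
#' triggering condition is reported as the first of a-d.
#'
#' @param records Data frame of one individual's records.
#' @return List with `individual_id`, `onset_year` (NA if never
#'   diagnosed) and `condition` (`"a"`..`"d"` or NA).
#' @export
diagnose_diabetes <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("need at least one record")
  if (length(unique(records$individual_id)) != 1L)
    stop("records must belong to a single individual")
  records <- records[order(records$year), ]
  pg <- records$PG
  a1c <- records$HbA1c
  lab_ok <- !is.na(pg) & !is.na(a1c)
  cond <- cbind(
    a = records$fasting %in% TRUE & lab_ok & pg >= 126 & a1c >= 6.5,
    b = records$fasting %in% FALSE & lab_ok & pg >= 200 & a1c >= 6.5,
    c = records$questionnaire_history %in% TRUE,
    d = records$questionnaire_treatment %in% TRUE
  )
  hit <- which(rowSums(cond) > 0)
  if (length(hit) == 0L)
    return(list(individual_id = records$individual_id[1],
                onset_year = NA_integer_, condition = NA_character_))
  first <- hit[1]
  list(individual_id = records$individual_id[1],
       onset_year = as.integer(records$year[first]),
       condition = colnames(cond)[which(cond[first, ])[1]])
}

#' Diagnose every individual in a cohort
#'
#' @param records Data frame of checkup records (many individuals).
#' @return Data frame `individual_id, onset_year, condition` (the onset
#'   map consumed by [apply_filters()]).
#' @export
diagnose_cohort <- function(records) {
  parts <- split(records, records$individual_id)
  out <- lapply(parts, diagnose_diabetes)
  data.frame(
    individual_id = vapply(out, `[[`, "", "individual_id"),
    onset_year = vapply(out, `[[`, NA_integer_, "onset_year"),
    condition = vapply(out, `[[`, NA_character_, "condition"),
    row.names = NULL
  )
}

#' Classify obesity from the first BMI measurement
#'
#' BMI of 25 kg/m2 or greater at the first (earliest-year) measurement
#' means obese; below 25 means non-obese. Later BMI values never change
#' the label. The earliest record with a non-missing BMI is used.
#'
#' @param records One individual's records.
#' @return `"obese"` or `"non_obese"`.
#' @export
classify_obesity <- function(records) {
  records <- as.data.frame(records)
  ok <- !is.na(records$BMI)
  if (!any(ok)) stop("no non-missing BMI measurement for individual ",
                     records$individual_id[1])
  first_bmi <- records$BMI[ok][which.min(records$year[ok])]
  if (first_bmi >= 25) "obese" else "non_obese"
}

#' Obesity labels for a whole cohort
#'
#' @param records Data frame of checkup records.
#' @return Data frame `individual_id, obesity`.
#' @export
classify_cohort_obesity <- function(records) {
  parts <- split(records, records$individual_id)
  data.frame(
    individual_id = names(parts),
    obesity = vapply(parts, classify_obesity, ""),
    row.names = NULL
  )
}

#' Multi-step record/feature exclusion pipeline
#'
#' Reproduces the pre-analysis exclusion flow on a raw cohort:
#' \enumerate{
#'   \item drop unsuitable feature columns — height, weight,
#'     non-numeric (categorical) columns, and any feature missing in more
#'     than `missing_threshold` of current records, except HbA1c which is
#'     kept regardless as clinically indispensable;
#'   \item drop females and all their records;
#'   \item drop records that are (a) non-fasting, then (b) at or after
#'     the individual's diabetes onset, then (c) missing any retained
#'     feature (criteria counted sequentially in that order);
#'   \item drop individuals left with no records.
#' }
#'
#' @param records Raw checkup records.
#' @param onset_map Data frame from [diagnose_cohort()].
#' @param missing_threshold Missingness fraction above which a feature is
#'   dropped in step 1 (default 0.30).
#' @param keep_despite_missing Features exempt from the step-1 missingness
#'   rule (default `"HbA1c"`).
#' @return List with `records` (the filtered data frame) and `report`
#'   (class `cohort_filter_report`; per-step exclusion counts).
#' @export
apply_filters <- function(records, onset_map,
                          missing_threshold = 0.3,
                          keep_despite_missing = "HbA1c") {
  records <- as.data.frame(records)
  n0_rec <- nrow(records)
  n0_ind <- length(unique(records$individual_id))
  feat_cols <- setdiff(names(records), RECORD_META)

  if (n0_rec == 0L) {
    rep0 <- structure(list(
      initial_records = 0L, initial_individuals = 0L,
      step1_features_dropped = character(0),
      retained_features = feat_cols,
      step2_records = 0L, step2_individuals = 0L,
      step3a_records = 0L, step3b_records = 0L, step3c_records = 0L,
      step4_individuals = 0L,
      final_records = 0L, final_individuals = 0L),
      class = "cohort_filter_report")
    return(list(records = records, report = rep0))
  }

  # step 1: feature exclusion
  numeric_feats <- feat_cols[vapply(records[feat_cols], is.numeric, TRUE)]
  drop1 <- union(intersect(c("height", "weight"), feat_cols),
                 setdiff(feat_cols, numeric_feats))
  miss_frac <- vapply(records[numeric_feats],
                      function(v) mean(is.na(v)), numeric(1))
  drop1 <- union(drop1, setdiff(numeric_feats[miss_frac > missing_threshold],
                                keep_despite_missing))
  retained <- setdiff(feat_cols, drop1)
  records <- records[, c(RECORD_META, retained), drop = FALSE]

  # step 2: drop females
  is_f <- records$sex == "female"
  step2_rec <- sum(is_f)
  step2_ind <- length(unique(records$individual_id[is_f]))
  records <- records[!is_f, , drop = FALSE]

  # step 3a: non-fasting records
  drop3a <- !(records$fasting %in% TRUE)
  step3a <- sum(drop3a)
  records <- records[!drop3a, , drop = FALSE]

  # step 3b: records at or after diabetes onset
  onset <- onset_map$onset_year[match(records$individual_id,
                                      onset_map$individual_id)]
  drop3b <- !is.na(onset) & records$year >= onset
  step3b <- sum(drop3b)
  records <- records[!drop3b, , drop = FALSE]

  # step 3c: records missing any retained feature
  core <- setdiff(retained, character(0))
  drop3c <- if (length(core))
    rowSums(is.na(records[, core, drop = FALSE])) > 0 else rep(FALSE, nrow(records))
  step3c <- sum(drop3c)
  records <- records[!drop3c, , drop = FALSE]

  # step 4: individuals with no remaining records (already absent; count them)
  n_ind_after2 <- n0_ind - step2_ind
  final_ind <- length(unique(records$individual_id))
  step4_ind <- n_ind_after2 - final_ind

  rownames(records) <- NULL
  report <- structure(list(
    initial_records = n0_rec, initial_individuals = n0_ind,
    step1_features_dropped = drop1, retained_features = retained,
    step2_records = step2_rec, step2_individuals = step2_ind,
    step3a_records = step3a, step3b_records = step3b,
    step3c_records = step3c, step4_individuals = step4_ind,
    final_records = nrow(records), final_individuals = final_ind),
    class = "cohort_filter_report")
  list(records = records, report = report)
}

#' @export
print.cohort_filter_report <- function(x, ...) {
  cat("Cohort filter report\n")
  cat(sprintf("  input: %d records / %d individuals\n",
              x$initial_records, x$initial_individuals))
  cat("  step 1: dropped features:",
      if (length(x$step1_features_dropped))
        paste(x$step1_features_dropped, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  step 2 (females): -%d records (-%d individuals)\n",
              x$step2_records, x$step2_individuals))
  cat(sprintf("  step 3: -%d non-fasting, -%d at/after onset, -%d incomplete\n",
              x$step3a_records, x$step3b_records, x$step3c_records))
  cat(sprintf("  step 4: -%d individuals without records\n",
              x$step4_individuals))
  cat(sprintf("  output: %d records / %d individuals\n",
              x$final_records, x$final_individuals))
  invisible(x)
}

#' Rank features by random-forest importance for 3-year onset prediction
#'
#' Labels every filtered record positive when the individual's diabetes
#' onset falls within the following `horizon` years (onset year minus
#' record year in 1..horizon), trains a random forest on the candidate
#' features (all retained biomarkers except the always-included ones),
#' and ranks them by mean decrease in Gini impurity. The selection is the
#' top `n_top` plus the always-included features (HbA1c, forced in on
#' clinical grounds).
#'
#' @param records Filtered records (complete on the candidate features).
#' @param onset_map From [diagnose_cohort()].
#' @param seed RNG seed for the forest.
#' @param n_trees Number of trees (default 500).
#' @param horizon Prediction horizon in years (default 3).
#' @param n_top How many ranked features to keep (default 5).
#' @param always_include Features appended regardless of rank.
#' @return List: `ranking` (all candidates, most important first),
#'   `importance` (named vector), `selected` (always-included first, then
#'   the top-ranked — the bit order used downstream), `n_positive`.
#' @export
rank_features <- function(records, onset_map, seed = 1, n_trees = 500,
                          horizon = 3, n_top = 5,
                          always_include = "HbA1c") {
  records <- as.data.frame(records)
  candidates <- setdiff(intersect(checkup_features(), names(records)),
                        always_include)
  if (length(candidates) < n_top)
    stop("not enough candidate features to rank")
  onset <- onset_map$onset_year[match(records$individual_id,
                                      onset_map$individual_id)]
  lag <- onset - records$year
  y <- factor(ifelse(!is.na(lag) & lag >= 1 & lag <= horizon,
                     "onset", "no_onset"), levels = c("no_onset", "onset"))
  if (length(unique(y)) < 2L)
    stop("feature ranking needs both positive and negative labels; ",
         "got only '", as.character(unique(y)), "'")
  x <- records[, candidates, drop = FALSE]
  if (anyNA(x)) stop("candidate features must be complete; filter first")
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
  imp <- rf$importance[, "MeanDecreaseGini"]
  ranking <- names(sort(imp, decreasing = TRUE))
  list(ranking = ranking,
       importance = sort(imp, decreasing = TRUE),
       selected = c(always_include, head(ranking, n_top)),
       n_positive = sum(y == "onset"))
}
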