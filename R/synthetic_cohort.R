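# Synthetic longitudinal checkup cohort with known latent-state ground
# truth. Individuals follow a latent Markov chain over health states;
# biomarkers are conditionally independent Gaussians given the latent
# state (correlation between features enters through the shared state);
# visits, fasting status, per-cell missingness and diabetes onset are
# applied on top.

# Per-state biomarker means and common SDs on clinically realistic scales.
# Three states: 1 healthy, 2 intermediate (obesity-flavoured: raised
# BMI/WC/TG/ALT/UA, lowered HDL-C, near-normal glycaemia), 3 unhealthy
# (pre-diabetic: raised PG and HbA1c).
#' Default per-state biomarker distribution parameters
#'
#' @param n_states Number of latent states (only 3 has built-in defaults).
#' @return Data frame with columns `feature`, `state`, `mean`, `sd`.
#' @export
default_feature_params <- function(n_states = 3) {
  if (n_states != 3L)
    stop("built-in feature parameters exist only for 3 latent states; ",
         "supply feature_params for other values")
  means <- rbind(
    #        BMI    WC   SBP  DBP   TG LDL_C HDL_C  PG HbA1c  UA  Cre AST ALT GGT  WBC RBC   Hb   Ht
    state1 = c(23.0, 84,  125, 79,  115, 129,  62,  90, 5.40, 6.0, 0.87, 23, 21, 50, 6100, 487, 15.2, 45.2),
    state2 = c(25.8, 90,  129, 82,  163, 132,  51,  92, 5.50, 6.8, 0.90, 27, 33, 63, 6250, 496, 15.4, 45.5),
    state3 = c(23.5, 85,  128, 80,  125, 130,  57, 103, 5.90, 6.0, 0.86, 23, 22, 52, 6100, 485, 15.0, 44.7)
  )
  sds <- c(2.3, 7, 15, 11, 90, 30, 12, 8, 0.25, 1.1, 0.15, 9, 12, 55,
           1650, 36, 1.0, 2.7)
  colnames(means) <- CHECKUP_FEATURES
  data.frame(
    feature = rep(CHECKUP_FEATURES, times = 3),
    state = rep(1:3, each = length(CHECKUP_FEATURES)),
    mean = as.vector(t(means)),
    sd = rep(sds, times = 3)
  )
}

default_transition_matrix <- function() {
  # non-obese-leaning dynamics: direct healthy -> unhealthy moves dominate
  matrix(c(0.86, 0.02, 0.12,
           0.20, 0.55, 0.25,
           0.12, 0.03, 0.85), 3, 3, byrow = TRUE)
}

default_obese_transition_matrix <- function() {
  # obese individuals favour the intermediate state en route to unhealthy
  matrix(c(0.84, 0.10, 0.06,
           0.10, 0.60, 0.30,
           0.10, 0.08, 0.82), 3, 3, byrow = TRUE)
}

default_missing_rates <- function() {
  r <- stats::setNames(rep(0.02, length(CHECKUP_FEATURES)), CHECKUP_FEATURES)
  r["HbA1c"] <- 0.37  # HbA1c is measured far less consistently
  r["WC"] <- 0.10
  r
}

#' Specify a synthetic checkup cohort
#'
#' Bundles and validates every knob of the generator. Defaults describe a
#' workplace-checkup cohort of middle-aged adults observed yearly
#' 2012-2020 with three latent health states (healthy / intermediate /
#' unhealthy), an obese subgroup whose dynamics favour the intermediate
#' state, heavy HbA1c missingness, and diabetes onset arising only from
#' the non-healthy states.
#'
#' @param n_individuals Number of individuals.
#' @param year_range Inclusive calendar-year pair, e.g. `c(2012, 2020)`.
#' @param visit_probability Per-year probability of a checkup visit.
#' @param obese_fraction Proportion of individuals in the obese subgroup.
#' @param female_fraction Proportion of females (dropped later by the
#'   filter pipeline; present so the pipeline can be exercised).
#' @param latent_states Number of latent health states K >= 2.
#' @param latent_transition_matrix K x K row-stochastic annual transition
#'   matrix (non-obese individuals).
#' @param obese_transition_matrix Optional K x K matrix for the obese
#'   subgroup; defaults to `latent_transition_matrix`.
#' @param initial_state_probs Length-K initial distribution.
#' @param feature_params Data frame `feature, state, mean, sd` giving the
#'   per-state Gaussian parameters in clinical units (SD > 0).
#' @param obese_bmi_shift,obese_wc_shift Additive mean shifts applied to
#'   BMI and WC for obese individuals.
#' @param missing_rates Named per-feature missing-completely-at-random
#'   cell probabilities.
#' @param fasting_probability Probability a visit is a fasting one.
#' @param onset_hazard Length-K per-state annual probability of diabetes
#'   onset; states with zero hazard never trigger onset.
#' @param seed Default RNG seed used by [generate_cohort()].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals = 500,
                        year_range = c(2012, 2020),
                        visit_probability = 0.85,
                        obese_fraction = 0.30,
                        female_fraction = 0.40,
                        latent_states = 3,
                        latent_transition_matrix = NULL,
                        obese_transition_matrix = NULL,
                        initial_state_probs = NULL,
                        feature_params = NULL,
                        obese_bmi_shift = 3.5,
                        obese_wc_shift = 9,
                        missing_rates = NULL,
                        fasting_probability = 0.6,
                        onset_hazard = NULL,
                        seed = 1) {
  K <- as.integer(latent_states)
  if (is.null(latent_transition_matrix)) {
    if (K == 3L) latent_transition_matrix <- default_transition_matrix()
    else stop("latent_transition_matrix required when latent_states != 3")
  }
  if (is.null(obese_transition_matrix)) {
    obese_transition_matrix <-
      if (K == 3L) default_obese_transition_matrix()
      else latent_transition_matrix
  }
  if (is.null(initial_state_probs))
    initial_state_probs <- if (K == 3L) c(0.60, 0.10, 0.30) else rep(1 / K, K)
  if (is.null(feature_params)) feature_params <- default_feature_params(K)
  if (is.null(missing_rates)) missing_rates <- default_missing_rates()
  if (is.null(onset_hazard))
    onset_hazard <- if (K == 3L) c(0, 0.01, 0.05) else rep(0.01, K)

  spec <- structure(
    list(n_individuals = as.integer(n_individuals),
         year_range = as.integer(year_range),
         visit_probability = visit_probability,
         obese_fraction = obese_fraction,
         female_fraction = female_fraction,
         latent_states = K,
         latent_transition_matrix = latent_transition_matrix,
         obese_transition_matrix = obese_transition_matrix,
         initial_state_probs = initial_state_probs,
         feature_params = feature_params,
         obese_bmi_shift = obese_bmi_shift,
         obese_wc_shift = obese_wc_shift,
         missing_rates = missing_rates,
         fasting_probability = fasting_probability,
         onset_hazard = onset_hazard,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  K <- spec$latent_states
  chk_prob <- function(p, field) {
    if (anyNA(p) || any(p < 0 | p > 1))
      stop("invalid cohort_spec: '", field, "' must be in [0, 1]")
  }
  if (is.na(spec$n_individuals) || spec$n_individuals < 1L)
    stop("invalid cohort_spec: 'n_individuals' must be >= 1")
  if (length(spec$year_range) != 2L || spec$year_range[1] > spec$year_range[2])
    stop("invalid cohort_spec: 'year_range' must be an increasing year pair")
  if (K < 2L) stop("invalid cohort_spec: 'latent_states' must be >= 2")
  chk_prob(spec$visit_probability, "visit_probability")
  chk_prob(spec$obese_fraction, "obese_fraction")
  chk_prob(spec$female_fraction, "female_fraction")
  chk_prob(spec$fasting_probability, "fasting_probability")
  chk_prob(spec$missing_rates, "missing_rates")
  chk_prob(spec$onset_hazard, "onset_hazard")
  if (length(spec$onset_hazard) != K)
    stop("invalid cohort_spec: 'onset_hazard' must have one entry per state")
  for (nm in c("latent_transition_matrix", "obese_transition_matrix")) {
    P <- spec[[nm]]
    if (!all(dim(P) == c(K, K)) || any(P < 0) ||
        max(abs(rowSums(P) - 1)) > 1e-8)
      stop("invalid cohort_spec: '", nm, "' must be ", K, "x", K,
           " row-stochastic")
  }
  if (length(spec$initial_state_probs) != K ||
      abs(sum(spec$initial_state_probs) - 1) > 1e-8)
    stop("invalid cohort_spec: 'initial_state_probs' must be a length-",
         K, " distribution")
  fp <- spec$feature_params
  need <- c("feature", "state", "mean", "sd")
  if (!all(need %in% names(fp)))
    stop("invalid cohort_spec: 'feature_params' needs columns ",
         paste(need, collapse = ", "))
  if (any(fp$sd <= 0))
    stop("invalid cohort_spec: 'feature_params' SDs must be > 0")
  if (!all(seq_len(K) %in% fp$state))
    stop("invalid cohort_spec: 'feature_params' must cover every state")
  invisible(spec)
}

#' Generate a synthetic longitudinal checkup cohort
#'
#' Each individual follows a latent Markov path over the study years;
#' on visited years the biomarkers are drawn from the state's Gaussian
#' parameters (obese individuals get shifted BMI/WC means), a fasting flag
#' is drawn, per-cell values are deleted completely at random, and — once
#' diabetes onset has fired, which can only happen while in a state with
#' positive hazard — the questionnaire history/treatment flags stay set in
#' the onset year and all later years.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed (defaults to the spec's); the output is a
#'   deterministic function of spec + seed.
#' @return Object of class `synthetic_cohort`: `records` (one data frame
#'   row per individual-year visit, schema `individual_id, year, sex,
#'   fasting, questionnaire_history, questionnaire_treatment,` plus the 18
#'   biomarkers) and `truth` (`individuals`: id, sex, obese, onset_year;
#'   `latent_paths`: id, year, state for every study year).
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  validate_cohort_spec(spec)
  set.seed(seed)
  years <- spec$year_range[1]:spec$year_range[2]
  n_years <- length(years)
  K <- spec$latent_states
  feats <- unique(spec$feature_params$feature)

  # mean/sd lookup matrices: state x feature
  mu <- matrix(NA_real_, K, length(feats), dimnames = list(NULL, feats))
  sg <- mu
  for (r in seq_len(nrow(spec$feature_params))) {
    p <- spec$feature_params[r, ]
    mu[p$state, p$feature] <- p$mean
    sg[p$state, p$feature] <- p$sd
  }
  if (anyNA(mu)) stop("feature_params must cover every feature x state")

  ids <- sprintf("I%05d", seq_len(spec$n_individuals))
  rec_list <- vector("list", spec$n_individuals)
  ind_rows <- vector("list", spec$n_individuals)
  path_mat <- matrix(NA_integer_, spec$n_individuals, n_years)

  for (i in seq_len(spec$n_individuals)) {
    female <- runif(1) < spec$female_fraction
    obese <- runif(1) < spec$obese_fraction
    P <- if (obese) spec$obese_transition_matrix
         else spec$latent_transition_matrix

    path <- integer(n_years)
    path[1] <- sample.int(K, 1, prob = spec$initial_state_probs)
    if (n_years > 1) for (t in 2:n_years)
      path[t] <- sample.int(K, 1, prob = P[path[t - 1], ])
    path_mat[i, ] <- path

    onset_year <- NA_integer_
    for (t in seq_len(n_years)) {
      hz <- spec$onset_hazard[path[t]]
      if (hz > 0 && runif(1) < hz) { onset_year <- years[t]; break }
    }

    visited <- runif(n_years) < spec$visit_probability
    vy <- years[visited]
    nv <- length(vy)
    if (nv == 0L) {
      ind_rows[[i]] <- data.frame(
        individual_id = ids[i], sex = if (female) "female" else "male",
        obese = obese, onset_year = onset_year)
      next
    }
    st <- path[visited]
    vals <- matrix(NA_real_, nv, length(feats),
                   dimnames = list(NULL, feats))
    for (f in feats) {
      m <- mu[st, f]
      if (obese && f == "BMI") m <- m + spec$obese_bmi_shift
      if (obese && f == "WC") m <- m + spec$obese_wc_shift
      vals[, f] <- pmax(rnorm(nv, m, sg[st, f]), 0.01)
    }
    for (f in feats) {
      drop_cell <- runif(nv) < spec$missing_rates[[f]]
      vals[drop_cell, f] <- NA_real_
    }
    post_onset <- !is.na(onset_year) & vy >= onset_year
    rec_list[[i]] <- data.frame(
      individual_id = ids[i], year = vy,
      sex = if (female) "female" else "male",
      fasting = runif(nv) < spec$fasting_probability,
      questionnaire_history = post_onset,
      questionnaire_treatment = post_onset,
      vals, check.names = FALSE)
    ind_rows[[i]] <- data.frame(
      individual_id = ids[i], sex = if (female) "female" else "male",
      obese = obese, onset_year = onset_year)
  }

  records <- do.call(rbind, rec_list[!vapply(rec_list, is.null, logical(1))])
  rownames(records) <- NULL
  latent_paths <- data.frame(
    individual_id = rep(ids, each = n_years),
    year = rep(years, times = spec$n_individuals),
    state = as.integer(t(path_mat)))
  structure(
    list(records = records,
         truth = list(individuals = do.call(rbind, ind_rows),
                      latent_paths = latent_paths),
         spec = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tr <- x$truth$individuals
  cat("Synthetic checkup cohort: ", nrow(tr), " individuals, ",
      nrow(x$records), " records, years ",
      x$spec$year_range[1], "-", x$spec$year_range[2], "\n", sep = "")
  cat("  obese: ", sum(tr$obese), "; females: ", sum(tr$sex == "female"),
      "; diabetes onsets: ", sum(!is.na(tr$onset_year)), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Records as CSV (the schema consumed by the filtering pipeline) and the
#' ground truth as JSON.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec_path <- file.path(dir, "cohort.csv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(cohort$records, rec_path, row.names = FALSE)
  jsonlite::write_json(cohort$truth, truth_path, dataframe = "columns",
                       na = "null", auto_unbox = TRUE, digits = NA)
  invisible(c(records = rec_path, truth = truth_path))
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path CSV path.
#' @return Data frame of checkup records.
#' @export
read_cohort_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (f in c("fasting", "questionnaire_history", "questionnaire_treatment"))
    if (f %in% names(rec)) rec[[f]] <- as.logical(rec[[f]])
  rec
}
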