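# End-to-end orchestration: raw records -> labels -> filters -> feature
# selection -> energy landscape -> transitions -> pre-transition table,
# for the whole cohort or for the diabetes sub-cohort, with optional
# artifact output.

# Small deterministic checksum for the run manifest (polynomial hash of
# the deparsed config).
config_checksum <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%010d", h)
}

#' Run the full energy-landscape analysis
#'
#' Orchestrates every stage: diabetes diagnosis and obesity labelling on
#' the raw records, the exclusion pipeline, feature selection (random
#' forest unless a 6-feature list is given), optional restriction to the
#' diabetes sub-cohort, median binarization, Ising fitting, basin and
#' disconnectivity computation (plain and modified), state assignment,
#' transition counting (whole cohort and stratified by obesity),
#' obese-vs-non-obese pathway-preference tests where the counts allow,
#' and the pre-transition feature table.
#'
#' @param records Raw checkup records, or a `synthetic_cohort`.
#' @param scope `"all"` (whole filtered cohort) or `"diabetes_only"`
#'   (pre-onset records of individuals who develop diabetes).
#' @param features Either NULL (rank by random forest and take HbA1c +
#'   top 5) or the 6 features to use, most significant bit first.
#' @param coding Ising state coding, see [ising_model()].
#' @param seed Seed for the feature-ranking forest.
#' @param out_dir If non-NULL, artifacts (thresholds, model, landscape,
#'   barriers, transition counts, tests, table, filter report, manifest)
#'   are written there as CSV/JSON.
#' @param n_trees,horizon Passed to [rank_features()].
#' @param missing_threshold Passed to [apply_filters()].
#' @return Object of class `ela_run` collecting every stage's output.
#' @export
run_full_analysis <- function(records, scope = c("all", "diabetes_only"),
                              features = NULL, coding = c("01", "pm1"),
                              seed = 1, out_dir = NULL,
                              n_trees = 500, horizon = 3,
                              missing_threshold = 0.3) {
  scope <- match.arg(scope)
  coding <- match.arg(coding)
  if (inherits(records, "synthetic_cohort")) records <- records$records
  records <- as.data.frame(records)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  onset_map <- stage("diagnose", diagnose_cohort(records))
  obesity <- stage("obesity", classify_cohort_obesity(records))
  filt <- stage("filter",
                apply_filters(records, onset_map,
                              missing_threshold = missing_threshold))

  ranking <- NULL
  if (is.null(features)) {
    ranking <- stage("rank_features",
                     rank_features(filt$records, onset_map, seed = seed,
                                   n_trees = n_trees, horizon = horizon))
    features <- ranking$selected
  }
  if (length(features) != 6L) stop("exactly 6 features are required")

  analysis <- filt$records
  if (scope == "diabetes_only") {
    diab <- onset_map$individual_id[!is.na(onset_map$onset_year)]
    analysis <- analysis[analysis$individual_id %in% diab, , drop = FALSE]
    if (nrow(analysis) == 0L)
      stop("stage 'scope' failed: no pre-onset records of diabetic individuals")
  }

  thresholds <- stage("thresholds", compute_thresholds(analysis, features))
  bits <- stage("binarize", binarize(analysis, thresholds))
  model <- stage("ising_fit",
                 fit_pairwise_maxent(bits, coding = coding,
                                     feature_order = features))
  landscape <- stage("landscape", energy_landscape(model))
  basins <- stage("basins", basin_graph(landscape))
  barriers <- stage("disconnectivity", disconnectivity(landscape, basins))
  barriers_modified <- stage("modified_disconnectivity",
                             modified_disconnectivity(landscape, basins))

  states <- stage("assign_states", assign_states(analysis, thresholds, basins))
  counts <- stage("transitions", count_transitions(states, basins$n_states))
  grp <- obesity$obesity[match(states$individual_id, obesity$individual_id)]
  counts_by_group <- list(
    obese = count_transitions(states[grp == "obese", , drop = FALSE],
                              basins$n_states),
    non_obese = count_transitions(states[grp == "non_obese", , drop = FALSE],
                                  basins$n_states))

  preference <- list()
  if (basins$n_states >= 3L) {
    pick <- function(m, from, to) m[from, to]
    mk <- function(p1, p2, label) {
      tab <- rbind(
        obese = c(pick(counts_by_group$obese, p1[1], p1[2]),
                  pick(counts_by_group$obese, p2[1], p2[2])),
        non_obese = c(pick(counts_by_group$non_obese, p1[1], p1[2]),
                      pick(counts_by_group$non_obese, p2[1], p2[2])))
      colnames(tab) <- c(paste0(p1[1], "to", p1[2]),
                         paste0(p2[1], "to", p2[2]))
      tryCatch(preference_test(tab), error = function(e) NULL)
    }
    preference$indirect_vs_direct <- mk(c(1, 2), c(1, 3))
    preference$via_intermediate_vs_direct <- mk(c(2, 3), c(1, 3))
  }

  pretab <- stage("pretransition", {
    tt <- transition_types_present(counts)
    pretransition_table(analysis, states,
                        transitions = tt$transitions,
                        comparisons = tt$comparisons)
  })

  config <- list(scope = scope, features = features, coding = coding,
                 seed = seed, n_trees = n_trees, horizon = horizon,
                 missing_threshold = missing_threshold)
  run <- structure(
    list(config = config, onset_map = onset_map, obesity = obesity,
         filter_report = filt$report, feature_ranking = ranking,
         thresholds = thresholds, model = model, landscape = landscape,
         basins = basins, barriers = barriers,
         barriers_modified = barriers_modified, states = states,
         transition_counts = counts, transition_counts_by_group = counts_by_group,
         preference_tests = preference, pretransition = pretab,
         n_analysis_records = nrow(analysis),
         n_analysis_individuals = length(unique(analysis$individual_id))),
    class = "ela_run"
  )
  if (!is.null(out_dir)) run$manifest <- write_run_artifacts(run, out_dir)
  run
}

# Transition types and comparison pairs actually observed in the counts.
transition_types_present <- function(counts) {
  K <- nrow(counts)
  trans <- list()
  for (a in seq_len(K)) for (b in seq_len(K))
    if (a != b && counts[a, b] > 0) trans[[length(trans) + 1L]] <- c(a, b)
  comps <- list()
  if (length(trans) >= 2L)
    for (i in seq_len(length(trans) - 1L))
      for (j in (i + 1L):length(trans))
        comps[[length(comps) + 1L]] <- list(trans[[i]], trans[[j]])
  list(transitions = trans, comparisons = comps)
}

#' @export
print.ela_run <- function(x, ...) {
  cat("Energy-landscape analysis run (scope: ", x$config$scope, ")\n",
      sep = "")
  cat("  features:", paste(x$config$features, collapse = ", "), "\n")
  cat("  analysis subset:", x$n_analysis_records, "records /",
      x$n_analysis_individuals, "individuals\n")
  cat("  states:", x$basins$n_states,
      "(sizes", paste(x$basins$state_sizes, collapse = "/"),
      "; minima", paste(x$basins$local_minima, collapse = "/"), ")\n")
  cat("  transitions counted:", sum(x$transition_counts), "\n")
  for (nm in names(x$preference_tests)) {
    pt <- x$preference_tests[[nm]]
    if (!is.null(pt))
      cat(sprintf("  preference test %s: p = %.4g\n", nm, pt$p.value))
  }
  invisible(x)
}

# Write CSV/JSON artifacts plus a manifest; returns the manifest.
write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  wjson <- function(x, f) jsonlite::write_json(
    x, path(f), auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)

  wjson(list(threshold = as.list(run$thresholds$threshold),
             reversed = as.list(run$thresholds$reversed)), "thresholds.json")
  wjson(list(h = as.list(run$model$h), J = run$model$J,
             feature_order = run$model$feature_order,
             coding = run$model$coding), "model.json")

  ls_df <- data.frame(pattern = 0:63,
                      bits = apply(all_patterns(), 1, paste, collapse = ""),
                      energy = run$landscape$energies,
                      probability = run$landscape$probabilities,
                      state = run$basins$state_of)
  utils::write.csv(ls_df, path("landscape.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$barriers$barrier),
                   path("barriers.csv"))
  utils::write.csv(as.data.frame(run$barriers_modified),
                   path("barriers_modified.csv"))
  utils::write.csv(as.data.frame(unclass(run$transition_counts)),
                   path("transitions.csv"))
  for (g in names(run$transition_counts_by_group))
    utils::write.csv(
      as.data.frame(unclass(run$transition_counts_by_group[[g]])),
      path(paste0("transitions_", g, ".csv")))
  utils::write.csv(run$pretransition, path("pretransition_table.csv"),
                   row.names = FALSE)
  wjson(run$filter_report[setdiff(names(run$filter_report), NULL)],
        "filter_report.json")
  pt <- lapply(run$preference_tests, function(p)
    if (is.null(p)) NULL else list(table = p$table, statistic = p$statistic,
                                   df = p$df, p.value = p$p.value))
  wjson(pt, "preference_tests.json")

  files <- c("thresholds.json", "model.json", "landscape.csv",
             "barriers.csv", "barriers_modified.csv", "transitions.csv",
             paste0("transitions_", names(run$transition_counts_by_group),
                    ".csv"),
             "pretransition_table.csv", "filter_report.json",
             "preference_tests.json")
  manifest <- list(
    config = run$config,
    config_checksum = config_checksum(run$config),
    package_version = as.character(utils::packageVersion("elacohort")),
    files = files)
  wjson(manifest, "manifest.json")
  manifest
}
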