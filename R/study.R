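#' Study configuration
#'
#' Bundles everything the two-round retraining protocol needs: the synthetic
#' world, the annotator cohort, the detector, and the
#' annotation-integration arms.
#'
#' @param task `"chest"` or `"brain"`.
#' @param counts per-subset case counts (see [default_subset_counts()]).
#' @param phantom a [phantom_params()].
#' @param detector a [detector_config()] (study default: linear baseline).
#' @param profiles named list of [annotator_profile()]s (default: the
#'   task's 12-annotator cohort).
#' @param threshold_mm integration matching distance (mm).
#' @param strategies integration strategies to run.
#' @param cohorts annotator cohorts for integration (`all`,
#'   `board_certified`, `resident`).
#' @param combo_cap maximum integration combinations per strategy x cohort.
#' @return object of class `study_config`.
#' @export
study_config <- function(task = c("chest", "brain"),
                         counts = default_subset_counts(),
                         phantom = phantom_params(task[1]),
                         detector = detector_config(
                           task[1], classifier = "linear_baseline"),
                         profiles = default_cohort(task[1]),
                         threshold_mm = 3.0,
                         strategies = c("AND", "OR", "VOTING"),
                         cohorts = c("all", "board_certified", "resident"),
                         combo_cap = 50L) {
  task <- match.arg(task)
  stopifnot(length(profiles) >= 1L, phantom$task == task,
            detector$task == task)
  structure(list(task = task, counts = counts, phantom = phantom,
                 detector = detector, profiles = profiles,
                 threshold_mm = threshold_mm, strategies = strategies,
                 cohorts = cohorts, combo_cap = combo_cap),
            class = "study_config")
}

score_prepared <- function(detector, pc) {
  cands <- pc$candidates
  if (!nrow(cands)) return(cands)
  cfg <- detector$config
  cands$score <- vapply(seq_along(pc$vois), function(i)
    nn_predict_prob(detector$net,
                    classifier_input(crop_center(pc$vois[[i]],
                                                 cfg$voi_edge),
                                     cfg, detector$stats)),
    numeric(1))
  cands[order(-cands$score), , drop = FALSE]
}

gt_labels <- function(cases) {
  labs <- lapply(cases, case_lesions)
  stats::setNames(labs, vapply(cases, `[[`, character(1), "case_id"))
}

ann_labels <- function(set, cases) {
  stats::setNames(lapply(cases, function(cs) case_rois(set, cs$case_id)),
                  vapply(cases, `[[`, character(1), "case_id"))
}

test_cpm <- function(detector, test_cases, prepared, hit_distance_mm = 3.0) {
  cand <- lapply(test_cases, function(cs)
    score_prepared(detector, prepared[[cs$case_id]]))
  names(cand) <- vapply(test_cases, `[[`, character(1), "case_id")
  cpm(froc(cand, test_cases, hit_distance_mm = hit_distance_mm))$cpm
}

cad_reference <- function(detector, cases, prepared) {
  out <- lapply(cases, function(cs) {
    sc <- score_prepared(detector, prepared[[cs$case_id]])
    sc[sc$score >= detector$config$display_score_threshold, , drop = FALSE]
  })
  stats::setNames(out, vapply(cases, `[[`, character(1), "case_id"))
}

#' Run the two-round annotation/retraining protocol
#'
#' The five-step protocol: (1) train Initial-CAD on the initial subset with
#' ground-truth labels; (2) every simulated annotator reads Retraining1 in
#' two passes, the second referencing Initial-CAD's displayed candidates;
#' (3) per annotator, Retrained-CAD1 is trained from scratch on initial +
#' that annotator's Retraining1 labels; (4) every annotator reads Retraining2
#' referencing their own Retrained-CAD1; (5) Retrained-CAD2 is trained on
#' initial + both retraining subsets. All models are evaluated on the
#' held-out test subset against ground-truth lesions (CPM). A failed arm is
#' recorded and the remaining arms continue.
#'
#' @param config a [study_config()].
#' @param seed master seed; the result is a pure function of
#'   `(config, seed)`.
#' @param volumes volume mode for dataset generation (default in-memory).
#' @return object of class `study_result`: `cpm_initial`, data frame
#'   `per_annotator` (annotator, tier, cpm_retrained1, cpm_retrained2,
#'   error), the Retraining1 [annotation_set()]s, and an internal `state`
#'   reused by [run_integration_experiment()].
#' @export
run_protocol <- function(config, seed = 1L, volumes = "memory") {
  manifest <- generate_dataset(config$phantom, config$counts,
                               seed = child_seed(seed, "dataset"),
                               volumes = volumes)
  dcfg <- config$detector
  subsets <- list(initial = manifest_subset(manifest, "initial"),
                  retraining1 = manifest_subset(manifest, "retraining1"),
                  retraining2 = manifest_subset(manifest, "retraining2"),
                  test = manifest_subset(manifest, "test"))
  prepared <- list()
  for (cs in manifest$cases)
    prepared[[cs$case_id]] <- prepare_case(cs, dcfg)

  initial_cases <- subsets$initial
  initial_labels <- gt_labels(initial_cases)
  initial_cad <- train_detector(dcfg, initial_cases, initial_labels,
                                seed = child_seed(seed, "train", "initial"),
                                prepared = prepared)
  cpm_initial <- test_cpm(initial_cad, subsets$test, prepared,
                          dcfg$hit_distance_mm)

  ref1 <- cad_reference(initial_cad, subsets$retraining1, prepared)
  ann1 <- list(); ann2 <- list()
  rows <- list(); models1 <- list()
  for (aid in names(config$profiles)) {
    prof <- config$profiles[[aid]]
    row <- data.frame(annotator = aid, tier = prof$tier,
                      cpm_retrained1 = NA_real_, cpm_retrained2 = NA_real_,
                      error = NA_character_, stringsAsFactors = FALSE)
    arm <- tryCatch({
      a1 <- annotate_subset(prof, manifest, "retraining1",
                            cad_by_case = ref1,
                            seed = child_seed(seed, "annotate1"))
      ann1[[aid]] <- a1
      labels1 <- c(initial_labels, ann_labels(a1, subsets$retraining1))
      cad1 <- train_detector(dcfg,
                             c(subsets$initial, subsets$retraining1),
                             labels1,
                             seed = child_seed(seed, "train", "r1", aid),
                             prepared = prepared)
      models1[[aid]] <- cad1
      row$cpm_retrained1 <- test_cpm(cad1, subsets$test, prepared,
                                     dcfg$hit_distance_mm)
      ref2 <- cad_reference(cad1, subsets$retraining2, prepared)
      a2 <- annotate_subset(prof, manifest, "retraining2",
                            cad_by_case = ref2,
                            seed = child_seed(seed, "annotate2"))
      ann2[[aid]] <- a2
      labels2 <- c(labels1, ann_labels(a2, subsets$retraining2))
      cad2 <- train_detector(dcfg,
                             c(subsets$initial, subsets$retraining1,
                               subsets$retraining2),
                             labels2,
                             seed = child_seed(seed, "train", "r2", aid),
                             prepared = prepared)
      row$cpm_retrained2 <- test_cpm(cad2, subsets$test, prepared,
                                     dcfg$hit_distance_mm)
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[aid]] <- arm
  }
  structure(list(
    task = config$task,
    cpm_initial = cpm_initial,
    per_annotator = do.call(rbind, rows),
    annotations_retraining1 = ann1,
    annotations_retraining2 = ann2,
    seed = seed,
    state = list(config = config, manifest = manifest, prepared = prepared,
                 subsets = subsets, initial_labels = initial_labels,
                 models1 = models1)),
    class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> task=%s  Initial-CAD CPM=%.3f  annotators=%d\n",
              x$task, x$cpm_initial, nrow(x$per_annotator)))
  print(x$per_annotator[, c("annotator", "tier", "cpm_retrained1",
                            "cpm_retrained2")], row.names = FALSE)
  invisible(x)
}

cohort_ids <- function(profiles, cohort) {
  if (cohort == "all") return(names(profiles))
  names(profiles)[vapply(profiles, `[[`, character(1), "tier") == cohort]
}

#' Run the annotation-integration experiment
#'
#' For each strategy (AND, OR, VOTING) and annotator cohort (all,
#' board-certified, resident), builds the integrated Retraining1 annotation
#' sets over annotator combinations, retrains one model per combination on
#' initial + integrated labels, and evaluates it on the test subset. The
#' Steel-Dwass test then compares, per cohort, the CPM distributions of the
#' single-annotator arms against each integration strategy. Integration runs
#' at the Retraining1 stage. Cohorts smaller than the strategy's arity are
#' skipped with a log entry.
#'
#' @param result a [run_protocol()] result.
#' @param seed seed for combination sampling and training.
#' @return list: data frame `combinations` (strategy, cohort, combination,
#'   cpm), list `steel_dwass` (one [steel_dwass()] result per cohort),
#'   character `skipped`.
#' @export
run_integration_experiment <- function(result, seed = 1L) {
  st <- result$state
  config <- st$config
  dcfg <- config$detector
  rows <- list(); sd_res <- list(); skipped <- character(0)
  for (cohort in config$cohorts) {
    ids <- intersect(cohort_ids(config$profiles, cohort),
                     names(result$annotations_retraining1))
    groups <- list()
    single <- result$per_annotator
    single <- single$cpm_retrained1[single$annotator %in% ids &
                                      !is.na(single$cpm_retrained1)]
    groups[["SINGLE"]] <- single
    for (strategy in config$strategies) {
      arity <- if (strategy == "VOTING") 3L else 2L
      if (length(ids) < arity) {
        skipped <- c(skipped, sprintf("%s/%s: cohort of %d below arity %d",
                                      cohort, strategy, length(ids), arity))
        next
      }
      sets <- result$annotations_retraining1[ids]
      integrated <- integrate_cohort(sets, strategy,
                                     threshold_mm = config$threshold_mm,
                                     cap = config$combo_cap,
                                     seed = child_seed(seed, "combos",
                                                       cohort, strategy))
      cpms <- vapply(names(integrated), function(nm) {
        labels <- c(st$initial_labels,
                    ann_labels(integrated[[nm]], st$subsets$retraining1))
        model <- tryCatch(
          train_detector(dcfg,
                         c(st$subsets$initial, st$subsets$retraining1),
                         labels,
                         seed = child_seed(seed, "train", cohort, strategy,
                                           nm),
                         prepared = st$prepared),
          error = function(e) NULL)
        if (is.null(model)) return(NA_real_)
        test_cpm(model, st$subsets$test, st$prepared, dcfg$hit_distance_mm)
      }, numeric(1))
      for (nm in names(cpms))
        rows[[length(rows) + 1L]] <-
          data.frame(strategy = strategy, cohort = cohort, combination = nm,
                     cpm = cpms[[nm]], stringsAsFactors = FALSE)
      groups[[strategy]] <- cpms[!is.na(cpms)]
    }
    usable <- Filter(function(g) length(g) >= 2L, groups)
    if (length(usable) >= 2L)
      sd_res[[cohort]] <- steel_dwass(usable)
  }
  list(combinations = do.call(rbind, c(list(data.frame()), rows)),
       steel_dwass = sd_res, skipped = skipped)
}

#' Summarize a study into flat tables
#'
#' @param result a [run_protocol()] result.
#' @param integration optional [run_integration_experiment()] result.
#' @param dir optional directory; when given, tables are written as CSV and
#'   the plot data as JSON.
#' @return list: `progression` (one row per annotator with CPM at each
#'   stage), `integration` (per strategy x cohort: n, mean/sd CPM),
#'   `comparisons` (Steel-Dwass pairs with significance markers).
#' @export
summarize_study <- function(result, integration = NULL, dir = NULL) {
  pa <- result$per_annotator
  progression <- if (is.null(pa) || !nrow(pa)) {
    data.frame(annotator = character(), tier = character(),
               cpm_initial = numeric(), cpm_retrained1 = numeric(),
               cpm_retrained2 = numeric())
  } else {
    data.frame(annotator = pa$annotator, tier = pa$tier,
               cpm_initial = result$cpm_initial,
               cpm_retrained1 = pa$cpm_retrained1,
               cpm_retrained2 = pa$cpm_retrained2)
  }
  integ_tab <- data.frame(strategy = character(), cohort = character(),
                          n = integer(), cpm_mean = numeric(),
                          cpm_sd = numeric())
  comp_tab <- data.frame(cohort = character(), group1 = character(),
                         group2 = character(), p = numeric(),
                         significant = character())
  if (!is.null(integration) && nrow(integration$combinations)) {
    cb <- integration$combinations
    agg <- stats::aggregate(cpm ~ strategy + cohort, cb,
                            function(v) c(n = sum(!is.na(v)),
                                          m = mean(v, na.rm = TRUE),
                                          s = stats::sd(v, na.rm = TRUE)))
    integ_tab <- data.frame(strategy = agg$strategy, cohort = agg$cohort,
                            n = as.integer(agg$cpm[, "n"]),
                            cpm_mean = agg$cpm[, "m"],
                            cpm_sd = agg$cpm[, "s"])
    for (cohort in names(integration$steel_dwass)) {
      pr <- integration$steel_dwass[[cohort]]$pairs
      comp_tab <- rbind(comp_tab,
                        data.frame(cohort = cohort, group1 = pr$group1,
                                   group2 = pr$group2, p = pr$p,
                                   significant = ifelse(pr$significant,
                                                        "*", "")))
    }
  }
  out <- list(progression = progression, integration = integ_tab,
              comparisons = comp_tab)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(progression, file.path(dir, "progression.csv"),
                     row.names = FALSE)
    utils::write.csv(integ_tab, file.path(dir, "integration.csv"),
                     row.names = FALSE)
    utils::write.csv(comp_tab, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out, file.path(dir, "plot_data.json"),
                         auto_unbox = TRUE, digits = 9, dataframe = "rows")
  }
  out
}
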