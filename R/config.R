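#' Load a study configuration from YAML or JSON
#'
#' The file may carry top-level blocks `task`, `counts`, `synthetic:`
#' (phantom parameters and a list of annotator profiles), `detector:`, and
#' `integration:` (`threshold_mm`, `strategies`, `cohorts`, `combo_cap`).
#' Unspecified fields fall back to the package defaults for the task.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [study_config()].
#' @export
load_study_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  task <- if (is.null(cfg$task)) "chest" else cfg$task
  call_with <- function(fn, args, extra = list()) {
    args <- args[intersect(names(args), names(formals(fn)))]
    do.call(fn, c(extra, args))
  }
  phantom <- call_with(phantom_params, as.list(cfg$synthetic),
                       list(task = task))
  detector <- call_with(detector_config, as.list(cfg$detector),
                        list(task = task))
  profiles <- if (!is.null(cfg$synthetic$annotators)) {
    pr <- lapply(cfg$synthetic$annotators, function(a)
      call_with(annotator_profile, as.list(a)))
    stats::setNames(pr, vapply(pr, `[[`, character(1), "annotator_id"))
  } else default_cohort(task)
  counts <- if (!is.null(cfg$counts))
    lapply(cfg$counts, function(v) as.integer(unlist(v)))
  else default_subset_counts()
  intg <- as.list(cfg$integration)
  study_config(
    task = task, counts = counts, phantom = phantom, detector = detector,
    profiles = profiles,
    threshold_mm = if (is.null(intg$threshold_mm)) 3.0 else intg$threshold_mm,
    strategies = if (is.null(intg$strategies))
      c("AND", "OR", "VOTING") else intg$strategies,
    cohorts = if (is.null(intg$cohorts))
      c("all", "board_certified", "resident") else intg$cohorts,
    combo_cap = if (is.null(intg$combo_cap)) 50L else intg$combo_cap)
}

#' Write candidates as CSV (`case_id, x_mm, y_mm, z_mm, score`)
#' @param candidates candidate data frame.
#' @param path output CSV path.
#' @export
write_candidates <- function(candidates, path) {
  out <- data.frame(case_id = candidates$case_id, x_mm = candidates$x,
                    y_mm = candidates$y, z_mm = candidates$z,
                    score = candidates$score)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character"))
  data.frame(case_id = df$case_id, x = df$x_mm, y = df$y_mm, z = df$z_mm,
             score = df$score, stringsAsFactors = FALSE)
}
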