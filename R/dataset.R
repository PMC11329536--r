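#' Default per-subset case counts (positive, negative)
#'
#' The study design: 50 positive / 0 negative initial-training cases, 40/35 in
#' each retraining subset, 50/50 in the test subset; within each retraining
#' and test subset exactly 10 negatives carry distractor structures (sub-6 mm
#' nodules or infundibular dilations / bifurcation look-alikes, by task).
#'
#' @return named list of `c(positive, negative)` per subset.
#' @export
default_subset_counts <- function() {
  list(initial = c(50L, 0L), retraining1 = c(40L, 35L),
       retraining2 = c(40L, 35L), test = c(50L, 50L))
}

#' Generate a complete synthetic dataset
#'
#' Builds phantom cases for every subset. Positive cases carry one or two
#' target lesions meeting the task's diameter floor; in each retraining and
#' test subset exactly `n_distractor_negatives` negatives (default 10) carry
#' distractor structures, the remaining negatives are plain background.
#' Per-case child seeds make the manifest independent of generation order and
#' of the volume mode.
#'
#' @param params a [phantom_params()].
#' @param counts per-subset `c(positive, negative)` counts; see
#'   [default_subset_counts()].
#' @param seed master seed.
#' @param volumes `"none"` (ground truth only; fast), `"memory"` (volumes kept
#'   in the records), or `"disk"` (NIfTI files under `dir`).
#' @param dir output directory for `volumes = "disk"`.
#' @param n_distractor_negatives distractor-bearing negatives per retraining /
#'   test subset.
#' @return a [dataset_manifest()].
#' @export
generate_dataset <- function(params, counts = default_subset_counts(),
                             seed = 1L, volumes = c("none", "memory", "disk"),
                             dir = NULL, n_distractor_negatives = 10L) {
  volumes <- match.arg(volumes)
  if (volumes == "disk") {
    if (is.null(dir)) stop("volumes='disk' requires a directory")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  }
  stopifnot(all(unlist(counts) >= 0))
  cases <- list()
  for (subset in names(counts)) {
    np <- counts[[subset]][1]; nn <- counts[[subset]][2]
    n_bearing <- if (subset == "initial") 0L else
      min(n_distractor_negatives, nn)
    # which negatives carry distractors is a seeded draw per subset
    bearing <- with_seed(child_seed(seed, "bearing", subset),
                         sample.int(max(nn, 1L), n_bearing))
    for (i in seq_len(np + nn)) {
      positive <- i <= np
      case_id <- sprintf("%s_%s_%03d", params$task, subset, i)
      cseed <- child_seed(seed, "case", case_id)
      n_les <- if (positive)
        with_seed(child_seed(seed, "nles", case_id),
                  1L + stats::rbinom(1L, 1L, 0.3)) else 0L
      n_dis <- if (!positive && (i - np) %in% bearing)
        with_seed(child_seed(seed, "ndis", case_id),
                  1L + stats::rbinom(1L, 1L, 0.5)) else 0L
      ph <- generate_phantom(params, n_les, n_dis, cseed, case_id,
                             render = volumes != "none")
      vol_path <- NULL; vol <- NULL
      if (volumes == "disk") {
        vol_path <- file.path(dir, paste0(case_id, ".nii.gz"))
        write_volume(ph$volume, vol_path)
      } else if (volumes == "memory") vol <- ph$volume
      cases[[case_id]] <- case_record(
        case_id, subset, positive, ph$rois, volume_path = vol_path,
        vol = vol, grid_dim = params$grid_dim,
        grid_spacing = rep(params$spacing_mm, 3),
        grid_origin = c(0, 0, 0))
    }
  }
  dataset_manifest(params$task, cases)
}
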