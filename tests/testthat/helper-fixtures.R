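# Shared fixture builders. Everything is generated in code; tests that need
# volumes use small grids (32-48 voxels) to stay fast.

tiny_chest_params <- function(grid = 48L)
  phantom_params("chest", grid_dim = grid,
                 lesion_diameter_range = c(6, min(18, grid %/% 3)))

tiny_brain_params <- function(grid = 48L)
  phantom_params("brain", grid_dim = grid)

fast_chest_config <- function(...)
  detector_config("chest", epochs = 4L, ...)

# one-row ROI helper with compact arguments
roi <- function(case, x, y, z, d, ann = "R1", tag = "unknown")
  spherical_roi(case, c(x, y, z), d, ann, tag)

aset <- function(ann, ...) {
  rows <- list(...)
  rois <- do.call(rbind, c(list(empty_rois()), rows))
  if (nrow(rois)) rois$annotator_id <- ann
  annotation_set(ann, rois)
}

# a case record without voxel data (grid geometry only)
gt_case <- function(id, lesions = NULL, distractors = NULL,
                    subset = "retraining1", grid = 64L) {
  gt <- empty_rois()
  for (L in lesions)
    gt <- rbind(gt, spherical_roi(id, L[1:3], L[4], "ground_truth", "lesion"))
  for (D in distractors)
    gt <- rbind(gt, spherical_roi(id, D[1:3], D[4], "ground_truth",
                                  "distractor"))
  case_record(id, subset, is_positive = !is.null(lesions), gt,
              grid_dim = rep(grid, 3L))
}

# candidate table helper
cand_df <- function(case, ...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(case_id = case, x = r[1], y = r[2], z = r[3], score = r[4],
               stringsAsFactors = FALSE)))
}

# independent brute-force FROC + CPM oracle: enumerates every threshold and
# recomputes hit/FP counts from scratch (used against froc()/cpm())
oracle_froc_cpm <- function(candidates_by_case, cases, hit_mm = 3) {
  lesions <- lapply(cases, function(cs) cs$ground_truth[
    cs$ground_truth$tag == "lesion", , drop = FALSE])
  n_lesions <- sum(vapply(lesions, nrow, integer(1)))
  all_scores <- sort(unique(unlist(lapply(candidates_by_case, function(cd)
    if (is.null(cd)) numeric(0) else cd$score))), decreasing = TRUE)
  pts <- data.frame(fp_per_case = numeric(0), sensitivity = numeric(0))
  for (th in c(Inf, all_scores)) {
    hits <- 0; fps <- 0
    for (ci in seq_along(cases)) {
      cs <- cases[[ci]]
      cd <- candidates_by_case[[cs$case_id]]
      les <- lesions[[ci]]
      taken <- logical(nrow(les))
      if (!is.null(cd) && nrow(cd)) {
        keep <- cd[cd$score >= th, , drop = FALSE]
        keep <- keep[order(-keep$score), , drop = FALSE]
        for (j in seq_len(nrow(keep))) {
          ok <- FALSE
          if (nrow(les)) {
            d <- sqrt((les$x - keep$x[j])^2 + (les$y - keep$y[j])^2 +
                        (les$z - keep$z[j])^2)
            cands <- which(!taken & d <= pmax(les$diameter_mm / 2, hit_mm))
            if (length(cands)) {
              taken[cands[which.min(d[cands])]] <- TRUE
              ok <- TRUE
            }
          }
          if (!ok) fps <- fps + 1
        }
      }
      hits <- hits + sum(taken)
    }
    pts <- rbind(pts, data.frame(fp_per_case = fps / length(cases),
                                 sensitivity = hits / n_lesions))
  }
  targets <- c(1 / 8, 1 / 4, 1 / 2, 1, 2, 4, 8)
  sens <- vapply(targets, function(f) {
    ok <- pts$fp_per_case <= f
    if (!any(ok)) {
      if (max(pts$fp_per_case) < f) pts$sensitivity[nrow(pts)] else 0
    } else max(pts$sensitivity[ok])
  }, numeric(1))
  list(points = pts, cpm = mean(sens), sens = sens)
}
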