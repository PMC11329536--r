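SUBSETS <- c("initial", "retraining1", "retraining2", "test")

#' Case records and dataset manifests
#'
#' A `case_record` ties a case id to its protocol subset, positivity flag,
#' ground-truth ROI table, an optional volume path (NIfTI on disk) or in-memory
#' [volume()], and the grid geometry (dims, spacing, origin) so annotator
#' simulation can run without loading voxel data. A `dataset_manifest`
#' collects case records for one task.
#'
#' @param case_id case identifier.
#' @param subset one of `initial`, `retraining1`, `retraining2`, `test`.
#' @param is_positive logical; positive cases must carry >= 1 lesion-tagged
#'   ground-truth ROI, negative cases none (distractor ROIs allowed).
#' @param ground_truth ROI data frame (annotator `"ground_truth"`).
#' @param volume_path optional path to the case volume on disk.
#' @param vol optional in-memory [volume()].
#' @param grid_dim,grid_spacing,grid_origin grid geometry (taken from `vol`
#'   when given).
#' @return an object of class `case_record`.
#' @export
case_record <- function(case_id, subset, is_positive,
                        ground_truth = empty_rois(), volume_path = NULL,
                        vol = NULL, grid_dim = c(64L, 64L, 64L),
                        grid_spacing = c(1, 1, 1),
                        grid_origin = c(0, 0, 0)) {
  subset <- match.arg(subset, SUBSETS)
  ground_truth <- validate_rois(ground_truth)
  n_lesion <- sum(ground_truth$tag == "lesion")
  if (is_positive && n_lesion < 1L)
    stop(sprintf("positive case %s must have >= 1 lesion ROI", case_id))
  if (!is_positive && n_lesion > 0L)
    stop(sprintf("negative case %s must have no lesion ROIs", case_id))
  if (!is.null(vol)) {
    grid_dim <- dim(vol$voxels); grid_spacing <- vol$spacing
    grid_origin <- vol$origin
  }
  structure(list(case_id = as.character(case_id), subset = subset,
                 is_positive = isTRUE(is_positive),
                 ground_truth = ground_truth,
                 volume_path = volume_path, volume = vol,
                 grid_dim = as.integer(grid_dim),
                 grid_spacing = as.numeric(grid_spacing),
                 grid_origin = as.numeric(grid_origin)),
            class = "case_record")
}

#' @rdname case_record
#' @param task `"chest"` or `"brain"`.
#' @param cases list of `case_record`s with unique ids.
#' @return `dataset_manifest()` returns an object of class `dataset_manifest`
#'   with a `counts` table (positive/negative per subset).
#' @export
dataset_manifest <- function(task, cases) {
  task <- match.arg(task, c("chest", "brain"))
  ids <- vapply(cases, `[[`, character(1), "case_id")
  if (anyDuplicated(ids)) stop("duplicate case ids in manifest")
  subs <- vapply(cases, `[[`, character(1), "subset")
  pos <- vapply(cases, `[[`, logical(1), "is_positive")
  counts <- sapply(SUBSETS, function(s)
    c(positive = sum(pos[subs == s]), negative = sum(!pos[subs == s])))
  structure(list(task = task, cases = stats::setNames(cases, ids),
                 counts = counts), class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest> task=%s  cases=%d\n", x$task,
              length(x$cases)))
  print(x$counts)
  invisible(x)
}

#' Cases of one subset
#' @param manifest a [dataset_manifest()].
#' @param subset subset name.
#' @return list of case records.
#' @export
manifest_subset <- function(manifest, subset) {
  subset <- match.arg(subset, SUBSETS)
  Filter(function(cs) cs$subset == subset, manifest$cases)
}

#' Load the voxel grid of a case (from memory or its NIfTI path).
#' @param case a [case_record()].
#' @param task task label for [read_volume()].
#' @return a [volume()].
#' @export
case_volume <- function(case, task = "chest") {
  if (!is.null(case$volume)) return(case$volume)
  if (!is.null(case$volume_path)) return(read_volume(case$volume_path, task))
  stop(sprintf("case %s has no volume (generated with volumes='none')",
               case$case_id))
}

#' Ground-truth lesions of a case (lesion-tagged ROIs only).
#' @param case a [case_record()].
#' @return ROI data frame.
#' @export
case_lesions <- function(case) {
  gt <- case$ground_truth
  gt[gt$tag == "lesion", , drop = FALSE]
}

#' Read/write a dataset manifest as JSON
#'
#' @param manifest a [dataset_manifest()].
#' @param path JSON path.
#' @return `read_manifest()` returns a [dataset_manifest()] (volumes
#'   referenced by path, not loaded).
#' @export
write_manifest <- function(manifest, path) {
  recs <- lapply(unname(manifest$cases), function(cs) {
    gt <- cs$ground_truth
    list(case_id = cs$case_id, subset = cs$subset,
         is_positive = cs$is_positive,
         volume_path = if (is.null(cs$volume_path)) NULL else cs$volume_path,
         grid_dim = cs$grid_dim, grid_spacing = cs$grid_spacing,
         grid_origin = cs$grid_origin,
         ground_truth = lapply(seq_len(nrow(gt)), function(i)
           list(centroid_mm = c(gt$x[i], gt$y[i], gt$z[i]),
                diameter_mm = gt$diameter_mm[i], tag = gt$tag[i])))
  })
  jsonlite::write_json(list(task = manifest$task, cases = recs), path,
                       auto_unbox = TRUE, digits = 9)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cases <- lapply(obj$cases, function(r) {
    gt <- do.call(rbind, c(list(empty_rois()), lapply(r$ground_truth,
      function(g) spherical_roi(r$case_id, unlist(g$centroid_mm),
                                g$diameter_mm, "ground_truth", g$tag))))
    case_record(r$case_id, r$subset, isTRUE(r$is_positive), gt,
                volume_path = r$volume_path,
                grid_dim = unlist(r$grid_dim),
                grid_spacing = unlist(r$grid_spacing),
                grid_origin = unlist(r$grid_origin))
  })
  dataset_manifest(obj$task, cases)
}
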