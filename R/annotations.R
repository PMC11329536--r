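ROI_TAGS <- c("lesion", "distractor", "unknown")
ROI_COLS <- c("case_id", "x", "y", "z", "diameter_mm", "annotator_id", "tag")

#' Spherical ROI annotations
#'
#' Annotations are stored as data frames with one row per spherical ROI and
#' columns `case_id`, `x`, `y`, `z` (world-mm centroid), `diameter_mm`,
#' `annotator_id`, and `tag` (`lesion`, `distractor`, or `unknown`).
#' `spherical_roi()` builds such a row; an `annotation_set` wraps one
#' annotator's ROI table.
#'
#' @param case_id case identifier.
#' @param centroid numeric length-3 world-mm centroid.
#' @param diameter_mm sphere diameter in mm, > 0.
#' @param annotator_id annotator identifier (or `"ground_truth"`,
#'   `"integrated"`).
#' @param tag one of `"lesion"`, `"distractor"`, `"unknown"`.
#' @return a one-row ROI data frame.
#' @export
spherical_roi <- function(case_id, centroid, diameter_mm,
                          annotator_id = "ground_truth", tag = "lesion") {
  stopifnot(length(centroid) == 3L, all(is.finite(centroid)),
            is.finite(diameter_mm), diameter_mm > 0, tag %in% ROI_TAGS)
  data.frame(case_id = as.character(case_id),
             x = centroid[1], y = centroid[2], z = centroid[3],
             diameter_mm = as.numeric(diameter_mm),
             annotator_id = as.character(annotator_id),
             tag = tag, stringsAsFactors = FALSE)
}

#' An empty ROI table with the canonical columns.
#' @return zero-row ROI data frame.
#' @export
empty_rois <- function() {
  data.frame(case_id = character(), x = numeric(), y = numeric(),
             z = numeric(), diameter_mm = numeric(),
             annotator_id = character(), tag = character(),
             stringsAsFactors = FALSE)
}

validate_rois <- function(rois) {
  if (is.null(rois)) return(empty_rois())
  missing <- setdiff(ROI_COLS, names(rois))
  if (length(missing))
    stop("ROI table missing columns: ", paste(missing, collapse = ", "))
  if (nrow(rois)) {
    if (any(!is.finite(rois$diameter_mm)) || any(rois$diameter_mm <= 0))
      stop("all ROI diameters must be positive and finite")
    if (any(!is.finite(as.matrix(rois[, c("x", "y", "z")]))))
      stop("all ROI centroids must be finite")
    if (any(!rois$tag %in% ROI_TAGS))
      stop("ROI tag must be one of: ", paste(ROI_TAGS, collapse = ", "))
  }
  rois[ROI_COLS]
}

#' @rdname spherical_roi
#' @param rois ROI data frame; all rows must carry `annotator_id`.
#' @return `annotation_set()` returns an object of class `annotation_set`
#'   with fields `annotator_id` and `rois`.
#' @export
annotation_set <- function(annotator_id, rois = empty_rois()) {
  rois <- validate_rois(rois)
  if (nrow(rois) && any(rois$annotator_id != annotator_id))
    stop("every ROI's annotator_id must equal the set's annotator_id")
  structure(list(annotator_id = as.character(annotator_id),
                 rois = rois), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> annotator=%s  rois=%d  cases=%d\n",
              x$annotator_id, nrow(x$rois), length(unique(x$rois$case_id))))
  invisible(x)
}

#' ROIs of one case from an annotation set (or raw ROI table).
#' @param set an `annotation_set` or ROI data frame.
#' @param case_id case to extract.
#' @return ROI data frame.
#' @export
case_rois <- function(set, case_id) {
  rois <- if (inherits(set, "annotation_set")) set$rois else set
  rois[rois$case_id == case_id, , drop = FALSE]
}

roi_table <- function(sets) {
  if (inherits(sets, "annotation_set")) sets <- list(sets)
  do.call(rbind, c(list(empty_rois()), lapply(sets, `[[`, "rois")))
}

#' Read and write spherical-ROI annotation files
#'
#' The on-disk dialect is a JSON list of records
#' `{"annotator_id", "case_id", "centroid_mm": [x,y,z], "diameter_mm", "tag"}`,
#' or an equivalent flat CSV with columns
#' `annotator_id, case_id, x, y, z, diameter_mm, tag`. Floats are written with
#' 9 significant digits so 3 mm threshold decisions are reproducible.
#'
#' @param path file path; format chosen by extension (`.json` or `.csv`).
#' @return `read_annotations()` returns a named list of [annotation_set()]s,
#'   one per annotator, ordered by annotator id.
#' @export
read_annotations <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(annotator_id = "character",
                                         case_id = "character"))
    need <- c("annotator_id", "case_id", "x", "y", "z", "diameter_mm", "tag")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("annotation CSV missing columns: ", paste(miss, collapse = ", "))
  } else {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (length(recs) == 0L) return(list())
    df <- do.call(rbind, lapply(seq_along(recs), function(i) {
      r <- recs[[i]]
      for (f in c("annotator_id", "case_id", "centroid_mm", "diameter_mm"))
        if (is.null(r[[f]]))
          stop(sprintf("annotation record %d: missing required field '%s'",
                       i, f))
      if (length(r$centroid_mm) != 3L)
        stop(sprintf("annotation record %d: centroid_mm must have 3 entries", i))
      data.frame(case_id = as.character(r$case_id),
                 x = as.numeric(r$centroid_mm[[1]]),
                 y = as.numeric(r$centroid_mm[[2]]),
                 z = as.numeric(r$centroid_mm[[3]]),
                 diameter_mm = as.numeric(r$diameter_mm),
                 annotator_id = as.character(r$annotator_id),
                 tag = if (is.null(r$tag)) "unknown" else as.character(r$tag),
                 stringsAsFactors = FALSE)
    }))
  }
  df <- validate_rois(df[ROI_COLS])
  ids <- sort(unique(df$annotator_id))
  sets <- lapply(ids, function(a)
    annotation_set(a, df[df$annotator_id == a, , drop = FALSE]))
  stats::setNames(sets, ids)
}

#' @rdname read_annotations
#' @param sets a list of [annotation_set()]s (or a single one).
#' @export
write_annotations <- function(sets, path) {
  df <- roi_table(sets)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    out <- df[, c("annotator_id", "case_id", "x", "y", "z",
                  "diameter_mm", "tag")]
    for (col in c("x", "y", "z", "diameter_mm"))
      out[[col]] <- signif(out[[col]], 9)
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    recs <- lapply(seq_len(nrow(df)), function(i)
      list(annotator_id = df$annotator_id[i], case_id = df$case_id[i],
           centroid_mm = c(df$x[i], df$y[i], df$z[i]),
           diameter_mm = df$diameter_mm[i], tag = df$tag[i]))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = 9)
  }
  invisible(path)
}
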