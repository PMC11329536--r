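#' Match spherical-ROI annotations across annotators
#'
#' Within each case, centroid distances between ROIs of different annotators
#' are measured exhaustively; pairs within `threshold_mm` are linked greedily
#' in ascending distance order, one-to-one per annotator pair (ties broken by
#' annotator id, then ROI order). Groups are the connected components of the
#' link graph. A group whose members span more than `threshold_mm` end to end
#' (possible through transitive links) is flagged with `chain = TRUE`.
#' Annotator sets are canonicalized by annotator id, so the result is
#' invariant to input order.
#'
#' @param sets list of [annotation_set()]s (distinct annotator ids).
#' @param threshold_mm matching distance (mm), default 3.
#' @return object of class `match_result`: `groups` (list of ROI data frames,
#'   each with >= 2 members and a `chain` attribute), `unmatched` (ROI data
#'   frame), `threshold_mm`.
#' @export
match_annotations <- function(sets, threshold_mm = 3.0) {
  stopifnot(threshold_mm > 0)
  if (inherits(sets, "annotation_set")) sets <- list(sets)
  ids <- vapply(sets, `[[`, character(1), "annotator_id")
  if (anyDuplicated(ids)) stop("annotator ids must be distinct")
  sets <- sets[order(ids)]
  all_rois <- roi_table(sets)
  if (nrow(all_rois)) {
    key <- paste(all_rois$annotator_id, all_rois$case_id, all_rois$x,
                 all_rois$y, all_rois$z, all_rois$diameter_mm)
    if (anyDuplicated(key))
      stop("duplicate ROI within one annotator's case list")
  }
  groups <- list(); unmatched <- empty_rois()
  for (cid in unique(all_rois$case_id)) {
    rois <- all_rois[all_rois$case_id == cid, , drop = FALSE]
    n <- nrow(rois)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    # exhaustive inter-annotator distances
    links <- NULL
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (rois$annotator_id[i] == rois$annotator_id[j]) next
      d <- sqrt((rois$x[i] - rois$x[j])^2 + (rois$y[i] - rois$y[j])^2 +
                  (rois$z[i] - rois$z[j])^2)
      if (d <= threshold_mm) links <- rbind(links, c(i, j, d))
    }
    if (!is.null(links)) {
      ord <- order(links[, 3], rois$annotator_id[links[, 1]],
                   rois$annotator_id[links[, 2]], links[, 1], links[, 2])
      links <- links[ord, , drop = FALSE]
      # one-to-one per ordered annotator pair
      used <- character(0)
      for (k in seq_len(nrow(links))) {
        i <- as.integer(links[k, 1]); j <- as.integer(links[k, 2])
        ki <- paste(i, rois$annotator_id[j]); kj <- paste(j, rois$annotator_id[i])
        if (ki %in% used || kj %in% used) next
        used <- c(used, ki, kj)
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      members <- rois[roots == r, , drop = FALSE]
      if (nrow(members) == 1L) {
        unmatched <- rbind(unmatched, members)
      } else {
        dmax <- 0
        for (a in seq_len(nrow(members) - 1L))
          for (b in (a + 1L):nrow(members))
            dmax <- max(dmax, sqrt((members$x[a] - members$x[b])^2 +
                                     (members$y[a] - members$y[b])^2 +
                                     (members$z[a] - members$z[b])^2))
        attr(members, "chain") <- dmax > threshold_mm
        groups[[length(groups) + 1L]] <- members
      }
    }
  }
  structure(list(groups = groups, unmatched = unmatched,
                 threshold_mm = threshold_mm), class = "match_result")
}

#' Merge a matched group into one integrated ROI
#'
#' The integrated centroid is the arithmetic mean of member centroids and the
#' integrated size the arithmetic mean of member diameters (volume averaging
#' available via `average = "volume"`).
#'
#' @param group ROI data frame (>= 1 row, one case).
#' @param average `"diameter"` (default) or `"volume"`.
#' @return one-row ROI data frame with annotator `"integrated"`.
#' @export
merge_group <- function(group, average = c("diameter", "volume")) {
  average <- match.arg(average)
  stopifnot(nrow(group) >= 1L)
  d <- if (average == "diameter") mean(group$diameter_mm)
  else mean(group$diameter_mm^3)^(1 / 3)
  tag <- if (length(unique(group$tag)) == 1L) group$tag[1] else "unknown"
  spherical_roi(group$case_id[1],
                c(mean(group$x), mean(group$y), mean(group$z)),
                d, "integrated", tag)
}

integrated_set <- function(rois) {
  if (nrow(rois)) rois$annotator_id <- "integrated"
  annotation_set("integrated", rois)
}

#' Integrate two annotation sets by AND / OR, or three by VOTING
#'
#' `integrate_and` keeps one merged ROI per matched group containing both
#' annotators; unmatched ROIs are discarded. `integrate_or` keeps merged
#' groups plus all unmatched ROIs from both annotators (geometry verbatim,
#' re-tagged `"integrated"`). `integrate_voting` is
#' `integrate_and(integrate_or(A, B), C)`: OR between the first two
#' annotators, then AND with the third; intermediate merged ROIs enter the
#' second matching with their averaged centroids.
#'
#' @param A,B,C [annotation_set()]s.
#' @param threshold_mm matching distance (mm).
#' @return an [annotation_set()] with annotator id `"integrated"`.
#' @export
integrate_and <- function(A, B, threshold_mm = 3.0) {
  mr <- match_annotations(list(A, B), threshold_mm)
  both <- Filter(function(g) all(c(A$annotator_id, B$annotator_id) %in%
                                   g$annotator_id), mr$groups)
  rois <- do.call(rbind, c(list(empty_rois()), lapply(both, merge_group)))
  integrated_set(rois)
}

#' @rdname integrate_and
#' @export
integrate_or <- function(A, B, threshold_mm = 3.0) {
  mr <- match_annotations(list(A, B), threshold_mm)
  rois <- do.call(rbind, c(list(empty_rois()),
                           lapply(mr$groups, merge_group),
                           list(mr$unmatched)))
  integrated_set(rois)
}

#' @rdname integrate_and
#' @export
integrate_voting <- function(A, B, C, threshold_mm = 3.0) {
  or_ab <- integrate_or(A, B, threshold_mm)
  # the third reader must carry a distinct id for the second matching pass
  crois <- C$rois
  if (nrow(crois)) crois$annotator_id <- paste0("third:", C$annotator_id)
  third <- annotation_set(paste0("third:", C$annotator_id), crois)
  integrate_and(or_ab, third, threshold_mm)
}

#' Integrate all pair/triple combinations from a cohort
#'
#' Enumerates unordered annotator pairs (AND, OR) or canonical triples
#' (VOTING: unordered `{first, second}` times a distinct third) from the
#' cohort. When the number of combinations exceeds `cap`, a seeded random
#' sample of `cap` combinations is drawn.
#'
#' @param sets named list of [annotation_set()]s (the cohort).
#' @param strategy `"AND"`, `"OR"`, or `"VOTING"`.
#' @param threshold_mm matching distance (mm).
#' @param cap maximum number of combinations (default 50).
#' @param seed seed for combination sampling.
#' @return named list of integrated [annotation_set()]s; names record the
#'   contributing annotators.
#' @export
integrate_cohort <- function(sets, strategy = c("AND", "OR", "VOTING"),
                             threshold_mm = 3.0, cap = 50L, seed = 1L) {
  strategy <- match.arg(strategy)
  n <- length(sets)
  arity <- if (strategy == "VOTING") 3L else 2L
  if (n < arity)
    stop(sprintf("cohort of %d is too small for %s (needs %d annotators)",
                 n, strategy, arity))
  ids <- vapply(sets, `[[`, character(1), "annotator_id")
  combos <- if (arity == 2L) {
    cm <- utils::combn(n, 2L)
    lapply(seq_len(ncol(cm)), function(k) cm[, k])
  } else {
    cm <- utils::combn(n, 2L)
    out <- list()
    for (k in seq_len(ncol(cm))) for (third in setdiff(seq_len(n), cm[, k]))
      out[[length(out) + 1L]] <- c(cm[, k], third)
    out
  }
  if (length(combos) > cap)
    combos <- combos[with_seed(child_seed(seed, "combos", strategy),
                               sort(sample.int(length(combos), cap)))]
  res <- lapply(combos, function(ix) {
    if (strategy == "AND") integrate_and(sets[[ix[1]]], sets[[ix[2]]],
                                         threshold_mm)
    else if (strategy == "OR") integrate_or(sets[[ix[1]]], sets[[ix[2]]],
                                            threshold_mm)
    else integrate_voting(sets[[ix[1]]], sets[[ix[2]]], sets[[ix[3]]],
                          threshold_mm)
  })
  names(res) <- vapply(combos, function(ix)
    paste(ids[ix], collapse = "+"), character(1))
  res
}
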