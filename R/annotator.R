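#' Simulated annotator profile
#'
#' Captures the observable error modes of a human annotator marking spherical
#' ROIs: lesions are detected with probability logistic in diameter
#' (`plogis((d - sens_d50) / sens_scale)`), marked ROIs get isotropic Gaussian
#' centroid jitter and multiplicative lognormal diameter noise, distractor
#' structures are mistaken for lesions with a fixed probability, and spurious
#' ROIs arrive as a Poisson count per case. Two further probabilities govern
#' the CAD-assisted second reading pass: accepting a CAD candidate that hits a
#' previously missed lesion, and accepting a CAD false positive.
#'
#' @param annotator_id identifier.
#' @param tier `"board_certified"` or `"resident"` (informational; behaviour
#'   is set only by the numeric parameters).
#' @param sens_d50 diameter (mm) at which detection probability reaches half
#'   its plateau; use `-Inf` for a perfectly sensitive annotator.
#' @param sens_scale logistic scale (mm).
#' @param sens_max sensitivity plateau: detection probability is
#'   `sens_max * plogis((d - sens_d50) / sens_scale)`.
#' @param fp_rate mean false annotations per case (Poisson).
#' @param centroid_jitter_sd per-axis centroid jitter SD (mm).
#' @param diameter_jitter_sd SD of `log` diameter noise (relative).
#' @param distractor_confusion_prob probability of annotating a distractor.
#' @param cad_rescue_prob probability of accepting a CAD candidate on a
#'   missed lesion in the second pass.
#' @param cad_fp_accept_prob probability of accepting a CAD false positive in
#'   the second pass.
#' @return an object of class `annotator_profile`.
#' @export
annotator_profile <- function(annotator_id,
                              tier = c("board_certified", "resident"),
                              sens_d50 = 4, sens_scale = 1, sens_max = 1,
                              fp_rate = 0.5, centroid_jitter_sd = 0.5,
                              diameter_jitter_sd = 0.08,
                              distractor_confusion_prob = 0.1,
                              cad_rescue_prob = 0.6,
                              cad_fp_accept_prob = 0.15) {
  tier <- match.arg(tier)
  probs <- c(distractor_confusion_prob, cad_rescue_prob, cad_fp_accept_prob,
             sens_max)
  stopifnot(all(probs >= 0 & probs <= 1), fp_rate >= 0,
            centroid_jitter_sd >= 0, diameter_jitter_sd >= 0, sens_scale > 0)
  structure(list(annotator_id = as.character(annotator_id), tier = tier,
                 sens_d50 = sens_d50, sens_scale = sens_scale,
                 sens_max = sens_max,
                 fp_rate = fp_rate, centroid_jitter_sd = centroid_jitter_sd,
                 diameter_jitter_sd = diameter_jitter_sd,
                 distractor_confusion_prob = distractor_confusion_prob,
                 cad_rescue_prob = cad_rescue_prob,
                 cad_fp_accept_prob = cad_fp_accept_prob),
            class = "annotator_profile")
}

#' A noise-free profile: perfect sensitivity, no jitter, no false ROIs.
#' @param annotator_id identifier.
#' @return an [annotator_profile()].
#' @export
noise_free_profile <- function(annotator_id = "oracle") {
  annotator_profile(annotator_id, sens_d50 = -Inf, sens_scale = 1,
                    fp_rate = 0, centroid_jitter_sd = 0,
                    diameter_jitter_sd = 0, distractor_confusion_prob = 0,
                    cad_rescue_prob = 1, cad_fp_accept_prob = 0)
}

#' Detection probability of a profile at given lesion diameters.
#' @param profile an [annotator_profile()].
#' @param diameter_mm numeric vector of diameters.
#' @return probabilities in `[0, 1]`.
#' @export
profile_sensitivity <- function(profile, diameter_mm) {
  smax <- if (is.null(profile$sens_max)) 1 else profile$sens_max
  if (identical(profile$sens_d50, -Inf))
    return(rep(smax, length(diameter_mm)))
  smax * stats::plogis((diameter_mm - profile$sens_d50) / profile$sens_scale)
}

#' Default 12-annotator cohort for a task
#'
#' Tier composition follows the study design: 5 board-certified and 7
#' resident annotators for the chest task, 4 and 8 for the brain task.
#' Individual parameters are drawn around tier means with a heterogeneity
#' factor; the tiers differ only through these configurable parameters.
#'
#' @param task `"chest"` or `"brain"`.
#' @param seed seed for the per-annotator parameter draws.
#' @param heterogeneity multiplier on the between-annotator parameter spread.
#' @return named list of [annotator_profile()]s.
#' @export
default_cohort <- function(task = c("chest", "brain"), seed = 1L,
                           heterogeneity = 1) {
  task <- match.arg(task)
  tiers <- if (task == "chest")
    c(rep("board_certified", 5), rep("resident", 7))
  else c(rep("board_certified", 4), rep("resident", 8))
  base <- list(
    board_certified = list(d50 = if (task == "chest") 4.0 else 1.6,
                           scale = 1.0, fp = 0.3, cj = 0.5, dj = 0.08,
                           dc = 0.10, cr = 0.7, cf = 0.10),
    resident        = list(d50 = if (task == "chest") 5.2 else 2.2,
                           scale = 1.3, fp = 0.8, cj = 0.8, dj = 0.12,
                           dc = 0.25, cr = 0.6, cf = 0.20))
  profiles <- list()
  for (i in seq_along(tiers)) {
    b <- base[[tiers[i]]]
    id <- sprintf("%s%02d", if (tiers[i] == "board_certified") "B" else "R",
                  i)
    profiles[[id]] <- with_seed(child_seed(seed, "profile", id), {
      h <- heterogeneity
      annotator_profile(
        id, tiers[i],
        sens_d50 = b$d50 + stats::rnorm(1, 0, 0.6 * h),
        sens_scale = b$scale * exp(stats::rnorm(1, 0, 0.2 * h)),
        fp_rate = max(0, b$fp * exp(stats::rnorm(1, 0, 0.4 * h))),
        centroid_jitter_sd = b$cj * exp(stats::rnorm(1, 0, 0.25 * h)),
        diameter_jitter_sd = b$dj * exp(stats::rnorm(1, 0, 0.25 * h)),
        distractor_confusion_prob =
          min(1, max(0, b$dc + stats::rnorm(1, 0, 0.05 * h))),
        cad_rescue_prob = min(1, max(0, b$cr + stats::rnorm(1, 0, 0.1 * h))),
        cad_fp_accept_prob =
          min(1, max(0, b$cf + stats::rnorm(1, 0, 0.05 * h))))
    })
  }
  profiles
}

jitter_roi <- function(roi, profile, annotator_id) {
  cj <- profile$centroid_jitter_sd
  dj <- profile$diameter_jitter_sd
  spherical_roi(
    roi$case_id,
    c(roi$x, roi$y, roi$z) + stats::rnorm(3, 0, cj),
    roi$diameter_mm * exp(stats::rnorm(1, 0, dj)),
    annotator_id, "unknown")
}

#' Simulate one annotator reading one case
#'
#' Pass 1 (unassisted): each ground-truth lesion is marked independently with
#' probability [profile_sensitivity()] of its diameter; marked ROIs receive
#' centroid and diameter jitter. Each distractor is marked (as if it were a
#' lesion) with `distractor_confusion_prob`. `Poisson(fp_rate)` additional
#' false ROIs are placed, preferentially at distractor structures when
#' present, else uniformly inside the case grid. Pass 2 (only when
#' `cad_candidates` is given): each candidate within `hit_distance_mm` of a
#' lesion missed in pass 1 rescues that lesion with `cad_rescue_prob`; each
#' candidate farther than `hit_distance_mm` from all true lesions is accepted
#' as a new ROI with `cad_fp_accept_prob`.
#'
#' @param profile an [annotator_profile()].
#' @param case a [case_record()] with ground truth.
#' @param cad_candidates optional candidate data frame for this case (columns
#'   `case_id, x, y, z, score`, optional `radius_mm`).
#' @param seed integer seed; annotations are a deterministic function of
#'   `(profile, case, cad_candidates, seed)`.
#' @param hit_distance_mm matching distance for the CAD pass (default 3).
#' @return ROI data frame carrying `profile$annotator_id`.
#' @export
simulate_annotation <- function(profile, case, cad_candidates = NULL,
                                seed = 1L, hit_distance_mm = 3.0) {
  stopifnot(inherits(profile, "annotator_profile"),
            inherits(case, "case_record"))
  if (!is.null(cad_candidates) && nrow(cad_candidates) &&
      any(cad_candidates$case_id != case$case_id))
    stop("cad_candidates must belong to the annotated case")
  gt <- case$ground_truth
  lesions <- gt[gt$tag == "lesion", , drop = FALSE]
  distractors <- gt[gt$tag == "distractor", , drop = FALSE]
  aid <- profile$annotator_id
  out <- empty_rois()

  out <- with_seed(child_seed(seed, case$case_id, aid, "pass1"), {
    hit <- logical(nrow(lesions))
    if (nrow(lesions)) {
      p <- profile_sensitivity(profile, lesions$diameter_mm)
      hit <- stats::runif(nrow(lesions)) < p
      for (i in which(hit))
        out <- rbind(out, jitter_roi(lesions[i, ], profile, aid))
    }
    if (nrow(distractors)) {
      take <- stats::runif(nrow(distractors)) <
        profile$distractor_confusion_prob
      for (i in which(take))
        out <- rbind(out, jitter_roi(distractors[i, ], profile, aid))
    }
    n_fp <- stats::rpois(1, profile$fp_rate)
    if (n_fp > 0) {
      fov <- case$grid_dim * case$grid_spacing
      d_fp <- exp(stats::rnorm(n_fp, log(if (nrow(gt)) mean(gt$diameter_mm)
                                         else fov[1] / 10), 0.25))
      for (j in seq_len(n_fp)) {
        at_distractor <- nrow(distractors) > 0 && stats::runif(1) < 0.5
        p <- if (at_distractor) {
          k <- sample.int(nrow(distractors), 1)
          c(distractors$x[k], distractors$y[k], distractors$z[k]) +
            stats::rnorm(3, 0, 1)
        } else case$grid_origin + stats::runif(3, 0.1, 0.9) * fov
        out <- rbind(out, spherical_roi(case$case_id, p,
                                        max(d_fp[j], 1), aid, "unknown"))
      }
    }
    attr(out, "hit") <- hit
    out
  })
  hit <- attr(out, "hit"); attr(out, "hit") <- NULL

  if (!is.null(cad_candidates) && nrow(cad_candidates)) {
    out <- with_seed(child_seed(seed, case$case_id, aid, "pass2"), {
      missed <- which(!hit)
      for (j in seq_len(nrow(cad_candidates))) {
        cand <- c(cad_candidates$x[j], cad_candidates$y[j],
                  cad_candidates$z[j])
        if (nrow(lesions)) {
          d <- sqrt((lesions$x - cand[1])^2 + (lesions$y - cand[2])^2 +
                      (lesions$z - cand[3])^2)
        } else d <- numeric(0)
        near <- which(d <= hit_distance_mm)
        near_missed <- intersect(near, missed)
        if (length(near_missed)) {
          i <- near_missed[which.min(d[near_missed])]
          if (stats::runif(1) < profile$cad_rescue_prob) {
            out <- rbind(out, jitter_roi(lesions[i, ], profile, aid))
            missed <- setdiff(missed, i)
          }
        } else if (!length(near)) {
          if (stats::runif(1) < profile$cad_fp_accept_prob) {
            dmm <- if (!is.null(cad_candidates$radius_mm) &&
                       is.finite(cad_candidates$radius_mm[j]))
              2 * cad_candidates$radius_mm[j]
            else if (nrow(gt)) mean(gt$diameter_mm) else 6
            out <- rbind(out, spherical_roi(case$case_id, cand, dmm, aid,
                                            "unknown"))
          }
        }
      }
      out
    })
  }
  out
}

#' Simulate an annotator over a whole subset
#'
#' @param profile an [annotator_profile()].
#' @param manifest a [dataset_manifest()].
#' @param subset subset to annotate.
#' @param cad_by_case optional named list of candidate data frames (the CAD
#'   reference for pass 2), keyed by case id.
#' @param seed master seed; per-case child streams.
#' @return an [annotation_set()].
#' @export
annotate_subset <- function(profile, manifest, subset = "retraining1",
                            cad_by_case = NULL, seed = 1L) {
  cases <- manifest_subset(manifest, subset)
  rois <- do.call(rbind, c(list(empty_rois()), lapply(cases, function(cs)
    simulate_annotation(profile, cs, cad_by_case[[cs$case_id]], seed))))
  annotation_set(profile$annotator_id, rois)
}

#' Recover annotator error parameters from annotations and ground truth
#'
#' Matches each case's annotations to ground-truth lesions with the greedy
#' centroid rule at `threshold_mm` and reports moment estimates: empirical
#' sensitivity per diameter bin, false annotations per case, per-axis
#' centroid-jitter SD, and the SD of log diameter ratios over matched pairs.
#'
#' @param annotations an [annotation_set()].
#' @param manifest a [dataset_manifest()] holding ground truth for every
#'   annotated case.
#' @param subset optional subset restriction (default: all cases).
#' @param threshold_mm matching distance (mm).
#' @param diameter_breaks bin edges for the sensitivity table.
#' @return list with `sensitivity` (data frame: bin, n_lesions, n_detected,
#'   sensitivity), `fp_rate`, `centroid_jitter_sd`, `diameter_jitter_sd`,
#'   `n_cases`, `defined` (FALSE when the annotation set is empty).
#' @export
estimate_profile <- function(annotations, manifest, subset = NULL,
                             threshold_mm = 3.0,
                             diameter_breaks = c(0, 4, 6, 8, 12, Inf)) {
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(manifest, "dataset_manifest"))
  unknown <- setdiff(unique(annotations$rois$case_id), names(manifest$cases))
  if (length(unknown))
    stop("annotations reference cases absent from the manifest: ",
         paste(unknown, collapse = ", "))
  cases <- if (is.null(subset)) manifest$cases
  else manifest_subset(manifest, subset)
  if (!nrow(annotations$rois)) {
    return(list(sensitivity = NULL, fp_rate = NA_real_,
                centroid_jitter_sd = NA_real_, diameter_jitter_sd = NA_real_,
                n_cases = length(cases), defined = FALSE))
  }
  offsets <- c(); log_ratios <- c(); fp_counts <- c()
  les_d <- c(); det <- c()
  for (cs in cases) {
    ann <- case_rois(annotations, cs$case_id)
    lesions <- case_lesions(cs)
    gt_set <- annotation_set("ground_truth", lesions)
    ann_set <- annotation_set(annotations$annotator_id, ann)
    mr <- match_annotations(list(gt_set, ann_set), threshold_mm)
    matched_ann <- 0L
    for (g in mr$groups) {
      if (length(unique(g$annotator_id)) < 2L) next
      gt_row <- g[g$annotator_id == "ground_truth", , drop = FALSE][1, ]
      an_row <- g[g$annotator_id != "ground_truth", , drop = FALSE][1, ]
      offsets <- c(offsets, an_row$x - gt_row$x, an_row$y - gt_row$y,
                   an_row$z - gt_row$z)
      log_ratios <- c(log_ratios,
                      log(an_row$diameter_mm / gt_row$diameter_mm))
      det <- c(det, gt_row$diameter_mm)
      matched_ann <- matched_ann + 1L
    }
    les_d <- c(les_d, lesions$diameter_mm)
    fp_counts <- c(fp_counts, nrow(ann) - matched_ann)
  }
  bins <- cut(les_d, diameter_breaks, right = FALSE)
  dbins <- cut(det, diameter_breaks, right = FALSE)
  sens <- data.frame(bin = levels(bins),
                     n_lesions = as.integer(table(bins)),
                     n_detected = as.integer(table(dbins)))
  sens$sensitivity <- ifelse(sens$n_lesions > 0,
                             sens$n_detected / sens$n_lesions, NA_real_)
  list(sensitivity = sens,
       fp_rate = mean(fp_counts),
       centroid_jitter_sd = if (length(offsets) > 1) stats::sd(offsets)
       else NA_real_,
       diameter_jitter_sd = if (length(log_ratios) > 1)
         stats::sd(log_ratios) else NA_real_,
       n_cases = length(cases), defined = TRUE)
}
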