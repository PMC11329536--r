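CPM_FP_TARGETS <- c(1 / 8, 1 / 4, 1 / 2, 1, 2, 4, 8)

#' Score one case: lesions hit and false positives at a threshold
#'
#' A lesion counts as hit when at least one candidate with
#' `score >= threshold` lies within `max(lesion radius, hit_distance_mm)` of
#' its centroid. Candidates are assigned one-to-one, greedily by descending
#' score then ascending distance; supra-threshold candidates hitting no
#' (remaining) lesion are false positives.
#'
#' @param candidates candidate data frame (`case_id, x, y, z, score`).
#' @param lesions ground-truth lesion ROI data frame.
#' @param threshold score threshold.
#' @param hit_distance_mm distance floor of the hit criterion (default 3 mm).
#' @return list `n_hit`, `n_fp`, `hit` (logical per lesion).
#' @export
score_case <- function(candidates, lesions, threshold = -Inf,
                       hit_distance_mm = 3.0) {
  nl <- if (is.null(lesions)) 0L else nrow(lesions)
  hit <- logical(nl)
  n_fp <- 0L
  cand <- candidates[!is.na(candidates$score) &
                       candidates$score >= threshold, , drop = FALSE]
  if (nrow(cand)) {
    cand <- cand[order(-cand$score), , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      assigned <- FALSE
      if (nl) {
        d <- sqrt((lesions$x - cand$x[j])^2 + (lesions$y - cand$y[j])^2 +
                    (lesions$z - cand$z[j])^2)
        reach <- pmax(lesions$diameter_mm / 2, hit_distance_mm)
        open <- which(!hit & d <= reach)
        if (length(open)) {
          hit[open[which.min(d[open])]] <- TRUE
          assigned <- TRUE
        }
      }
      if (!assigned) n_fp <- n_fp + 1L
    }
  }
  list(n_hit = sum(hit), n_fp = n_fp, hit = hit)
}

#' Compute an FROC curve over a set of cases
#'
#' Operating points are the distinct candidate scores in descending order
#' (plus `+Inf`). At each threshold, sensitivity is the fraction of all
#' ground-truth lesions (over positive cases) hit, and FP/case the total
#' false-positive count divided by the number of all cases, positive and
#' negative.
#'
#' @param candidates_by_case named list of candidate data frames, keyed by
#'   case id (missing/empty entries allowed).
#' @param manifest a [dataset_manifest()] (or list of [case_record()]s).
#' @param subset optional subset restriction.
#' @param hit_distance_mm hit criterion floor (mm).
#' @return object of class `froc_curve`: data frame `points` with columns
#'   `threshold`, `sensitivity`, `fp_per_case`, plus `n_lesions`, `n_cases`.
#' @export
froc <- function(candidates_by_case, manifest, subset = NULL,
                 hit_distance_mm = 3.0) {
  cases <- if (inherits(manifest, "dataset_manifest")) {
    if (is.null(subset)) manifest$cases else manifest_subset(manifest, subset)
  } else manifest
  n_lesions <- sum(vapply(cases, function(cs) nrow(case_lesions(cs)),
                          integer(1)))
  if (n_lesions == 0L) stop("FROC undefined: no ground-truth lesions in the ",
                            "evaluated cases")
  n_cases <- length(cases)
  scores <- sort(unique(unlist(lapply(cases, function(cs) {
    cd <- candidates_by_case[[cs$case_id]]
    if (is.null(cd)) numeric(0) else cd$score
  }))), decreasing = TRUE)
  thresholds <- c(Inf, scores)
  pts <- vapply(thresholds, function(th) {
    tot_hit <- 0L; tot_fp <- 0L
    for (cs in cases) {
      cd <- candidates_by_case[[cs$case_id]]
      if (is.null(cd)) cd <- data.frame(case_id = character(), x = numeric(),
                                        y = numeric(), z = numeric(),
                                        score = numeric())
      sc <- score_case(cd, case_lesions(cs), th, hit_distance_mm)
      tot_hit <- tot_hit + sc$n_hit; tot_fp <- tot_fp + sc$n_fp
    }
    c(th, tot_hit / n_lesions, tot_fp / n_cases)
  }, numeric(3))
  points <- data.frame(threshold = pts[1, ], sensitivity = pts[2, ],
                       fp_per_case = pts[3, ])
  structure(list(points = points, n_lesions = n_lesions, n_cases = n_cases),
            class = "froc_curve")
}

#' Competition performance metric of an FROC curve
#'
#' The CPM is the mean sensitivity at FP/case targets 1/8, 1/4, 1/2, 1, 2, 4
#' and 8. At each target the operating point with the largest
#' `fp_per_case <= target` is used (right-continuous step convention; 0 when
#' no point qualifies). When the curve never reaches a target FP rate, its
#' final (most permissive) sensitivity is used.
#'
#' @param curve a [froc()] curve, or a data frame with columns `fp_per_case`
#'   and `sensitivity`.
#' @return object of class `cpm_result`: `cpm` plus `sensitivities` (the
#'   seven per-target values, named by FP/case target).
#' @export
cpm <- function(curve) {
  pts <- if (inherits(curve, "froc_curve")) curve$points else curve
  pts <- pts[order(pts$fp_per_case, pts$sensitivity), , drop = FALSE]
  max_fp <- max(pts$fp_per_case)
  sens <- vapply(CPM_FP_TARGETS, function(f) {
    if (max_fp < f) return(pts$sensitivity[nrow(pts)])
    ok <- which(pts$fp_per_case <= f)
    if (!length(ok)) return(0)
    max(pts$sensitivity[ok])
  }, numeric(1))
  names(sens) <- paste0("fp", signif(CPM_FP_TARGETS, 3))
  structure(list(cpm = mean(sens), sensitivities = sens),
            class = "cpm_result")
}

#' @export
print.cpm_result <- function(x, ...) {
  cat(sprintf("CPM = %.4f\n", x$cpm))
  print(round(x$sensitivities, 4))
  invisible(x)
}

#' Steel-Dwass all-pairs rank comparison
#'
#' For every unordered pair of groups the two samples are pooled and
#' midranked; with `W` the rank sum of the first group, `E[W] = n_i (n_i +
#' n_j + 1) / 2` and the tie-corrected variance
#' `Var[W] = n_i n_j / (N (N - 1)) * sum_k (r_k - (N + 1) / 2)^2`, the
#' standardized statistic is `t = (W - E[W]) / sqrt(Var[W])` and the p-value
#' `P(Q[k, Inf] >= sqrt(2) |t|)` from the studentized-range distribution with
#' `k` groups. Degenerate pairs (zero variance) get `p = 1`. With
#' `mode = "permutation"` the asymptotic reference is replaced by the
#' Monte-Carlo permutation distribution of `|t|` under random relabelling of
#' the pooled pair (add-one tail estimate).
#'
#' @param groups named list of numeric vectors (k >= 2 groups, each n >= 2).
#' @param alpha significance level for the `significant` flag.
#' @param mode `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Monte-Carlo permutation count.
#' @param seed seed for permutation mode.
#' @return object of class `steel_dwass_result`: data frame `pairs` with
#'   columns `group1, group2, n1, n2, W, t, p, significant`, plus `k`,
#'   `alpha`, `mode`.
#' @export
steel_dwass <- function(groups, alpha = 0.05,
                        mode = c("asymptotic", "permutation"),
                        n_perm = 20000L, seed = 1L) {
  mode <- match.arg(mode)
  k <- length(groups)
  if (k < 2L) stop("Steel-Dwass needs at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop("every group needs at least 2 observations (group '",
         names(groups)[which(sizes < 2L)[1]], "' is too small)")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  pair_stat <- function(xi, xj) {
    N <- length(xi) + length(xj)
    r <- rank(c(xi, xj))
    W <- sum(r[seq_along(xi)])
    EW <- length(xi) * (N + 1) / 2
    VW <- length(xi) * length(xj) / (N * (N - 1)) *
      sum((r - (N + 1) / 2)^2)
    list(W = W, t = if (VW > 0) (W - EW) / sqrt(VW) else NA_real_, VW = VW)
  }
  cm <- utils::combn(k, 2L)
  stats_obs <- lapply(seq_len(ncol(cm)), function(col)
    pair_stat(groups[[cm[1, col]]], groups[[cm[2, col]]]))
  q_obs <- vapply(stats_obs, function(s)
    if (is.na(s$t)) NA_real_ else sqrt(2) * abs(s$t), numeric(1))
  if (mode == "permutation") {
    # max-T resampling: permute all groups jointly and record the largest
    # pairwise statistic; its distribution is the finite-sample analog of
    # the studentized-range reference
    pooled <- unlist(groups, use.names = FALSE)
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    q_max <- with_seed(child_seed(seed, "perm"), {
      vapply(seq_len(n_perm), function(b) {
        px <- pooled[sample.int(length(pooled))]
        gs <- lapply(seq_len(k), function(g) px[starts[g]:ends[g]])
        max(vapply(seq_len(ncol(cm)), function(col) {
          s <- pair_stat(gs[[cm[1, col]]], gs[[cm[2, col]]])
          if (is.na(s$t)) 0 else sqrt(2) * abs(s$t)
        }, numeric(1)))
      }, numeric(1))
    })
  }
  rows <- lapply(seq_len(ncol(cm)), function(col) {
    i <- cm[1, col]; j <- cm[2, col]
    st <- stats_obs[[col]]
    p <- if (st$VW == 0) {
      1
    } else if (mode == "asymptotic") {
      stats::ptukey(q_obs[col], nmeans = k, df = Inf, lower.tail = FALSE)
    } else {
      (sum(q_max >= q_obs[col] - 1e-12) + 1) / (n_perm + 1)
    }
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               n1 = sizes[i], n2 = sizes[j], W = st$W,
               t = st$t, p = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  structure(list(pairs = do.call(rbind, rows), k = k, alpha = alpha,
                 mode = mode), class = "steel_dwass_result")
}

#' @export
print.steel_dwass_result <- function(x, ...) {
  cat(sprintf("Steel-Dwass (%s, k=%d, alpha=%g)\n", x$mode, x$k, x$alpha))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
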