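test_that("match_annotations applies the 3 mm threshold", {
  A <- aset("R1", roi("c", 0, 0, 0, 6))
  B <- aset("R2", roi("c", 0, 0, 2.9, 8))
  mr <- match_annotations(list(A, B))
  expect_length(mr$groups, 1L)
  expect_equal(nrow(mr$groups[[1]]), 2L)
  expect_equal(nrow(mr$unmatched), 0L)

  B2 <- aset("R2", roi("c", 0, 0, 3.1, 8))
  mr2 <- match_annotations(list(A, B2))
  expect_length(mr2$groups, 0L)
  expect_equal(nrow(mr2$unmatched), 2L)
})

test_that("transitive chains merge into one flagged group", {
  A <- aset("R1", roi("c", 0, 0, 0, 6))
  B <- aset("R2", roi("c", 0, 0, 2.5, 6))
  C <- aset("R3", roi("c", 0, 0, 5, 6))
  mr <- match_annotations(list(A, B, C))
  expect_length(mr$groups, 1L)
  expect_equal(nrow(mr$groups[[1]]), 3L)
  expect_true(attr(mr$groups[[1]], "chain"))
  # a tight 2-member group is not flagged
  mr2 <- match_annotations(list(A, B))
  expect_false(attr(mr2$groups[[1]], "chain"))
})

test_that("matching is one-to-one per annotator pair and order-invariant", {
  # one R1 ROI within 3 mm of two R2 ROIs: closer one wins
  A <- aset("R1", roi("c", 0, 0, 0, 6))
  B <- aset("R2", roi("c", 0, 0, 1, 6), roi("c", 0, 0, 2.5, 6))
  mr <- match_annotations(list(A, B))
  expect_length(mr$groups, 1L)
  expect_equal(sort(mr$groups[[1]]$z), c(0, 1))
  expect_equal(mr$unmatched$z, 2.5)

  mr_swap <- match_annotations(list(B, A))
  expect_equal(mr_swap$groups[[1]]$z, mr$groups[[1]]$z)

  expect_error(match_annotations(list(
    annotation_set("R1", rbind(roi("c", 0, 0, 0, 6, "R1"),
                               roi("c", 0, 0, 0, 6, "R1"))))),
    "duplicate ROI")
})

test_that("merge_group averages centroid and diameter", {
  g <- rbind(roi("c", 0, 0, 0, 6), roi("c", 0, 0, 2.9, 8, "R2"))
  m <- merge_group(g)
  expect_equal(c(m$x, m$y, m$z), c(0, 0, 1.45))
  expect_equal(m$diameter_mm, 7)
  expect_identical(m$annotator_id, "integrated")
  # single member: identical geometry, re-tagged
  m1 <- merge_group(roi("c", 1, 2, 3, 5))
  expect_equal(c(m1$x, m1$y, m1$z, m1$diameter_mm), c(1, 2, 3, 5))
  # symmetric triple around the origin
  g3 <- rbind(roi("c", 1, 0, 0, 6), roi("c", -0.5, sqrt(3) / 2, 0, 6, "R2"),
              roi("c", -0.5, -sqrt(3) / 2, 0, 6, "R3"))
  m3 <- merge_group(g3)
  expect_equal(c(m3$x, m3$y, m3$z), c(0, 0, 0), tolerance = 1e-12)
  # volume averaging behind the flag
  expect_equal(merge_group(g, average = "volume")$diameter_mm,
               mean(c(6^3, 8^3))^(1 / 3))
})

test_that("AND keeps consensus only; OR keeps everything", {
  A <- aset("R1", roi("c", 0, 0, 0, 6), roi("c", 10, 0, 0, 8),
            roi("c", 20, 0, 0, 7))
  B <- aset("R2", roi("c", 0, 0, 1, 7), roi("c", 10, 0, 1, 9))
  land <- integrate_and(A, B)
  expect_equal(nrow(land$rois), 2L)
  expect_equal(sort(land$rois$x), c(0, 10))
  lor <- integrate_or(A, B)
  expect_equal(nrow(lor$rois), 3L)

  # disjoint sets
  C <- aset("R2", roi("c", 50, 50, 50, 6), roi("c", 40, 40, 40, 6))
  expect_equal(nrow(integrate_and(A, C)$rois), 0L)
  expect_equal(nrow(integrate_or(A, C)$rois), 5L)
})

test_that("AND/OR/VOTING are idempotent on identical inputs", {
  geom <- list(c(5, 5, 5, 6), c(20, 20, 20, 9))
  mk <- function(ann) aset(ann, roi("c", 5, 5, 5, 6, ann),
                           roi("c", 20, 20, 20, 9, ann))
  A <- mk("R1"); B <- mk("R2"); C <- mk("R3")
  for (res in list(integrate_and(A, B), integrate_or(A, B),
                   integrate_voting(A, B, C))) {
    expect_equal(nrow(res$rois), 2L)
    expect_equal(sort(res$rois$x), c(5, 20))
    expect_equal(sort(res$rois$diameter_mm), c(6, 9))
  }
})

test_that("AND and OR are symmetric in their arguments", {
  set.seed(8)
  for (rep in 1:10) {
    A <- aset("R1", roi("c", runif(1, 0, 20), runif(1, 0, 20),
                        runif(1, 0, 20), runif(1, 4, 10)),
              roi("c", runif(1, 0, 20), runif(1, 0, 20), runif(1, 0, 20),
                  runif(1, 4, 10)))
    B <- aset("R2", roi("c", runif(1, 0, 20), runif(1, 0, 20),
                        runif(1, 0, 20), runif(1, 4, 10)))
    norm <- function(s) {
      r <- s$rois[order(s$rois$x, s$rois$y, s$rois$z), ]
      rownames(r) <- NULL
      r
    }
    expect_equal(norm(integrate_and(A, B)), norm(integrate_and(B, A)))
    expect_equal(norm(integrate_or(A, B)), norm(integrate_or(B, A)))
  }
})

test_that("VOTING follows OR-then-AND with the third reader", {
  L1 <- c(5, 5, 5, 6); L2 <- c(20, 20, 20, 8)
  A <- aset("R1", roi("c", 5, 5, 5, 6, "R1"))
  B <- aset("R2", roi("c", 20, 20, 20, 8, "R2"))
  Conly <- aset("R3", roi("c", 40, 40, 40, 7, "R3"))
  # lesion annotated only by the third reader is absent
  expect_equal(nrow(integrate_voting(A, B, Conly)$rois), 0L)
  # lesion annotated by A and C (not B) survives
  C2 <- aset("R3", roi("c", 5, 5, 6, 7, "R3"))
  v <- integrate_voting(A, B, C2)
  expect_equal(nrow(v$rois), 1L)
  expect_equal(v$rois$x, 5, tolerance = 1e-9)
})

test_that("merged centroids stay in the convex hull of members", {
  set.seed(15)
  for (rep in 1:25) {
    n <- sample(2:4, 1)
    g <- do.call(rbind, lapply(seq_len(n), function(i)
      roi("c", runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2),
          runif(1, 4, 8), paste0("R", i))))
    m <- merge_group(g)
    expect_gte(m$x, min(g$x)); expect_lte(m$x, max(g$x))
    expect_gte(m$y, min(g$y)); expect_lte(m$y, max(g$y))
    expect_gte(m$z, min(g$z)); expect_lte(m$z, max(g$z))
    expect_gte(m$diameter_mm, min(g$diameter_mm))
    expect_lte(m$diameter_mm, max(g$diameter_mm))
  }
})

test_that("integrate_cohort enumerates pairs, canonical triples, and caps", {
  mk <- function(ann) aset(ann, roi("c", runif(1, 0, 30), runif(1, 0, 30),
                                    runif(1, 0, 30), 6, ann))
  set.seed(2)
  sets4 <- lapply(paste0("R", 1:4), mk)
  names(sets4) <- paste0("R", 1:4)
  expect_length(integrate_cohort(sets4, "AND"), 6L)    # C(4,2)
  expect_length(integrate_cohort(sets4, "OR"), 6L)
  # cohort of 3, VOTING: {unordered pair} x {third} = 3
  sets3 <- sets4[1:3]
  expect_length(integrate_cohort(sets3, "VOTING"), 3L)
  # cap
  expect_length(integrate_cohort(sets4, "VOTING", cap = 5L, seed = 1), 5L)
  # arity errors
  expect_error(integrate_cohort(sets4[1], "AND"), "too small")
  expect_error(integrate_cohort(sets4[1:2], "VOTING"), "too small")
})

test_that("greedy matching agrees with minimum-distance optimal matching", {
  # exhaustive optimal one-to-one assignment for two annotators
  optimal_pairs <- function(da) {
    n1 <- nrow(da); n2 <- ncol(da)
    best <- NULL; best_cost <- Inf; best_n <- -1L
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (pm in perms(seq_len(max(n1, n2)))) {
      pairs <- 0L; cost <- 0
      for (i in seq_len(n1)) {
        j <- pm[i]
        if (j <= n2 && da[i, j] <= 3) {
          pairs <- pairs + 1L; cost <- cost + da[i, j]
        }
      }
      if (pairs > best_n || (pairs == best_n && cost < best_cost)) {
        best_n <- pairs; best_cost <- cost
      }
    }
    c(best_n, best_cost)
  }
  set.seed(31)
  agree <- 0L; total <- 0L
  for (rep in 1:120) {
    n1 <- sample(1:4, 1); n2 <- sample(1:4, 1)
    p1 <- matrix(runif(3 * n1, 0, 8), ncol = 3)
    p2 <- matrix(runif(3 * n2, 0, 8), ncol = 3)
    A <- annotation_set("R1", do.call(rbind, lapply(seq_len(n1), function(i)
      roi("c", p1[i, 1], p1[i, 2], p1[i, 3], 6, "R1"))))
    B <- annotation_set("R2", do.call(rbind, lapply(seq_len(n2), function(i)
      roi("c", p2[i, 1], p2[i, 2], p2[i, 3], 6, "R2"))))
    da <- as.matrix(dist(rbind(p1, p2)))[seq_len(n1), n1 + seq_len(n2),
                                         drop = FALSE]
    opt <- optimal_pairs(da)
    mr <- match_annotations(list(A, B))
    n_greedy <- sum(vapply(mr$groups, nrow, integer(1)) - 1L)
    total <- total + 1L
    if (n_greedy == opt[1]) agree <- agree + 1L
  }
  expect_gte(agree / total, 0.95)
})
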