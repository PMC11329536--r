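test_that("phantom params enforce the task diameter floors", {
  expect_error(phantom_params("chest", lesion_diameter_range = c(4, 18)),
               ">= 6 mm")
  expect_error(phantom_params("brain", lesion_diameter_range = c(1, 8)),
               ">= 2 mm")
  expect_error(phantom_params("chest",
                              distractor_diameter_range = c(3, 7)),
               "below 6 mm")
  expect_error(phantom_params("chest", grid_dim = 16L), "grid too small")
})

test_that("generate_phantom honours counts, contrast, and determinism", {
  pp <- tiny_chest_params()
  # background only
  ph0 <- generate_phantom(pp, 0, 0, seed = 1)
  expect_equal(nrow(ph0$rois), 0L)

  # a lesion is measurably brighter than background inside its ROI sphere
  ph <- generate_phantom(pp, 1, 0, seed = 2)
  les <- ph$rois
  expect_gte(les$diameter_mm, 6)
  v <- ph$volume$voxels
  cc <- expand.grid(x = (seq_len(48) - 1), y = (seq_len(48) - 1),
                    z = (seq_len(48) - 1))
  d2 <- (cc$x - les$x)^2 + (cc$y - les$y)^2 + (cc$z - les$z)^2
  inside <- v[d2 <= (les$diameter_mm / 2)^2]
  bg <- stats::median(v)
  expect_gt(mean(inside), bg + 5 * pp$noise_sd)

  # determinism: bit-identical volume and ROI list
  ph2 <- generate_phantom(pp, 1, 0, seed = 2)
  expect_identical(ph$volume$voxels, ph2$volume$voxels)
  expect_identical(ph$rois, ph2$rois)
  # layout is stable across rendering modes
  ph3 <- generate_phantom(pp, 1, 0, seed = 2, render = FALSE)
  expect_identical(ph3$rois, ph$rois)
  expect_null(ph3$volume)
})

test_that("brain phantoms put lesions on the vessel tree", {
  pb <- tiny_brain_params()
  ph <- generate_phantom(pb, 2, 2, seed = 5)
  les <- ph$rois[ph$rois$tag == "lesion", ]
  expect_equal(nrow(les), 2L)
  expect_true(all(les$diameter_mm >= 2))
  dis <- ph$rois[ph$rois$tag == "distractor", ]
  expect_equal(nrow(dis), 2L)
  # aneurysm voxels are vessel-bright
  v <- ph$volume$voxels
  for (i in seq_len(nrow(les))) {
    iv <- round(les[i, c("x", "y", "z")] / pb$spacing_mm) + 1
    nb <- v[max(1, iv$x - 2):min(48, iv$x + 2),
            max(1, iv$y - 2):min(48, iv$y + 2),
            max(1, iv$z - 2):min(48, iv$z + 2)]
    expect_gt(max(nb), 100)
  }
})

test_that("generate_dataset reproduces the default subset design", {
  pp <- tiny_chest_params()
  m <- generate_dataset(pp, seed = 3, volumes = "none")
  expect_equal(unname(m$counts["positive", ]), c(50, 40, 40, 50))
  expect_equal(unname(m$counts["negative", ]), c(0, 35, 35, 50))
  expect_equal(sum(m$counts[, "retraining1"]), 75)
  expect_equal(sum(m$counts[, "test"]), 100)
  # exactly 10 distractor-bearing negatives in each retraining/test subset
  for (ss in c("retraining1", "retraining2", "test")) {
    cases <- manifest_subset(m, ss)
    nbearing <- sum(vapply(cases, function(cs)
      !cs$is_positive && any(cs$ground_truth$tag == "distractor"),
      logical(1)))
    expect_equal(nbearing, 10L)
  }
  # every positive case meets the diameter floor
  for (cs in m$cases) {
    if (cs$is_positive) {
      les <- case_lesions(cs)
      expect_gte(nrow(les), 1L)
      expect_true(all(les$diameter_mm >= 6))
    } else {
      expect_equal(nrow(case_lesions(cs)), 0L)
      dis <- cs$ground_truth[cs$ground_truth$tag == "distractor", ]
      expect_true(all(dis$diameter_mm < 6))
    }
  }
})

test_that("tiny count overrides and disk mode work", {
  pp <- tiny_chest_params(32L)
  counts <- list(initial = c(2L, 0L), retraining1 = c(2L, 1L),
                 retraining2 = c(2L, 1L), test = c(2L, 2L))
  dir <- withr::local_tempdir()
  m <- generate_dataset(pp, counts, seed = 4, volumes = "disk", dir = dir,
                        n_distractor_negatives = 1L)
  expect_length(m$cases, 12L)
  cs <- m$cases[[1]]
  expect_true(file.exists(cs$volume_path))
  vol <- case_volume(cs, "chest")
  expect_equal(dim(vol$voxels), rep(32L, 3))
  # ground truth identical to the in-memory mode
  m2 <- generate_dataset(pp, counts, seed = 4, volumes = "none",
                         n_distractor_negatives = 1L)
  expect_equal(m$cases[[3]]$ground_truth, m2$cases[[3]]$ground_truth)
})

test_that("noise-free annotation is the identity on lesion ground truth", {
  cs <- gt_case("c1", lesions = list(c(10, 10, 10, 8), c(30, 30, 30, 6.5)),
                distractors = list(c(20, 20, 20, 4)))
  out <- simulate_annotation(noise_free_profile(), cs, seed = 1)
  les <- case_lesions(cs)
  expect_equal(nrow(out), 2L)
  expect_equal(sort(out$x), sort(les$x))
  expect_equal(sort(out$diameter_mm), sort(les$diameter_mm))
  expect_true(all(out$annotator_id == "oracle"))

  # blind annotator: empty output
  blind <- annotator_profile("blind", sens_d50 = 1e6, fp_rate = 0,
                             distractor_confusion_prob = 0)
  expect_equal(nrow(simulate_annotation(blind, cs, seed = 1)), 0L)
})

test_that("false-annotation counts follow the Poisson rate", {
  prof <- annotator_profile("fp", sens_d50 = 1e6, fp_rate = 2.0)
  counts <- vapply(1:200, function(i) {
    cs <- gt_case(paste0("n", i))
    nrow(simulate_annotation(prof, cs, seed = i))
  }, numeric(1))
  expect_gte(mean(counts), 1.7)
  expect_lte(mean(counts), 2.3)
})

test_that("the CAD-assisted second pass rescues missed lesions", {
  cs <- gt_case("c1", lesions = list(c(10, 10, 10, 8)))
  miss_all <- annotator_profile("m", sens_d50 = 1e6, fp_rate = 0,
                                centroid_jitter_sd = 0,
                                diameter_jitter_sd = 0,
                                cad_rescue_prob = 1, cad_fp_accept_prob = 0)
  cad <- cand_df("c1", c(10.5, 10, 10, 0.9), c(40, 40, 40, 0.8))
  out <- simulate_annotation(miss_all, cs, cad_candidates = cad, seed = 1)
  expect_equal(nrow(out), 1L)
  expect_equal(out$x, 10)     # jitter-free copy of the rescued lesion

  # far candidate accepted as FP when cad_fp_accept_prob = 1
  fp_taker <- annotator_profile("f", sens_d50 = 1e6, fp_rate = 0,
                                cad_rescue_prob = 0, cad_fp_accept_prob = 1)
  out2 <- simulate_annotation(fp_taker, cs, cad_candidates = cad, seed = 1)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$x, 40)
  # candidates of a different case are rejected
  bad <- cand_df("other", c(1, 1, 1, 0.5))
  expect_error(simulate_annotation(fp_taker, cs, cad_candidates = bad),
               "belong")
})

test_that("annotation is deterministic and stable across cohort growth", {
  cs <- gt_case("c1", lesions = list(c(10, 10, 10, 8)))
  prof <- annotator_profile("R1", sens_d50 = 6, fp_rate = 1,
                            centroid_jitter_sd = 0.7)
  a1 <- simulate_annotation(prof, cs, seed = 9)
  a2 <- simulate_annotation(prof, cs, seed = 9)
  expect_identical(a1, a2)
  # a different annotator id gets an independent stream
  prof2 <- annotator_profile("R2", sens_d50 = 6, fp_rate = 1,
                             centroid_jitter_sd = 0.7)
  b <- simulate_annotation(prof2, cs, seed = 9)
  expect_false(identical(a1$x, b$x) && identical(a1$diameter_mm,
                                                 b$diameter_mm))
})

test_that("estimate_profile recovers simulated parameters", {
  # noise-free annotator: sensitivity 1 in occupied bins, zero FP rate
  cases <- lapply(1:20, function(i)
    gt_case(paste0("c", i), lesions = list(c(runif(3, 10, 50), 8))))
  m <- dataset_manifest("chest", cases)
  rois <- do.call(rbind, lapply(cases, function(cs)
    simulate_annotation(noise_free_profile("A"), cs, seed = 1)))
  est <- estimate_profile(annotation_set("A", rois), m)
  expect_true(est$defined)
  expect_equal(est$fp_rate, 0)
  occ <- est$sensitivity[est$sensitivity$n_lesions > 0, ]
  expect_true(all(occ$sensitivity == 1))
  expect_equal(est$centroid_jitter_sd, 0, tolerance = 1e-12)

  # empty annotation set flagged undefined
  est0 <- estimate_profile(annotation_set("B"), m)
  expect_false(est0$defined)
  expect_true(is.na(est0$fp_rate))

  # unknown cases rejected
  stray <- annotation_set("A", roi("zzz", 1, 1, 1, 6, "A"))
  expect_error(estimate_profile(stray, m), "absent from the manifest")
})

test_that("moment estimates converge at moderate case counts", {
  set.seed(40)
  cases <- lapply(1:120, function(i)
    gt_case(paste0("c", i), lesions = list(c(runif(3, 10, 50),
                                             runif(1, 6.5, 12)))))
  m <- dataset_manifest("chest", cases)
  prof <- annotator_profile("A", sens_d50 = -Inf, fp_rate = 1.5,
                            centroid_jitter_sd = 1.0,
                            diameter_jitter_sd = 0.1)
  rois <- do.call(rbind, lapply(cases, function(cs)
    simulate_annotation(prof, cs, seed = 77)))
  est <- estimate_profile(annotation_set("A", rois), m)
  expect_lt(abs(est$fp_rate - 1.5), 0.35)
  expect_lt(abs(est$centroid_jitter_sd - 1.0), 0.25)
  expect_lt(abs(est$diameter_jitter_sd - 0.1), 0.05)
})

test_that("default cohorts carry the documented tier composition", {
  ch <- default_cohort("chest")
  expect_length(ch, 12L)
  tiers <- vapply(ch, `[[`, character(1), "tier")
  expect_equal(sum(tiers == "board_certified"), 5L)
  expect_equal(sum(tiers == "resident"), 7L)
  br <- default_cohort("brain")
  tiers_b <- vapply(br, `[[`, character(1), "tier")
  expect_equal(sum(tiers_b == "board_certified"), 4L)
  expect_equal(sum(tiers_b == "resident"), 8L)
  # higher heterogeneity spreads the profiles further
  h0 <- default_cohort("chest", seed = 2, heterogeneity = 0)
  d50 <- vapply(h0, `[[`, numeric(1), "sens_d50")
  expect_lt(stats::sd(d50[tiers == "resident"]), 1e-12)
})
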