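test_that("isotropic resampling follows shape arithmetic", {
  v <- volume(array(rnorm(16^3), c(16, 16, 16)), spacing = c(2, 2, 2))
  dc <- detector_config("chest", target_spacing_mm = 1)
  out <- preprocess(v, dc)
  # 2 mm -> 1 mm: each axis dimension doubles (boundary convention +/- 1)
  expect_true(all(abs(dim(out$voxels) - 32L) <= 1L))
  expect_equal(out$spacing, c(1, 1, 1))
  # already-isotropic input at target spacing is untouched
  v1 <- volume(array(rnorm(10^3), c(10, 10, 10)), spacing = c(1, 1, 1))
  expect_identical(preprocess(v1, dc)$voxels, v1$voxels)
})

test_that("brain standardization is a monotone intensity map", {
  set.seed(6)
  ramp <- array(seq(0, 200, length.out = 12^3), c(12, 12, 12))
  v <- volume(ramp, spacing = rep(0.469, 3), task = "brain")
  dc <- detector_config("brain")
  out <- preprocess(v, dc)
  i <- sample(12^3, 1000, replace = TRUE)
  j <- sample(12^3, 1000, replace = TRUE)
  ord_in <- sign(ramp[i] - ramp[j])
  ord_out <- sign(out$voxels[i] - out$voxels[j])
  expect_true(all(ord_in * ord_out >= 0))
  # constant volume: standardization skipped with a warning
  vc <- volume(array(7, c(8, 8, 8)), spacing = rep(0.469, 3), task = "brain")
  expect_warning(preprocess(vc, dc), "standardization skipped")
})

test_that("brain vessel mask covers a constructed bright tube", {
  d <- 32L
  v <- array(rnorm(d^3, 20, 3), c(d, d, d))
  # axis-aligned tube at the grid centre (~4% of voxels, like an MRA tree)
  for (x in 1:d) for (y in (d / 2 - 3):(d / 2 + 3))
    for (z in (d / 2 - 3):(d / 2 + 3))
      if ((y - d / 2)^2 + (z - d / 2)^2 <= 12) v[x, y, z] <- 200
  vol <- volume(v, spacing = c(0.469, 0.469, 0.469), task = "brain")
  dc <- detector_config("brain")
  mask <- extract_organ_mask(vol, dc)
  tube <- v >= 190
  expect_gte(sum(mask & tube) / sum(tube), 0.9)

  # all-background volume: empty-mask warning path
  flat <- volume(array(rnorm(16^3, 20, 3), c(16, 16, 16)),
                 spacing = rep(0.469, 3), task = "brain")
  expect_warning(m2 <- extract_organ_mask(flat, dc), "empty")
  expect_false(any(m2))
})

test_that("mask extraction is robust to noise (Dice over seeds)", {
  base <- generate_phantom(tiny_chest_params(), 1, 0, seed = 12)
  dc <- fast_chest_config()
  ref <- extract_organ_mask(preprocess(base$volume, dc), dc)
  gap <- diff(range(base$volume$voxels)) * 0.02
  for (s in 1:5) {
    noisy <- base$volume
    noisy$voxels <- noisy$voxels + with_seed(s, array(
      rnorm(length(noisy$voxels), 0, gap), dim(noisy$voxels)))
    m <- extract_organ_mask(preprocess(noisy, dc), dc)
    dice <- 2 * sum(m & ref) / (sum(m) + sum(ref))
    expect_gte(dice, 0.95)
  }
})

test_that("candidate extraction finds bright lesions and fades with contrast", {
  pp <- tiny_chest_params()
  dc <- fast_chest_config()
  ph <- generate_phantom(pp, 1, 0, seed = 20)
  les <- ph$rois
  pre <- preprocess(ph$volume, dc)
  mask <- extract_organ_mask(pre, dc)
  cands <- extract_candidates(pre, mask, dc, "c")
  d <- sqrt((cands$x - les$x)^2 + (cands$y - les$y)^2 + (cands$z - les$z)^2)
  expect_true(any(d <= les$diameter_mm / 2))

  # contrast ramp: lesion contrast shrinks while noise stays fixed, so the
  # candidate hitting the lesion eventually disappears (monotone sweep)
  scores <- vapply(c(1, 0.5, 0.25, 0.1, 0.015), function(f) {
    ppf <- tiny_chest_params()
    ppf$lesion_contrast <- ppf$lesion_contrast * f
    phf <- generate_phantom(ppf, 1, 0, seed = 20)
    pref <- preprocess(phf$volume, dc)
    c2 <- extract_candidates(pref, mask, dc, "c")
    if (!nrow(c2)) return(0)
    lf <- phf$rois
    dd <- sqrt((c2$x - lf$x)^2 + (c2$y - lf$y)^2 + (c2$z - lf$z)^2)
    hit <- dd <= max(lf$diameter_mm / 2, 3)
    if (any(hit)) max(c2$score[hit]) else 0
  }, numeric(1))
  expect_true(all(diff(scores) <= 1e-9))
  expect_equal(scores[5], 0)

  # background-only phantom: finite candidate count is legal
  ph0 <- generate_phantom(pp, 0, 0, seed = 21)
  pre0 <- preprocess(ph0$volume, dc)
  c0 <- extract_candidates(pre0, extract_organ_mask(pre0, dc), dc, "c")
  expect_true(is.finite(nrow(c0)))
})

test_that("label_candidates applies the radius/3mm floor rule", {
  ann <- rbind(roi("c", 10, 10, 10, 4), roi("c", 30, 30, 30, 6))
  cands <- cand_df("c", c(10, 10, 10, 1),      # exactly at a centroid
                   c(10, 10, 12.9, 1),          # 2.9 mm from 4 mm-diam ann
                   c(30, 30, 35, 1))            # 5 mm from 6 mm-diam ann
  lab <- label_candidates(cands, ann)
  expect_identical(lab, c(TRUE, TRUE, FALSE))
  expect_identical(label_candidates(cands, empty_rois()),
                   c(FALSE, FALSE, FALSE))
})

test_that("augmentation yields exactly 29 copies and honours the seed", {
  dc <- fast_chest_config()
  set.seed(1)
  voi <- array(rnorm(24^3), c(24, 24, 24))     # padded super-VOI
  a1 <- with_seed(5, augment_positive(voi, dc))
  expect_length(a1, 29L)
  expect_true(all(vapply(a1, function(a) all(dim(a) == 16L), logical(1))))
  a2 <- with_seed(5, augment_positive(voi, dc))
  expect_identical(a1, a2)
  a3 <- with_seed(6, augment_positive(voi, dc))
  expect_false(identical(a1, a3))
})

test_that("a zero-shift unit-scale zero-rotation draw is the identity", {
  voi <- array(rnorm(16^3), c(16, 16, 16))
  expect_identical(apply_augment(voi), voi)
  # four quarter-turns come back to the start
  r4 <- apply_augment(voi, rot = c(4L, 0L, 0L))
  expect_identical(r4, voi)
  r1 <- apply_augment(voi, rot = c(1L, 0L, 0L))
  expect_false(identical(r1, voi))
  expect_identical(apply_augment(r1, rot = c(3L, 0L, 0L)), voi)
})

test_that("network gradients match numerical differentiation", {
  layers <- list(nn_conv(2L, 3L), nn_relu(), nn_pool(2L), nn_flatten(),
                 nn_dense(3L), nn_relu(), nn_dense(1L))
  net <- nn_init(layers, c(6L, 6L, 6L, 1L), seed = 3)
  set.seed(4)
  x <- array(rnorm(6^3), c(6, 6, 6, 1))
  y <- 1
  loss <- function(nt) {
    p <- stats::plogis(nn_forward(nt, x)[1])
    -y * log(p) - (1 - y) * log(1 - p)
  }
  fw <- nn_forward(net, x, keep = TRUE)
  p <- stats::plogis(fw$out[1])
  grads <- nn_backward(net, fw, p - y)
  eps <- 1e-5
  for (li in c(1L, 5L, 7L)) {
    W <- net$layers[[li]]$W
    for (k in sample(length(W), min(4, length(W)))) {
      n2 <- net
      n2$layers[[li]]$W[k] <- W[k] + eps
      up <- loss(n2)
      n2$layers[[li]]$W[k] <- W[k] - eps
      dn <- loss(n2)
      expect_equal(grads[[li]]$W[k], (up - dn) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("training separates a separable toy problem and balances classes", {
  # bright-centre vs flat VOIs through the real training loop
  set.seed(9)
  pp <- tiny_chest_params(32L)
  balance_log <- list()
  dc <- detector_config("chest", epochs = 3L,
                        epoch_hook = function(e, np, nn)
                          balance_log[[length(balance_log) + 1L]] <<-
                            c(np, nn))
  cases <- list(); prepared <- list()
  for (i in 1:4) {
    id <- sprintf("t%d", i)
    ph <- generate_phantom(pp, if (i <= 2) 1 else 0, 0, seed = i,
                           case_id = id)
    cs <- case_record(id, "initial", i <= 2, ph$rois, vol = ph$volume)
    cases[[id]] <- cs
    prepared[[id]] <- prepare_case(cs, dc)
  }
  labels <- lapply(cases, case_lesions)
  det <- train_detector(dc, cases, labels, seed = 1, prepared = prepared)
  # every epoch balanced
  expect_length(balance_log, 3L)
  for (b in balance_log) expect_equal(b[1], b[2])
  # training accuracy on its own candidates
  probs <- lapply(cases, function(cs)
    annoret:::score_prepared(det, prepared[[cs$case_id]]))
  accs <- unlist(lapply(names(cases), function(id) {
    lab <- label_candidates(prepared[[id]]$candidates, labels[[id]])
    sc <- probs[[id]]
    ord <- match(paste(prepared[[id]]$candidates$x,
                       prepared[[id]]$candidates$y),
                 paste(sc$x, sc$y))
    (sc$score[ord] > 0.5) == lab
  }))
  expect_gte(mean(accs), 0.9)
  # single-class errors
  expect_error(train_detector(dc, cases["t3"], labels["t3"],
                              prepared = prepared),
               "positive")
})

test_that("training and inference are deterministic given the seed", {
  pp <- tiny_chest_params(32L)
  dc <- detector_config("chest", epochs = 2L)
  cases <- list(); prepared <- list()
  for (i in 1:3) {
    id <- sprintf("t%d", i)
    ph <- generate_phantom(pp, if (i <= 2) 1 else 0, 0, seed = i,
                           case_id = id)
    cs <- case_record(id, "initial", i <= 2, ph$rois, vol = ph$volume)
    cases[[id]] <- cs
    prepared[[id]] <- prepare_case(cs, dc)
  }
  labels <- lapply(cases, case_lesions)
  d1 <- train_detector(dc, cases, labels, seed = 42, prepared = prepared)
  d2 <- train_detector(dc, cases, labels, seed = 42, prepared = prepared)
  probe <- generate_phantom(pp, 1, 0, seed = 99, case_id = "probe")
  c1 <- run_cad(d1, probe$volume, "probe")
  c2 <- run_cad(d2, probe$volume, "probe")
  expect_identical(c1, c2)
  expect_true(all(c1$score >= 0 & c1$score <= 1))
  d3 <- train_detector(dc, cases, labels, seed = 43, prepared = prepared)
  c3 <- run_cad(d3, probe$volume, "probe")
  expect_false(identical(c1$score, c3$score))
})

test_that("cnn classifiers train end to end on a tiny problem", {
  pp <- tiny_chest_params(32L)
  cases <- list()
  for (i in 1:3) {
    id <- sprintf("t%d", i)
    ph <- generate_phantom(pp, if (i <= 2) 1 else 0, 0, seed = i,
                           case_id = id)
    cases[[id]] <- case_record(id, "initial", i <= 2, ph$rois,
                               vol = ph$volume)
  }
  for (kind in c("cnn3d", "cnn_mip")) {
    dc <- detector_config("chest", classifier = kind, epochs = 1L,
                          augment_copies = 3L,
                          learning_rate = if (kind == "cnn3d") 1e-3 else 1e-3)
    det <- train_detector(dc, cases, lapply(cases, case_lesions), seed = 1)
    sc <- run_cad(det, cases$t1$volume, "t1")
    expect_true(all(sc$score >= 0 & sc$score <= 1))
  }
})
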