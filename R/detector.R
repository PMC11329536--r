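#' Detector configuration
#'
#' Bundles preprocessing, candidate-extraction, and classifier hyperparameters
#' for one task. Published-scale values (32-voxel VOIs, 500/10 epochs,
#' learning rate 1e-5 for the 3D net) remain available; desk defaults use
#' 16-voxel VOIs and 20 epochs so training runs on one CPU in seconds.
#'
#' @param task `"chest"` or `"brain"`.
#' @param target_spacing_mm isotropic resampling pitch (default 1.0 chest,
#'   0.469 brain).
#' @param voi_edge cubic VOI edge length in voxels (published scale 32;
#'   desk default 16).
#' @param classifier `"linear_baseline"`, `"cnn3d"`, or `"cnn_mip"`.
#' @param learning_rate SGD learning rate; default 1e-5 for `cnn3d` (the
#'   published value), 1e-3 for `cnn_mip`, 0.05 for the linear baseline.
#' @param momentum SGD momentum (published 0.99).
#' @param weight_decay L2 weight decay (published 0.001).
#' @param minibatch minibatch size (published 8).
#' @param epochs training epochs (desk default 20).
#' @param augment_copies augmented VOIs per positive per epoch (published 29).
#' @param shift_range augmentation shift range in voxels (published 4).
#' @param scale_range augmentation scale range (published `c(0.85, 1.15)`).
#' @param blob_z_threshold candidate blobness threshold in robust z units;
#'   chosen low (recall-oriented).
#' @param max_candidates cap on candidates per case (highest blobness kept).
#' @param vessel_quantiles weak/strong intensity quantiles of the brain-task
#'   hysteresis vessel segmentation.
#' @param blob_diameter_range blob scales to search, mm (defaults to the
#'   task's target-lesion diameter range).
#' @param display_score_threshold classifier score above which candidates are
#'   shown to annotators during assisted reading (default 0.5).
#' @param hit_distance_mm candidate-to-annotation matching floor (mm).
#' @param epoch_hook optional `function(epoch, n_pos, n_neg)` called once per
#'   epoch (used by tests to assert class balance).
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(task = c("chest", "brain"),
                            target_spacing_mm = NULL,
                            voi_edge = 16L,
                            classifier = c("linear_baseline", "cnn3d",
                                           "cnn_mip"),
                            learning_rate = NULL,
                            momentum = 0.99, weight_decay = 0.001,
                            minibatch = 8L, epochs = 20L,
                            augment_copies = 29L, shift_range = 4L,
                            scale_range = c(0.85, 1.15),
                            blob_z_threshold = 4,
                            blob_diameter_range = NULL,
                            max_candidates = 40L,
                            vessel_quantiles = c(0.955, 0.985),
                            display_score_threshold = 0.5,
                            hit_distance_mm = 3.0,
                            epoch_hook = NULL) {
  task <- match.arg(task)
  classifier <- match.arg(classifier)
  if (is.null(target_spacing_mm))
    target_spacing_mm <- if (task == "chest") 1.0 else 0.469
  if (is.null(learning_rate))
    learning_rate <- switch(classifier, cnn3d = 1e-5, cnn_mip = 1e-3,
                            linear_baseline = 0.05)
  if (is.null(blob_diameter_range))
    blob_diameter_range <- if (task == "chest") c(6, 18) else c(2, 8)
  stopifnot(voi_edge > 2L * shift_range, all(scale_range > 0), epochs >= 1L)
  structure(as.list(environment()), class = "detector_config")
}

# -- preprocessing -----------------------------------------------------------

catmull_rom_matrix <- function(n_in, u) {
  i0 <- floor(u); f <- u - i0
  W <- matrix(0, length(u), n_in)
  w <- cbind(-0.5 * f + f^2 - 0.5 * f^3,
             1 - 2.5 * f^2 + 1.5 * f^3,
             0.5 * f + 2 * f^2 - 1.5 * f^3,
             -0.5 * f^2 + 0.5 * f^3)
  for (k in -1:2) {
    idx <- pmin(pmax(i0 + k, 0), n_in - 1) + 1
    W[cbind(seq_along(u), idx)] <- W[cbind(seq_along(u), idx)] + w[, k + 2]
  }
  W
}

resample_axis <- function(a, axis, W) {
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- W %*% matrix(ap, nrow = d[1])
  out <- array(m, dim = c(nrow(W), d[2], d[3]))
  aperm(out, order(perm))
}

#' Resample a volume to an isotropic grid (tricubic interpolation)
#'
#' @param vol a [volume()].
#' @param spacing_mm target isotropic spacing.
#' @return a resampled [volume()] covering the same extent.
#' @export
resample_isotropic <- function(vol, spacing_mm) {
  d <- dim(vol$voxels)
  a <- vol$voxels
  for (ax in 1:3) {
    if (abs(vol$spacing[ax] - spacing_mm) < 1e-9) next
    n_out <- floor((d[ax] - 1) * vol$spacing[ax] / spacing_mm) + 1
    u <- (seq_len(n_out) - 1) * spacing_mm / vol$spacing[ax]
    a <- resample_axis(a, ax, catmull_rom_matrix(d[ax], u))
  }
  volume(a, spacing = rep(spacing_mm, 3), origin = vol$origin,
         task = vol$task)
}

#' Preprocess a volume for candidate detection
#'
#' Resamples to the task's isotropic spacing; for the brain task the
#' intensity distribution is additionally standardized by a global piecewise
#' linear map taking the 0/50/98/100 intensity percentiles onto a fixed
#' reference scale (0, 100, 400, 500). A constant volume skips
#' standardization with a warning.
#'
#' @param vol a [volume()].
#' @param config a [detector_config()].
#' @return a preprocessed [volume()].
#' @export
preprocess <- function(vol, config) {
  out <- resample_isotropic(vol, config$target_spacing_mm)
  if (config$task == "brain") {
    v <- out$voxels
    lm <- stats::quantile(v, c(0, 0.5, 0.98, 1), names = FALSE)
    if (lm[4] - lm[1] < 1e-9) {
      warning("constant volume: intensity standardization skipped")
    } else {
      ref <- c(0, 100, 400, 500)
      keep <- c(TRUE, diff(lm) > 1e-9)
      v <- stats::approx(lm[keep], ref[keep], xout = pmin(pmax(v, lm[1]),
                                                          lm[4]),
                         rule = 2)$y
      out <- volume(array(v, dim(out$voxels)), out$spacing, out$origin,
                    out$task)
    }
  }
  out
}

# -- morphology / connected components --------------------------------------

shift_arr <- function(a, ax, by, fill) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- idx; dst <- idx
  if (by > 0) { src[[ax]] <- 1:(d[ax] - by); dst[[ax]] <- (1 + by):d[ax] }
  else if (by < 0) { src[[ax]] <- (1 - by):d[ax]; dst[[ax]] <- 1:(d[ax] + by) }
  out <- array(fill, d)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

neighbor_max <- function(a, fill = -Inf) {
  out <- a
  for (ax in 1:3) for (by in c(-1L, 1L))
    out <- pmax(out, shift_arr(a, ax, by, fill))
  out
}

# label connected components (6-connectivity); igraph does the union-find
label_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  vid <- array(0L, d)
  vid[idx] <- seq_along(idx)
  strides <- c(1L, d[1], d[1] * d[2])
  edges <- integer(0)
  ai <- arrayInd(idx, d)
  for (ax in 1:3) {
    ok <- ai[, ax] < d[ax]
    nb <- idx[ok] + strides[ax]
    both <- mask[nb]
    if (any(both))
      edges <- c(edges, rbind(vid[idx[ok][both]], vid[nb[both]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  lab[idx] <- igraph::components(g)$membership
  lab
}

dilate <- function(mask, iter = 1L) {
  for (i in seq_len(iter)) mask <- neighbor_max(mask, fill = FALSE) > 0
  mask
}
erode <- function(mask, iter = 1L) !dilate(!mask, iter)

fill_holes <- function(mask) {
  # background components not touching the volume border are holes
  bg <- !mask
  if (!any(bg)) return(mask)
  lab <- label_components(bg)
  border <- array(FALSE, dim(mask))
  border[c(1, dim(mask)[1]), , ] <- TRUE
  border[, c(1, dim(mask)[2]), ] <- TRUE
  border[, , c(1, dim(mask)[3])] <- TRUE
  outside <- unique(lab[border & bg])
  mask | !(lab %in% outside & bg)
}

#' Extract the organ mask (lung region or arterial tree)
#'
#' Chest: voxels below a robust brightness threshold (parenchyma) form the
#' body of the mask; the largest connected component is kept, holes left by
#' bright nodules and vessels are filled, and a one-step morphological
#' closing smooths the boundary. Brain: hysteresis thresholding of the bright
#' vessel tree — strong voxels seed region growing into the weak-threshold
#' region, then a one-step dilation captures the vessel wall.
#'
#' @param vol a preprocessed [volume()].
#' @param config a [detector_config()].
#' @return logical 3D array; empty masks trigger a warning.
#' @export
extract_organ_mask <- function(vol, config) {
  v <- vol$voxels
  if (config$task == "chest") {
    med <- stats::median(v)
    hi <- stats::quantile(v, 0.999, names = FALSE)
    thr <- med + 0.4 * (hi - med)
    m <- v < thr
    lab <- label_components(m)
    if (any(lab > 0)) {
      counts <- table(lab[lab > 0])
      big <- as.numeric(names(counts)[which.max(counts)])
      m <- lab == big
    }
    # closing absorbs thin bright vessels into the mask; any remaining
    # bright blob (a nodule) becomes an enclosed hole and is filled
    m <- fill_holes(erode(dilate(m, 3L), 3L))
  } else {
    # the arterial tree occupies a small bright fraction of the volume;
    # hysteresis thresholds are set by intensity quantiles so the rule
    # survives any monotone intensity standardization
    t_hi <- stats::quantile(v, config$vessel_quantiles[2], names = FALSE)
    t_lo <- stats::quantile(v, config$vessel_quantiles[1], names = FALSE)
    # structureless volume guard: arteries must stand clear of the noise
    if (t_hi - t_lo < 2 * stats::mad(v)) {
      warning("organ mask is empty (no bright vascular structure)")
      return(array(FALSE, dim(v)))
    }
    strong <- v >= t_hi
    weak <- v >= t_lo
    lab <- label_components(weak)
    seeded <- setdiff(unique(lab[strong]), 0L)
    m <- array(lab %in% seeded & weak, dim(v))
    m <- dilate(m, 1L)
  }
  if (!any(m)) warning("organ mask is empty")
  m
}

# -- candidate extraction ----------------------------------------------------

fft_gaussian_blur <- function(a, sigma_vox) {
  d <- dim(a)
  kern1 <- lapply(d, function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sigma_vox^2)); k / sum(k)
  })
  K <- outer(outer(kern1[[1]], kern1[[2]]), kern1[[3]])
  dim(K) <- d
  Re(stats::fft(stats::fft(a) * stats::fft(K), inverse = TRUE)) / prod(d)
}

mirror_pad <- function(a, p) {
  idx <- lapply(dim(a), function(n)
    c(rev(seq_len(min(p, n))), seq_len(n),
      n + 1 - seq_len(min(p, n))))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

laplacian <- function(a) {
  out <- -6 * a
  for (ax in 1:3) for (by in c(-1L, 1L))
    out <- out + shift_arr(a, ax, by, fill = 0)
  out
}

# scale-normalized negated LoG, mirror-padded against FFT wraparound and
# border gradients
log_response <- function(a, sigma_vox) {
  p <- min(ceiling(3 * sigma_vox) + 1, dim(a)[1])
  ap <- mirror_pad(a, p)
  resp <- -sigma_vox^2 * laplacian(fft_gaussian_blur(ap, sigma_vox))
  d <- dim(a)
  resp[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]),
       drop = FALSE]
}

#' Extract lesion candidates by multiscale blob detection
#'
#' A Laplacian-of-Gaussian filter bank spanning the configured diameter range
#' (scale-normalized, negated so bright blobs score high) is evaluated via
#' FFT; the per-voxel maximum over scales is converted to robust z units
#' (median/MAD over the mask). Supra-threshold voxels inside the mask are
#' grouped into connected components and each component yields one candidate
#' at its response-weighted centre of gravity, scored by its peak blobness.
#'
#' @param vol preprocessed [volume()].
#' @param mask logical organ mask.
#' @param config a [detector_config()].
#' @param case_id id stamped on the candidates.
#' @return candidate data frame: `case_id, x, y, z, score, radius_mm` (world
#'   mm), sorted by descending score. Zero rows is a legal result.
#' @export
extract_candidates <- function(vol, mask, config, case_id = "case") {
  empty <- data.frame(case_id = character(), x = numeric(), y = numeric(),
                      z = numeric(), score = numeric(), radius_mm = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(mask)) return(empty)
  sp <- vol$spacing[1]
  radii <- exp(seq(log(config$blob_diameter_range[1] / 2),
                   log(config$blob_diameter_range[2] / 2), length.out = 3))
  best <- array(-Inf, dim(vol$voxels))
  best_r <- array(radii[1], dim(vol$voxels))
  for (r in radii) {
    sigma <- r / sqrt(3) / sp
    resp <- log_response(vol$voxels, sigma)
    upd <- resp > best
    best[upd] <- resp[upd]
    best_r[upd] <- r
  }
  med <- stats::median(best)
  madv <- stats::mad(best)
  if (madv < 1e-12) madv <- stats::sd(best) + 1e-12
  z <- (best - med) / madv
  # local maxima of the blobness field (3x3x3 box), supra-threshold, in-mask
  boxmax <- best
  for (ax in 1:3)
    boxmax <- pmax(boxmax, shift_arr(boxmax, ax, 1L, -Inf),
                   shift_arr(boxmax, ax, -1L, -Inf))
  peaks <- which(mask & z > config$blob_z_threshold & best >= boxmax)
  if (!length(peaks)) return(empty)
  ai <- arrayInd(peaks, dim(best))
  ord <- order(-z[peaks])
  ai <- ai[ord, , drop = FALSE]; peaks <- peaks[ord]
  # group nearby maxima: greedy non-maximum suppression at the blob radius
  keep <- logical(length(peaks))
  pos_mm <- sweep(sweep(ai - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  for (i in seq_along(peaks)) {
    if (i == 1L) { keep[1] <- TRUE; next }
    kept <- which(keep)
    dd <- sqrt(rowSums((pos_mm[kept, , drop = FALSE] -
                          matrix(pos_mm[i, ], length(kept), 3,
                                 byrow = TRUE))^2))
    sup_r <- pmax(best_r[peaks[kept]], best_r[peaks[i]])
    if (all(dd > sup_r)) keep[i] <- TRUE
  }
  sel <- which(keep)
  out <- data.frame(case_id = case_id,
                    x = pos_mm[sel, 1], y = pos_mm[sel, 2],
                    z = pos_mm[sel, 3],
                    score = z[peaks[sel]],
                    radius_mm = best_r[peaks[sel]],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  utils::head(out, config$max_candidates)
}

#' Label candidates against annotations
#'
#' A candidate is positive iff its centroid lies within
#' `max(annotation radius, hit_distance_mm)` of some annotated ROI centroid.
#'
#' @param candidates candidate data frame.
#' @param annotations ROI data frame for the same case.
#' @param hit_distance_mm distance floor (default 3 mm).
#' @return logical vector, one entry per candidate.
#' @export
label_candidates <- function(candidates, annotations, hit_distance_mm = 3.0) {
  if (!nrow(candidates)) return(logical(0))
  if (is.null(annotations) || !nrow(annotations))
    return(logical(nrow(candidates)))
  if (any(candidates$case_id != annotations$case_id[1]))
    stop("candidates and annotations must share a case_id")
  vapply(seq_len(nrow(candidates)), function(i) {
    d <- sqrt((annotations$x - candidates$x[i])^2 +
                (annotations$y - candidates$y[i])^2 +
                (annotations$z - candidates$z[i])^2)
    any(d <= pmax(annotations$diameter_mm / 2, hit_distance_mm))
  }, logical(1))
}

# -- VOI extraction and augmentation ----------------------------------------

#' Extract a cubic VOI around a world point
#'
#' Indices are clamped at the volume edge (replicate padding), so the result
#' always has the requested shape.
#'
#' @param vol a [volume()].
#' @param centre_mm world-mm centre.
#' @param edge VOI edge length in voxels.
#' @return numeric `edge^3` array.
#' @export
extract_voi <- function(vol, centre_mm, edge) {
  cv <- round(world_to_voxel(vol, centre_mm))
  half <- edge %/% 2L
  idx <- lapply(1:3, function(ax)
    pmin(pmax(cv[ax] - half + seq_len(edge) - 1L, 0L),
         dim(vol$voxels)[ax] - 1L) + 1L)
  vol$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Apply one augmentation transform to a VOI
#'
#' The transform is a shift of whole voxels per axis, isotropic rescaling
#' about the centre (cubic interpolation), and 90-degree-multiple rotations
#' in the axial, coronal, and sagittal planes. A zero-shift, unit-scale,
#' zero-rotation draw is the identity.
#'
#' @param voi cubic array.
#' @param shift integer length-3 shift in voxels.
#' @param scale isotropic scale factor.
#' @param rot integer length-3, quarter-turns in planes (xy, xz, yz).
#' @return augmented array of the same shape.
#' @export
apply_augment <- function(voi, shift = c(0L, 0L, 0L), scale = 1,
                          rot = c(0L, 0L, 0L)) {
  d <- dim(voi)
  out <- voi
  if (any(shift != 0L)) {
    for (ax in 1:3) if (shift[ax] != 0L)
      out <- shift_arr(out, ax, shift[ax], fill = NA)
    # replicate padding for the vacated border
    for (ax in 1:3) {
      # fill NA planes with nearest valid plane
      if (shift[ax] > 0) for (i in seq_len(shift[ax]))
        out[slice.index(out, ax) == i] <-
          out[slice.index(out, ax) == shift[ax] + 1]
      if (shift[ax] < 0) for (i in (d[ax] + shift[ax] + 1):d[ax])
        out[slice.index(out, ax) == i] <-
          out[slice.index(out, ax) == d[ax] + shift[ax]]
    }
  }
  if (abs(scale - 1) > 1e-12) {
    ctr <- (d[1] - 1) / 2
    u <- ctr + (seq_len(d[1]) - 1 - ctr) / scale
    W <- catmull_rom_matrix(d[1], u)      # cubic VOI: one matrix, three axes
    for (ax in 1:3) out <- resample_axis(out, ax, W)
  }
  planes <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (p in 1:3) {
    k <- rot[p] %% 4L
    ax <- planes[[p]]
    for (q in seq_len(k)) {
      perm <- 1:3; perm[ax] <- rev(ax)
      out <- aperm(out, perm)
      ridx <- lapply(dim(out), seq_len)
      ridx[[ax[1]]] <- rev(ridx[[ax[1]]])
      out <- out[ridx[[1]], ridx[[2]], ridx[[3]], drop = FALSE]
    }
  }
  out
}

#' Generate the augmented copies of a positive VOI
#'
#' Draws `config$augment_copies` (default 29) independent transforms: integer
#' shifts within the shift range, a scale in the configured range, and
#' quarter-turn rotations in each plane. When `voi` is larger than the
#' configured VOI edge (a padded super-VOI), shifts are realized as
#' off-centre crops so shifted copies contain real image content; otherwise
#' borders are replicate-padded. Draws depend on the current RNG state, so
#' per-epoch regeneration yields fresh copies.
#'
#' @param voi cubic array of edge `config$voi_edge` or
#'   `config$voi_edge + 2 * config$shift_range`.
#' @param config a [detector_config()].
#' @return list of `augment_copies` augmented arrays of edge
#'   `config$voi_edge`.
#' @export
augment_positive <- function(voi, config) {
  edge <- config$voi_edge
  pad <- (dim(voi)[1] - edge) %/% 2L
  lapply(seq_len(config$augment_copies), function(i) {
    shift <- sample(-config$shift_range:config$shift_range, 3,
                    replace = TRUE)
    if (pad >= config$shift_range) {
      o <- pad + shift
      v <- voi[o[1] + seq_len(edge), o[2] + seq_len(edge),
               o[3] + seq_len(edge), drop = FALSE]
    } else {
      v <- apply_augment(voi, shift = shift)
    }
    apply_augment(v,
                  scale = stats::runif(1, config$scale_range[1],
                                       config$scale_range[2]),
                  rot = sample(0:3, 3, replace = TRUE))
  })
}

# -- features and classifiers -----------------------------------------------

.voi_mask_cache <- new.env(parent = emptyenv())

voi_radial_masks <- function(d) {
  key <- paste(d, collapse = "x")
  m <- .voi_mask_cache[[key]]
  if (!is.null(m)) return(m)
  ctr <- (d + 1) / 2
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - ctr[a])^2)
  r <- sqrt(outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+"))
  m <- list(core = r <= d[1] / 5,
            mid = r > d[1] / 5 & r <= d[1] / 3,
            outer = r > d[1] / 3)
  .voi_mask_cache[[key]] <- m
  m
}

voi_features <- function(voi) {
  d <- dim(voi)
  m <- voi_radial_masks(d)
  g <- 0
  for (ax in 1:3)
    g <- g + (shift_arr(voi, ax, 1L, fill = 0) - voi)^2
  q <- stats::quantile(voi, c(0.1, 0.5, 0.9), names = FALSE)
  core <- mean(voi[m$core]); mid <- mean(voi[m$mid])
  outer_sh <- mean(voi[m$outer])
  c(mean(voi), stats::sd(voi), max(voi), q,
    core, mid, outer_sh,
    core - outer_sh,
    core - mid,
    sqrt(mean(g)))
}

N_FEATURES <- 12L

classifier_layers <- function(config) {
  switch(config$classifier,
         linear_baseline = list(nn_dense(1L)),
         cnn3d = list(nn_conv(4L, 3L), nn_relu(), nn_pool(2L),
                      nn_conv(8L, 3L), nn_relu(), nn_pool(2L),
                      nn_flatten(), nn_dense(16L), nn_relu(), nn_dense(1L)),
         cnn_mip = list(nn_conv(8L, 3L), nn_relu(), nn_pool(2L),
                        nn_conv(16L, 3L), nn_relu(), nn_pool(2L),
                        nn_flatten(), nn_dense(32L), nn_relu(),
                        nn_dense(1L)))
}

classifier_input_shape <- function(config) {
  e <- config$voi_edge
  switch(config$classifier,
         linear_baseline = N_FEATURES,
         cnn3d = c(e, e, e, 1L),
         cnn_mip = c(e, e, 3L))
}

# orthogonal maximum-intensity projections stacked as channels
voi_to_mip <- function(voi) {
  e <- dim(voi)[1]
  out <- array(0, c(e, e, 3L))
  out[, , 1] <- apply(voi, c(1, 2), max)
  out[, , 2] <- apply(voi, c(1, 3), max)
  out[, , 3] <- apply(voi, c(2, 3), max)
  out
}

classifier_input <- function(voi, config, stats_ms) {
  x <- switch(config$classifier,
              linear_baseline = voi_features(voi),
              cnn3d = array(voi, c(dim(voi), 1L)),
              cnn_mip = voi_to_mip(voi))
  (x - stats_ms$m) / stats_ms$s
}

#' Initialize an (untrained) detector
#'
#' @param config a [detector_config()].
#' @param seed parameter-initialization seed.
#' @return object of class `trained_detector` with random parameters.
#' @export
init_detector <- function(config, seed = 1L) {
  net <- nn_init(classifier_layers(config), classifier_input_shape(config),
                 seed = child_seed(seed, "init"))
  structure(list(config = config, net = net,
                 stats = list(m = 0, s = 1),
                 provenance = list(trained = FALSE, seed = seed)),
            class = "trained_detector")
}

#' Prepare the reusable per-case detection products for training
#'
#' Runs preprocessing, organ-mask extraction, and candidate extraction once
#' for a case and extracts a padded super-VOI per candidate (for shift
#' augmentation). Results depend only on the volume and config, so they can
#' be cached across training arms that differ only in annotations.
#'
#' @param case a [case_record()].
#' @param config a [detector_config()].
#' @return list `candidates` (data frame) and `vois` (list of padded arrays).
#' @export
prepare_case <- function(case, config) {
  vol <- case_volume(case, config$task)
  pre <- preprocess(vol, config)
  mask <- extract_organ_mask(pre, config)
  cands <- extract_candidates(pre, mask, config, case$case_id)
  pad <- config$voi_edge + 2L * config$shift_range
  vois <- lapply(seq_len(nrow(cands)), function(i)
    extract_voi(pre, c(cands$x[i], cands$y[i], cands$z[i]), pad))
  list(candidates = cands, vois = vois)
}

crop_center <- function(voi, edge) {
  d <- dim(voi)[1]
  o <- (d - edge) %/% 2L
  voi[o + seq_len(edge), o + seq_len(edge), o + seq_len(edge), drop = FALSE]
}

#' Train a detector
#'
#' Candidates from the training cases are labelled against the supplied
#' annotations (positive iff within `max(radius, hit_distance_mm)` of an
#' annotated ROI). Each epoch regenerates `augment_copies` augmented copies
#' of every positive VOI and re-draws a negative undersample so the class
#' counts are equal, then fits the configured classifier by minibatch
#' momentum SGD on cross-entropy loss. Candidates the annotator did not mark
#' train as negatives — missed lesions therefore become label noise, which is
#' the phenomenon this package studies.
#'
#' @param config a [detector_config()].
#' @param cases list of [case_record()]s.
#' @param annotations_by_case named list (case id -> ROI data frame), or a
#'   single ROI data frame covering all cases.
#' @param seed training seed (initialization, augmentation, undersampling,
#'   shuffling).
#' @param prepared optional named list of [prepare_case()] results keyed by
#'   case id (cache).
#' @return a `trained_detector`.
#' @export
train_detector <- function(config, cases, annotations_by_case, seed = 1L,
                           prepared = NULL) {
  if (is.data.frame(annotations_by_case)) {
    df <- annotations_by_case
    annotations_by_case <- split(df, df$case_id)
  }
  pos_vois <- list(); neg_vois <- list()
  for (cs in cases) {
    pc <- prepared[[cs$case_id]]
    if (is.null(pc)) pc <- prepare_case(cs, config)
    if (!nrow(pc$candidates)) next
    ann <- annotations_by_case[[cs$case_id]]
    lab <- label_candidates(pc$candidates, ann, config$hit_distance_mm)
    pos_vois <- c(pos_vois, pc$vois[lab])
    neg_vois <- c(neg_vois, pc$vois[!lab])
  }
  if (!length(pos_vois))
    stop("training set has no positive candidates (missing class: positive)")
  if (!length(neg_vois))
    stop("training set has no negative candidates (missing class: negative)")
  edge <- config$voi_edge
  # input standardization from the unaugmented candidate population
  base_inputs <- lapply(c(pos_vois, neg_vois), function(v)
    switch(config$classifier,
           linear_baseline = voi_features(crop_center(v, edge)),
           cnn3d = array(crop_center(v, edge), c(edge, edge, edge, 1L)),
           cnn_mip = voi_to_mip(crop_center(v, edge))))
  if (config$classifier == "linear_baseline") {
    fm <- do.call(rbind, base_inputs)
    stats_ms <- list(m = colMeans(fm), s = pmax(apply(fm, 2, stats::sd),
                                                1e-9))
  } else {
    allv <- unlist(base_inputs)
    stats_ms <- list(m = mean(allv), s = max(stats::sd(allv), 1e-9))
  }
  net <- nn_init(classifier_layers(config), classifier_input_shape(config),
                 seed = child_seed(seed, "init"))
  state <- list()
  for (epoch in seq_len(config$epochs)) {
    ep <- with_seed(child_seed(seed, "epoch", epoch), {
      xs <- list(); ys <- numeric(0)
      for (v in pos_vois) {
        copies <- c(list(crop_center(v, edge)), augment_positive(v, config))
        for (cp in copies) {
          xs[[length(xs) + 1L]] <- classifier_input(cp, config, stats_ms)
          ys <- c(ys, 1)
        }
      }
      n_pos <- length(xs)
      pick <- sample.int(length(neg_vois), n_pos,
                         replace = length(neg_vois) < n_pos)
      for (i in pick) {
        xs[[length(xs) + 1L]] <-
          classifier_input(crop_center(neg_vois[[i]], edge), config,
                           stats_ms)
        ys <- c(ys, 0)
      }
      ord <- sample.int(length(xs))
      list(xs = xs[ord], ys = ys[ord], n_pos = n_pos,
           n_neg = length(xs) - n_pos)
    })
    if (!is.null(config$epoch_hook))
      config$epoch_hook(epoch, ep$n_pos, ep$n_neg)
    nb <- ceiling(length(ep$xs) / config$minibatch)
    for (b in seq_len(nb)) {
      ix <- ((b - 1L) * config$minibatch + 1L):min(b * config$minibatch,
                                                   length(ep$xs))
      upd <- nn_train_batch(net, ep$xs[ix], ep$ys[ix], state,
                            config$learning_rate, config$momentum,
                            config$weight_decay)
      net <- upd$net; state <- upd$state
    }
  }
  structure(list(config = config, net = net, stats = stats_ms,
                 provenance = list(trained = TRUE, seed = seed,
                                   case_ids = vapply(cases, `[[`,
                                                     character(1), "case_id"),
                                   n_pos_candidates = length(pos_vois),
                                   n_neg_candidates = length(neg_vois))),
            class = "trained_detector")
}

#' Score candidates of a case with a trained detector
#'
#' @param detector a `trained_detector`.
#' @param pre preprocessed [volume()] of the case.
#' @param candidates candidate data frame from [extract_candidates()].
#' @return the candidates with `score` replaced by the classifier probability
#'   (in `[0, 1]`), sorted by descending score.
#' @export
score_candidates <- function(detector, pre, candidates) {
  if (!nrow(candidates)) return(candidates)
  cfg <- detector$config
  probs <- vapply(seq_len(nrow(candidates)), function(i) {
    voi <- extract_voi(pre, c(candidates$x[i], candidates$y[i],
                              candidates$z[i]), cfg$voi_edge)
    nn_predict_prob(detector$net,
                    classifier_input(voi, cfg, detector$stats))
  }, numeric(1))
  candidates$score <- probs
  candidates[order(-candidates$score), , drop = FALSE]
}

#' Run the full CAD pipeline on one volume
#'
#' Preprocess, extract the organ mask and blob candidates, then attach the
#' classifier score to each candidate. An empty mask yields an empty
#' candidate list with a warning.
#'
#' @param detector a `trained_detector`.
#' @param vol a [volume()] of the detector's task.
#' @param case_id id stamped on the candidates.
#' @return scored candidate data frame sorted by descending score.
#' @export
run_cad <- function(detector, vol, case_id = "case") {
  cfg <- detector$config
  pre <- preprocess(vol, cfg)
  mask <- extract_organ_mask(pre, cfg)
  cands <- extract_candidates(pre, mask, cfg, case_id)
  score_candidates(detector, pre, cands)
}
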