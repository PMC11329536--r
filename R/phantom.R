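#' Phantom generation parameters
#'
#' Describes the synthetic world for one task. Chest phantoms emulate lung
#' parenchyma: a smooth low-frequency background plus Gaussian noise, bright
#' tubular vessels, and soft-edged spherical nodules (target nodules >= 6 mm
#' in diameter, distractor nodules < 6 mm; a configurable fraction of targets
#' is rendered at reduced contrast to emulate ground-glass opacity). Brain
#' phantoms emulate MRA: a dark background, a bright binary-branching vessel
#' tree, hemispherical aneurysm bumps (>= 2 mm) at bifurcation points, and
#' cone-shaped infundibular-dilation distractors at branch origins.
#'
#' Diameters are drawn from truncated lognormal distributions with the task's
#' diameter floor enforced on targets.
#'
#' @param task `"chest"` or `"brain"`.
#' @param grid_dim voxels per axis (length 1 or 3).
#' @param spacing_mm isotropic voxel spacing (mm).
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param background_mean mean background intensity.
#' @param background_lf_amp amplitude of the smooth low-frequency background
#'   field.
#' @param lesion_contrast range (min,max) of lesion peak contrast above
#'   background.
#' @param lesion_diameter_meanlog,lesion_diameter_sdlog lognormal parameters
#'   of target-lesion diameter (mm).
#' @param lesion_diameter_range truncation range of target diameters; the
#'   lower bound is the task's positivity floor (6 mm chest, 2 mm brain).
#' @param distractor_diameter_range diameter range of distractor nodules
#'   (chest; must stay < 6 mm) or infundibulum cone base (brain).
#' @param ggo_prob probability a chest target is rendered as a low-contrast
#'   ground-glass variant.
#' @param vessel_intensity peak vessel intensity.
#' @param n_vessels number of straight vessel tubes (chest).
#' @param vessel_radius_range vessel tube radius range (mm).
#' @param branch_levels binary-tree depth of the brain vessel tree.
#' @param branch_length_range segment length range (mm, brain tree).
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(task = c("chest", "brain"),
                           grid_dim = 64L,
                           spacing_mm = if (task[1] == "chest") 1.0 else 0.5,
                           noise_sd = 8,
                           background_mean = if (task[1] == "chest") 100 else 20,
                           background_lf_amp = if (task[1] == "chest") 15 else 0,
                           lesion_contrast = c(90, 160),
                           lesion_diameter_meanlog =
                             if (task[1] == "chest") log(9) else log(3.5),
                           lesion_diameter_sdlog = 0.3,
                           lesion_diameter_range =
                             if (task[1] == "chest") c(6, 18) else c(2, 8),
                           distractor_diameter_range =
                             if (task[1] == "chest") c(3, 5.8) else c(1.5, 3),
                           ggo_prob = if (task[1] == "chest") 0.2 else 0,
                           vessel_intensity = 200,
                           n_vessels = 6L,
                           vessel_radius_range = c(0.8, 1.8),
                           branch_levels = 4L,
                           branch_length_range = c(6, 10)) {
  task <- match.arg(task)
  if (length(grid_dim) == 1L) grid_dim <- rep(grid_dim, 3L)
  floor_mm <- if (task == "chest") 6 else 2
  if (lesion_diameter_range[1] < floor_mm)
    stop(sprintf("target-lesion minimum diameter must be >= %g mm for the %s task",
                 floor_mm, task))
  if (task == "chest" && distractor_diameter_range[2] >= 6)
    stop("chest distractor nodules must stay below 6 mm")
  fov <- grid_dim * spacing_mm
  if (lesion_diameter_range[2] > min(fov) / 2)
    stop("grid too small to fit the largest configured lesion")
  structure(as.list(environment()), class = "phantom_params")
}

# -- placement layer ---------------------------------------------------------
# Placement draws are separated from texture draws so the ground-truth layout
# of a case is identical whether or not voxel data is rendered.

rtrunc_lnorm <- function(n, meanlog, sdlog, range) {
  lo <- stats::plnorm(range[1], meanlog, sdlog)
  hi <- stats::plnorm(range[2], meanlog, sdlog)
  stats::qlnorm(stats::runif(n, lo, hi), meanlog, sdlog)
}

# rejection-sample non-overlapping sphere centres inside the field of view
place_spheres <- function(diams, fov, margin, existing = NULL,
                          max_tries = 500L) {
  centres <- existing
  placed <- matrix(NA_real_, length(diams), 3L)
  for (i in seq_along(diams)) {
    r <- diams[i] / 2
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      p <- stats::runif(3, margin + r, fov - margin - r)
      if (is.null(centres) || nrow(centres) == 0L ||
          all(sqrt(colSums((t(centres[, 1:3, drop = FALSE]) - p)^2)) >
              centres[, 4] / 2 + r + 2)) { ok <- TRUE; break }
    }
    if (!ok) stop("phantom generation: lesion placement failed after ",
                  max_tries, " tries (grid too crowded)")
    placed[i, ] <- p
    centres <- rbind(centres, c(p, diams[i]))
  }
  placed
}

# random binary-branching vessel tree; returns segments plus node types
grow_vessel_tree <- function(params, fov) {
  segs <- list()
  bif <- NULL; orig <- NULL
  root <- c(fov[1] / 2, fov[2] / 2, 0.08 * fov[3])
  queue <- list(list(p = root, dir = c(0, 0, 1),
                     r = 0.045 * min(fov), level = 1L))
  while (length(queue)) {
    node <- queue[[1]]; queue <- queue[-1]
    len <- stats::runif(1, params$branch_length_range[1],
                        params$branch_length_range[2])
    q <- node$p + node$dir * len
    # steer back toward the interior so branches stay in the grid
    q <- pmin(pmax(q, 0.08 * fov), 0.92 * fov)
    segs[[length(segs) + 1L]] <- c(node$p, q, node$r)
    if (node$level < params$branch_levels) {
      bif <- rbind(bif, q)
      for (k in 1:2) {
        d <- node$dir + stats::rnorm(3, 0, 0.45)
        d <- d / sqrt(sum(d^2))
        orig <- rbind(orig, c(q, d))
        queue[[length(queue) + 1L]] <-
          list(p = q, dir = d, r = node$r * 0.8, level = node$level + 1L)
      }
    }
  }
  list(segments = do.call(rbind, segs), bifurcations = bif,
       branch_origins = orig)
}

phantom_layout <- function(params, n_lesions, n_distractors, seed,
                           case_id = "case") {
  with_seed(child_seed(seed, "placement"), {
    fov <- params$grid_dim * params$spacing_mm
    out <- list(rois = empty_rois())
    add_roi <- function(p, d, tag)
      out$rois <<- rbind(out$rois,
                         spherical_roi(case_id, p, d, "ground_truth", tag))
    if (params$task == "chest") {
      # straight vessel tubes through the volume
      vs <- replicate(params$n_vessels, {
        a <- stats::runif(3, 0.1 * fov, 0.9 * fov)
        d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
        c(a - d * max(fov), a + d * max(fov),
          stats::runif(1, params$vessel_radius_range[1],
                       params$vessel_radius_range[2]))
      })
      out$vessels <- t(vs)
      diams <- c(if (n_lesions > 0)
                   rtrunc_lnorm(n_lesions, params$lesion_diameter_meanlog,
                                params$lesion_diameter_sdlog,
                                params$lesion_diameter_range),
                 if (n_distractors > 0)
                   rtrunc_lnorm(n_distractors, log(4.5), 0.25,
                                params$distractor_diameter_range))
      if (length(diams)) {
        pos <- place_spheres(diams, fov, margin = 2)
        out$ggo <- stats::runif(length(diams)) < params$ggo_prob
        for (i in seq_along(diams))
          add_roi(pos[i, ], diams[i],
                  if (i <= n_lesions) "lesion" else "distractor")
      }
    } else {
      tree <- grow_vessel_tree(params, fov)
      out$vessels <- tree$segments
      nb <- if (is.null(tree$bifurcations)) 0L else nrow(tree$bifurcations)
      if (n_lesions > nb)
        stop("phantom generation: vessel tree has ", nb,
             " bifurcations, cannot host ", n_lesions, " aneurysms")
      if (n_lesions > 0) {
        at <- sample.int(nb, n_lesions)
        diams <- rtrunc_lnorm(n_lesions, params$lesion_diameter_meanlog,
                              params$lesion_diameter_sdlog,
                              params$lesion_diameter_range)
        for (i in seq_len(n_lesions)) {
          # bump sits on the vessel wall, offset outwards from the branch point
          off <- stats::rnorm(3); off <- off / sqrt(sum(off^2))
          p <- tree$bifurcations[at[i], ] + off * diams[i] / 4
          add_roi(pmin(pmax(p, 2), fov - 2), diams[i], "lesion")
        }
      }
      no <- if (is.null(tree$branch_origins)) 0L else nrow(tree$branch_origins)
      if (n_distractors > 0) {
        if (n_distractors > no)
          stop("phantom generation: not enough branch origins for distractors")
        at <- sample.int(no, n_distractors)
        diams <- stats::runif(n_distractors,
                              params$distractor_diameter_range[1],
                              params$distractor_diameter_range[2])
        for (i in seq_len(n_distractors)) {
          o <- tree$branch_origins[at[i], ]
          out$cones <- rbind(out$cones, c(o, diams[i]))
          add_roi(pmin(pmax(o[1:3], 2), fov - 2), diams[i], "distractor")
        }
      }
    }
    out
  })
}

# -- rendering layer ---------------------------------------------------------

voxel_coords <- function(params) {
  gd <- params$grid_dim; sp <- params$spacing_mm
  list(x = (seq_len(gd[1]) - 1) * sp,
       y = (seq_len(gd[2]) - 1) * sp,
       z = (seq_len(gd[3]) - 1) * sp)
}

# squared distance of every voxel to a segment (a, b); cc = voxel_coords
dist2_segment <- function(cc, a, b) {
  gd <- c(length(cc$x), length(cc$y), length(cc$z))
  d <- b - a
  dd <- sum(d^2)
  px <- cc$x - a[1]; py <- cc$y - a[2]; pz <- cc$z - a[3]
  # t = clamp((P-a).d / |d|^2); separable accumulation over axes
  tx <- outer(px * d[1], py * d[2], "+")
  t3 <- outer(as.vector(tx), pz * d[3], "+") / max(dd, 1e-12)
  t3 <- array(pmin(pmax(t3, 0), 1), dim = gd)
  qx <- array(rep(px, times = gd[2] * gd[3]), gd)
  qy <- array(rep(rep(py, each = gd[1]), times = gd[3]), gd)
  qz <- array(rep(pz, each = gd[1] * gd[2]), gd)
  (qx - t3 * d[1])^2 + (qy - t3 * d[2])^2 + (qz - t3 * d[3])^2
}

dist2_point <- function(cc, p) {
  gd <- c(length(cc$x), length(cc$y), length(cc$z))
  dx2 <- (cc$x - p[1])^2; dy2 <- (cc$y - p[2])^2; dz2 <- (cc$z - p[3])^2
  array(outer(as.vector(outer(dx2, dy2, "+")), dz2, "+"), gd)
}

# soft-edged sphere profile: ~1 inside, 0.5 at radius, fast Gaussian-like
# falloff outside
soft_sphere <- function(cc, centre, diameter_mm, contrast) {
  r2 <- dist2_point(cc, centre)
  contrast * exp(-log(2) * (r2 / (diameter_mm / 2)^2)^3)
}

render_phantom <- function(params, layout, seed) {
  with_seed(child_seed(seed, "texture"), {
    gd <- params$grid_dim
    cc <- voxel_coords(params)
    vox <- array(params$background_mean, dim = gd)
    if (params$background_lf_amp > 0) {
      ph <- stats::runif(6, 0, 2 * pi)
      fov <- gd * params$spacing_mm
      lf <- outer(sin(2 * pi * cc$x / fov[1] + ph[1]) +
                    0.6 * sin(4 * pi * cc$x / fov[1] + ph[2]),
                  sin(2 * pi * cc$y / fov[2] + ph[3]), "+")
      lf <- outer(as.vector(lf), sin(2 * pi * cc$z / fov[3] + ph[5]), "+")
      vox <- vox + params$background_lf_amp / 3 * array(lf, gd)
    }
    if (!is.null(layout$vessels)) {
      for (i in seq_len(nrow(layout$vessels))) {
        sg <- layout$vessels[i, ]
        d2 <- dist2_segment(cc, sg[1:3], sg[4:6])
        vox <- pmax(vox, params$vessel_intensity *
                           exp(-log(2) * (d2 / sg[7]^2)^2))
      }
    }
    rois <- layout$rois
    for (i in seq_len(nrow(rois))) {
      contrast <- stats::runif(1, params$lesion_contrast[1],
                               params$lesion_contrast[2])
      if (!is.null(layout$ggo) && i <= length(layout$ggo) && layout$ggo[i])
        contrast <- contrast * 0.4                    # ground-glass variant
      if (params$task == "brain" && rois$tag[i] == "distractor") {
        # cone-shaped infundibular widening along the branch direction
        co <- layout$cones[match(i, which(rois$tag == "distractor")), ]
        axis <- co[4:6]; base <- co[1:3]; h <- co[7] * 1.5
        for (s in seq(0, 1, length.out = 4)) {
          p <- base + axis * s * h
          w <- co[7] * (1 - 0.6 * s)
          vox <- pmax(vox, soft_sphere(cc, p, w, params$vessel_intensity))
        }
      } else {
        add <- soft_sphere(cc, c(rois$x[i], rois$y[i], rois$z[i]),
                           rois$diameter_mm[i], contrast)
        vox <- if (params$task == "brain")
          pmax(vox, add / max(contrast, 1e-9) * params$vessel_intensity)
        else vox + add
      }
    }
    vox <- vox + stats::rnorm(length(vox), 0, params$noise_sd)
    volume(vox, spacing = rep(params$spacing_mm, 3), origin = c(0, 0, 0),
           task = params$task)
  })
}

#' Generate one phantom volume with ground truth
#'
#' Places `n_lesions` target lesions and `n_distractors` distractor
#' structures (see [phantom_params()]) and renders the voxel grid. The
#' returned ROIs are the exact placed centres and diameters. Identical
#' `(params, ..., seed)` give bit-identical output; the ground-truth layout
#' uses an RNG stream separate from the texture so it is stable across
#' rendering modes.
#'
#' @param params a [phantom_params()].
#' @param n_lesions number of target lesions.
#' @param n_distractors number of distractor structures.
#' @param seed integer seed.
#' @param case_id case id stamped on the ROIs.
#' @param render if `FALSE`, skip voxel rendering (layout only).
#' @return list with `volume` (a [volume()], or `NULL` when `render = FALSE`)
#'   and `rois` (ground-truth ROI data frame).
#' @export
generate_phantom <- function(params, n_lesions, n_distractors, seed,
                             case_id = "case", render = TRUE) {
  stopifnot(inherits(params, "phantom_params"),
            n_lesions >= 0, n_distractors >= 0)
  layout <- phantom_layout(params, n_lesions, n_distractors, seed, case_id)
  vol <- if (render) render_phantom(params, layout, seed) else NULL
  list(volume = vol, rois = layout$rois)
}
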