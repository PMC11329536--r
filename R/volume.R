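#' 3D image volume
#'
#' A `volume` couples a 3D scalar voxel grid with its world geometry: voxel
#' spacing in mm per axis and the world-mm position of voxel (0,0,0). Axis
#' order is (x, y, z) throughout; voxel indices are 0-based in world-geometry
#' computations (see [world_to_voxel()]).
#'
#' @param voxels numeric 3D array of intensities (all finite).
#' @param spacing numeric length-3, mm per axis, all > 0.
#' @param origin numeric length-3, world mm of voxel (0,0,0).
#' @param task `"chest"` or `"brain"`.
#' @return an object of class `volume`.
#' @export
volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   task = c("chest", "brain")) {
  task <- match.arg(task)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("voxel grid must be non-empty")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  if (any(!is.finite(voxels))) stop("all intensities must be finite")
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         origin = as.numeric(origin), task = task),
    class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> task=%s  dim=%s  spacing=%s mm  origin=%s mm\n",
              x$task, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ","),
              paste(signif(x$origin, 4), collapse = ",")))
  invisible(x)
}

#' Convert world-mm coordinates to continuous voxel indices (and back)
#'
#' The mapping is `point_mm = origin + index * spacing` per axis, with 0-based
#' indices. `world_to_voxel` returns the continuous index; round only when you
#' need an integer grid position. Out-of-grid points are returned as
#' out-of-range indices; callers clip.
#'
#' @param vol a [volume()].
#' @param point_mm numeric length-3 world point, or an n x 3 matrix of points.
#' @return continuous voxel index (length-3 vector or n x 3 matrix).
#' @export
world_to_voxel <- function(vol, point_mm) {
  if (is.matrix(point_mm))
    return(sweep(sweep(point_mm, 2, vol$origin), 2, vol$spacing, "/"))
  (point_mm - vol$origin) / vol$spacing
}

#' @rdname world_to_voxel
#' @param index continuous 0-based voxel index (vector or n x 3 matrix).
#' @export
voxel_to_world <- function(vol, index) {
  if (is.matrix(index))
    return(sweep(sweep(index, 2, vol$spacing, "*"), 2, vol$origin, "+"))
  vol$origin + index * vol$spacing
}
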