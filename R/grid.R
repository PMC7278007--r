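#' Regular 3D voxel grid
#'
#' Geometry shared by all volumes and masks: voxel counts, spacing in mm,
#' and the world coordinate (mm) of the centre of voxel (0,0,0). Indexing
#' is 0-based and voxel-centred, with x the fastest-varying axis; the world
#' coordinate of voxel index i is `origin + i * spacing` per axis.
#'
#' @param shape integer(3), voxel counts (nx, ny, nz); all >= 1.
#' @param spacing numeric(3), voxel size in mm per axis; all > 0.
#' @param origin numeric(3), world coordinate (mm) of the first voxel centre.
#' @return An object of class `grid3d`.
#' @export
grid3d <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(shape < 1L)) stop("all shape entries must be >= 1")
  if (any(spacing <= 0)) stop("all spacings must be > 0")
  if (any(!is.finite(spacing)) || any(!is.finite(origin))) {
    stop("spacing and origin must be finite")
  }
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @rdname grid3d
#' @param g,a,b `grid3d` objects.
#' @param tol geometry tolerance in mm.
#' @export
grids_equal <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

#' @rdname grid3d
#' @export
voxel_volume_mm3 <- function(g) prod(g$spacing)

#' @rdname grid3d
#' @param axis axis index 1..3.
#' @export
grid_coords <- function(g, axis) {
  g$origin[axis] + (seq_len(g$shape[axis]) - 1) * g$spacing[axis]
}

# world extent of the grid as a box [lo, hi] per axis (voxel edges)
grid_extent <- function(g) {
  lo <- g$origin - 0.5 * g$spacing
  hi <- g$origin + (g$shape - 0.5) * g$spacing
  rbind(lo = lo, hi = hi)
}

#' Scalar volume on a grid
#'
#' A 3D scalar field with geometry and a unit tag. HU volumes are
#' validated against the scanner range \[-1024, 3071\].
#'
#' @param values numeric array with dim equal to `grid$shape`.
#' @param grid a [grid3d()].
#' @param unit one of "HU", "MR-arbitrary", "density", "Gy", "mm",
#'   "gamma", "unitless".
#' @return An object of class `volume`.
#' @export
volume <- function(values, grid, unit = "unitless") {
  unit <- match.arg(unit, c("HU", "MR-arbitrary", "density", "Gy",
                            "mm", "gamma", "unitless"))
  values <- as.array(values)
  if (is.null(dim(values)) || length(dim(values)) != 3 ||
      !all(dim(values) == grid$shape)) {
    stop("values must be a 3D array matching grid shape")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("volume values must be finite everywhere")
  }
  if (unit == "HU" && (min(values) < -1024 || max(values) > 3071)) {
    stop("HU values must lie within [-1024, 3071]")
  }
  structure(list(values = values, grid = grid, unit = unit),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("volume [%s]: ", x$unit))
  print(x$grid)
  cat(sprintf("  range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Binary mask on a grid
#'
#' @param member logical array with dim equal to `grid$shape`.
#' @param grid a [grid3d()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(member, grid) {
  member <- as.array(member)
  storage.mode(member) <- "logical"
  if (length(dim(member)) != 3 || !all(dim(member) == grid$shape)) {
    stop("member must be a 3D logical array matching grid shape")
  }
  if (anyNA(member)) stop("mask must not contain NA")
  structure(list(member = member, grid = grid), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d member voxels (%.2f cm^3) on ",
              sum(x$member), mask_volume_cm3(x)))
  print(x$grid)
  invisible(x)
}

#' @rdname binary_mask
#' @param mask a `binary_mask`.
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$member) * voxel_volume_mm3(mask$grid) / 1000
}

#' Tissue label map
#'
#' Integer class codes on a grid: air = 0, soft tissue = 1, cortical
#' bone = 2, grey matter = 3, white matter = 4, CSF = 5.
#'
#' @param labels integer array matching `grid$shape` with values in 0..5.
#' @param grid a [grid3d()].
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, grid) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (length(dim(labels)) != 3 || !all(dim(labels) == grid$shape)) {
    stop("labels must be a 3D array matching grid shape")
  }
  if (anyNA(labels) || min(labels) < 0L || max(labels) > 5L) {
    stop("labels must be integers in 0..5")
  }
  structure(list(labels = labels, grid = grid), class = "label_map")
}

#' Tissue class codes and names
#'
#' @return Named integer vector mapping class name to label code.
#' @export
tissue_classes <- function() {
  c(air = 0L, soft = 1L, bone = 2L, gm = 3L, wm = 4L, csf = 5L)
}

#' Resample a volume onto a target grid
#'
#' Trilinear (scalars) or nearest-neighbour (labels, masks) sampling at
#' the target voxel centres. Voxels sampled outside the source extent
#' receive `fill` (default -1000 for HU volumes, 0 otherwise).
#'
#' @param vol a [volume()].
#' @param target a [grid3d()] overlapping `vol` in world space.
#' @param mode "trilinear" or "nearest".
#' @param fill fill value for out-of-extent voxels.
#' @return A [volume()] on `target`.
#' @export
resample_to <- function(vol, target,
                        mode = c("trilinear", "nearest"),
                        fill = NULL) {
  mode <- match.arg(mode)
  if (is.null(fill)) fill <- if (vol$unit == "HU") -1000 else 0
  ea <- grid_extent(vol$grid)
  eb <- grid_extent(target)
  if (any(ea["hi", ] <= eb["lo", ]) || any(eb["hi", ] <= ea["lo", ])) {
    stop("no spatial overlap between volume and target grid")
  }
  out <- .resample_cpp(as.numeric(vol$values), vol$grid$shape,
                       vol$grid$spacing, vol$grid$origin,
                       target$shape, target$spacing, target$origin,
                       mode, fill)
  dim(out) <- target$shape
  volume(out, target, unit = vol$unit)
}

#' @rdname resample_to
#' @param mask a [binary_mask()].
#' @export
resample_mask <- function(mask, target) {
  v <- volume(array(as.numeric(mask$member), mask$grid$shape),
              mask$grid, unit = "unitless")
  r <- resample_to(v, target, mode = "nearest", fill = 0)
  binary_mask(r$values > 0.5, target)
}

#' Euclidean distance from a mask
#'
#' Exact Euclidean distance (mm) from each voxel centre to the nearest
#' member voxel centre, 0 inside the mask; respects anisotropic spacing.
#'
#' @param mask a nonempty [binary_mask()].
#' @return A [volume()] with unit "mm".
#' @export
distance_from_mask <- function(mask) {
  if (!any(mask$member)) stop("empty mask")
  d <- .distance_transform_cpp(as.logical(mask$member), mask$grid$shape,
                               mask$grid$spacing)
  dim(d) <- mask$grid$shape
  volume(d, mask$grid, unit = "mm")
}

#' Connected components of a mask (6-connectivity)
#'
#' @param mask a [binary_mask()].
#' @return Integer array of component labels (0 outside the mask).
#' @export
label_components <- function(mask) {
  lab <- .label_components_cpp(as.logical(mask$member), mask$grid$shape)
  dim(lab) <- mask$grid$shape
  lab
}
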