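#' Default CT Hounsfield units per tissue class
#'
#' Air -1000, other soft tissue 40, cortical bone 942, grey matter 41,
#' white matter 25, CSF 15. The five brain values are the literature
#' values used by the segmentation-based sCT conversion; "other soft
#' tissue" at 40 HU is the configurable sixth class.
#'
#' @return Named numeric vector over the six tissue classes.
#' @export
hu_table <- function() {
  c(air = -1000, soft = 40, bone = 942, gm = 41, wm = 25, csf = 15)
}

#' Default T1w-like MR class mean intensities (arbitrary units)
#'
#' Ordered so that every class is separable from its intensity
#' neighbours: air < bone < CSF < GM < soft tissue < WM. White matter
#' brightest and CSF dark as on T1-weighted images; scalp fat bright.
#'
#' @return Named numeric vector over the six tissue classes.
#' @export
mr_class_means <- function() {
  c(air = 0, soft = 135, bone = 30, gm = 100, wm = 170, csf = 65)
}

# clinical structure volume ranges (cm^3) used to draw cohort lesions
gtv_range <- function(group) {
  switch(group, glioma = c(14.2, 112.3), metastasis = c(0.1, 16.4))
}
ptv_range <- function(group) {
  switch(group, glioma = c(132.8, 373.3), metastasis = c(0.3, 28.8))
}

sphere_radius_mm <- function(vol_cm3) (3 * 1000 * vol_cm3 / (4 * pi))^(1 / 3)

# GTV -> PTV margin by matching the quantile of the group's GTV range to
# the same quantile of its PTV range (sphere-equivalent radii).
matched_ptv_margin <- function(lesion_volume_cm3, group) {
  gr <- gtv_range(group)
  pr <- ptv_range(group)
  q <- (lesion_volume_cm3 - gr[1]) / diff(gr)
  q <- min(max(q, 0), 1)
  target_ptv <- pr[1] + q * diff(pr)
  max(sphere_radius_mm(target_ptv) - sphere_radius_mm(lesion_volume_cm3), 1)
}

#' Head phantom configuration
#'
#' Study conditions for one synthetic case: a ~200 x 200 x 180 mm head
#' with nested ellipsoid layers (scalp, skull shell, CSF, grey-matter
#' shell, white-matter core), an air sinus cavity and an ellipsoidal
#' contrast-enhancing lesion. Acquisition geometry follows the emulated
#' protocol: 1 x 1 mm in-plane with 2 mm slices for glioma and 1 mm
#' slices for metastasis cases; `spacing_scale` coarsens all axes for
#' desk-scale runs.
#'
#' @param group "glioma" or "metastasis".
#' @param lesion_volume_cm3 target GTV volume; must lie inside the
#'   group's clinical GTV range (glioma 14.2-112.3, metastasis
#'   0.1-16.4 cm^3). Defaults to the group mean (50.0 / 4.3 cm^3).
#' @param spacing_scale multiplier on voxel spacing (1 = clinical
#'   resolution; 3 is a typical desk-scale choice).
#' @param grid optional explicit [grid3d()] overriding the default.
#' @param ptv_margin_mm GTV to PTV expansion; default derives it by
#'   matching range quantiles of the group's GTV and PTV volumes.
#' @param noise_sd_ct CT noise SD in HU (default 20).
#' @param noise_sd_mr MR noise SD in intensity units (default 5, i.e.
#'   ~3\% of the white-matter mean).
#' @param bias_field_amplitude multiplicative MR shading amplitude in
#'   \[0, 1) (default 0.1).
#' @param contrast_enhancement multiplicative MR boost of the lesion
#'   (default 1.4; 1 = no enhancement).
#' @param skull_hu_range continuous skull HU gradient (outer/inner
#'   cortical tables high, diploe low); NULL for uniform 942 HU.
#' @param pv_blur_voxels partial-volume Gaussian blur of the CT, in
#'   voxels (0 disables).
#' @param skull_thickness_mm skull shell thickness.
#' @param hu,mr_means class HU and MR mean lookups.
#' @param seed integer RNG seed; every stochastic element derives from it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(group = c("glioma", "metastasis"),
                           lesion_volume_cm3 = NULL,
                           spacing_scale = 1,
                           grid = NULL,
                           ptv_margin_mm = NULL,
                           noise_sd_ct = 20,
                           noise_sd_mr = 5,
                           bias_field_amplitude = 0.1,
                           contrast_enhancement = 1.4,
                           skull_hu_range = c(700, 1300),
                           pv_blur_voxels = 0.5,
                           skull_thickness_mm = 7,
                           hu = hu_table(),
                           mr_means = mr_class_means(),
                           seed = 1L) {
  group <- match.arg(group)
  if (is.null(lesion_volume_cm3)) {
    lesion_volume_cm3 <- switch(group, glioma = 50.0, metastasis = 4.3)
  }
  gr <- gtv_range(group)
  if (lesion_volume_cm3 < gr[1] || lesion_volume_cm3 > gr[2]) {
    stop(sprintf("lesion_volume_cm3 must lie in [%g, %g] cm^3 for %s",
                 gr[1], gr[2], group))
  }
  if (is.null(grid)) {
    base_spacing <- switch(group, glioma = c(1, 1, 2), metastasis = c(1, 1, 1))
    spacing <- base_spacing * spacing_scale
    extent <- c(200, 200, 180)
    shape <- pmax(round(extent / spacing), 8)
    origin <- -(shape - 1) * spacing / 2
    grid <- grid3d(shape, spacing, origin)
  }
  if (is.null(ptv_margin_mm)) {
    ptv_margin_mm <- matched_ptv_margin(lesion_volume_cm3, group)
  }
  stopifnot(bias_field_amplitude >= 0, bias_field_amplitude < 1,
            noise_sd_ct >= 0, noise_sd_mr >= 0, contrast_enhancement > 0)
  structure(list(group = group, lesion_volume_cm3 = lesion_volume_cm3,
                 grid = grid, ptv_margin_mm = ptv_margin_mm,
                 noise_sd_ct = noise_sd_ct, noise_sd_mr = noise_sd_mr,
                 bias_field_amplitude = bias_field_amplitude,
                 contrast_enhancement = contrast_enhancement,
                 skull_hu_range = skull_hu_range,
                 pv_blur_voxels = pv_blur_voxels,
                 skull_thickness_mm = skull_thickness_mm,
                 hu = hu, mr_means = mr_means, seed = as.integer(seed)),
            class = "phantom_config")
}

#' @rdname phantom_config
#' @param ... passed on to [phantom_config()].
#' @details `noiseless_config()` is the exact-recovery limit: no noise,
#'   no bias field, no contrast enhancement, uniform skull HU and no
#'   partial-volume blur, so the CT is exactly the class-mean lookup of
#'   the labels and the sCT pipeline has a zero-error fixed point.
#' @export
noiseless_config <- function(group = "glioma", ...) {
  phantom_config(group = group, noise_sd_ct = 0, noise_sd_mr = 0,
                 bias_field_amplitude = 0, contrast_enhancement = 1,
                 skull_hu_range = NULL, pv_blur_voxels = 0, ...)
}

# logical array: inside ellipsoid with centre/semi-axes in mm
ellipsoid_array <- function(grid, center, semi) {
  xs <- ((grid_coords(grid, 1) - center[1]) / semi[1])^2
  ys <- ((grid_coords(grid, 2) - center[2]) / semi[2])^2
  zs <- ((grid_coords(grid, 3) - center[3]) / semi[3])^2
  outer(outer(xs, ys, "+"), zs, "+") <= 1
}

# separable Gaussian blur with edge replication, sigma in voxels
gauss_blur3d <- function(arr, sigma_vox) {
  if (all(sigma_vox <= 0)) return(arr)
  for (axis in 1:3) {
    s <- sigma_vox[min(axis, length(sigma_vox))]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    acc <- array(0, dim(arr))
    for (o in seq(-r, r)) {
      acc <- acc + k[o + r + 1] * shift_array(arr, o, axis)
    }
    arr <- acc
  }
  arr
}

# shift with edge replication along one axis
shift_array <- function(arr, offset, axis) {
  n <- dim(arr)[axis]
  idx <- pmin(pmax(seq_len(n) + offset, 1L), n)
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

#' Generate one co-registered CT/MR phantom case
#'
#' Builds the labelled anatomy, simulates the CT (class-mean HU plus an
#' optional continuous skull gradient, partial-volume blur and Gaussian
#' noise) and the MR (class means times a smooth multiplicative bias
#' field plus noise, with the lesion boosted by the contrast-enhancement
#' factor), and attaches BODY/GTV/PTV structures and a beam plan.
#' Deterministic for a fixed config (seeded).
#'
#' @param config a [phantom_config()].
#' @param n_beams,prescription_gy plan parameters passed to [make_plan()].
#' @return An object of class `phantom_case` with elements `labels`
#'   ([label_map()]), `ct`, `mr` ([volume()]s), `structures` (list of
#'   BODY/GTV/PTV [binary_mask()]s), `plan` and `config`.
#' @export
generate_case <- function(config, n_beams = 4, prescription_gy = 30) {
  withr::with_seed(config$seed, generate_case_impl(config, n_beams,
                                                   prescription_gy))
}

generate_case_impl <- function(config, n_beams, prescription_gy) {
  g <- config$grid
  cls <- tissue_classes()
  head_semi <- c(78, 92, 82)
  scalp_th <- 6
  skull_th <- config$skull_thickness_mm
  csf_th <- 4
  gm_th <- 12
  r1 <- head_semi
  r2 <- r1 - scalp_th
  r3 <- r2 - skull_th
  r4 <- r3 - csf_th
  r5 <- r4 - gm_th
  ctr <- c(0, 0, 0)

  labels <- array(cls[["air"]], g$shape)
  labels[ellipsoid_array(g, ctr, r1)] <- cls[["soft"]]
  labels[ellipsoid_array(g, ctr, r2)] <- cls[["bone"]]
  labels[ellipsoid_array(g, ctr, r3)] <- cls[["csf"]]
  labels[ellipsoid_array(g, ctr, r4)] <- cls[["gm"]]
  labels[ellipsoid_array(g, ctr, r5)] <- cls[["wm"]]
  sinus <- ellipsoid_array(g, c(0, 62, -40), c(13, 11, 9)) &
    ellipsoid_array(g, ctr, r1)
  labels[sinus] <- cls[["air"]]

  body <- binary_mask(ellipsoid_array(g, ctr, r1), g)

  # lesion: ellipsoid of the requested volume placed uniformly inside
  # the brain (GM + WM) eroded by its largest semi-axis
  r_eq <- sphere_radius_mm(config$lesion_volume_cm3)
  a1 <- runif(1, 0.8, 1.25)
  a2 <- runif(1, 0.8, 1.25)
  semi <- r_eq * c(a1, a2, 1 / (a1 * a2))
  brain <- binary_mask(labels == cls[["gm"]] | labels == cls[["wm"]], g)
  depth <- distance_from_mask(binary_mask(!brain$member, g))
  candidates <- which(brain$member & depth$values >= max(semi) + max(g$spacing))
  if (length(candidates) == 0) {
    stop(sprintf("lesion of %.1f cm^3 cannot fit inside the brain",
                 config$lesion_volume_cm3))
  }
  pick <- candidates[sample.int(length(candidates), 1)]
  ijk <- arrayInd(pick, g$shape)
  center <- g$origin + (as.numeric(ijk) - 1) * g$spacing
  lesion <- ellipsoid_array(g, center, semi)
  if (!any(lesion)) {  # sub-voxel lesion at coarse spacing
    lesion[pick] <- TRUE
  }
  labels[lesion] <- cls[["gm"]]  # lesion rides in the grey-matter class

  # CT: class-mean HU, optional skull gradient, blur, noise
  ct <- array(unname(config$hu[names(cls)])[match(labels, cls)], g$shape)
  if (!is.null(config$skull_hu_range)) {
    bone_mask_arr <- labels == cls[["bone"]]
    dn <- distance_from_mask(binary_mask(!bone_mask_arr, g))$values
    f <- pmin(dn / (skull_th / 2), 1)
    lohi <- config$skull_hu_range
    ct[bone_mask_arr] <- lohi[2] - (lohi[2] - lohi[1]) * f[bone_mask_arr]
  }
  if (config$pv_blur_voxels > 0) {
    ct <- gauss_blur3d(ct, rep(config$pv_blur_voxels, 3))
  }
  if (config$noise_sd_ct > 0) {
    ct <- ct + rnorm(length(ct), sd = config$noise_sd_ct)
  }
  ct <- pmin(pmax(ct, -1000), 3000)

  # MR: class means x smooth bias field + noise; lesion enhanced
  mr <- array(unname(config$mr_means[names(cls)])[match(labels, cls)],
              g$shape)
  mr[lesion] <- config$mr_means[["gm"]] * config$contrast_enhancement
  if (config$bias_field_amplitude > 0) {
    nx <- grid_coords(g, 1) / max(abs(grid_coords(g, 1)))
    ny <- grid_coords(g, 2) / max(abs(grid_coords(g, 2)))
    nz <- grid_coords(g, 3) / max(abs(grid_coords(g, 3)))
    co <- rnorm(9)
    X <- array(rep(nx, times = prod(g$shape[2:3])), g$shape)
    Y <- aperm(array(rep(ny, times = prod(g$shape[c(1, 3)])),
                     g$shape[c(2, 1, 3)]), c(2, 1, 3))
    Z <- aperm(array(rep(nz, times = prod(g$shape[1:2])),
                     g$shape[c(3, 1, 2)]), c(2, 3, 1))
    f <- co[1] * X + co[2] * Y + co[3] * Z + co[4] * X * Y +
      co[5] * X * Z + co[6] * Y * Z + co[7] * X^2 + co[8] * Y^2 +
      co[9] * Z^2
    f <- f / max(abs(f))
    mr <- mr * (1 + config$bias_field_amplitude * f)
  }
  if (config$noise_sd_mr > 0) {
    mr <- mr + rnorm(length(mr), sd = config$noise_sd_mr)
  }
  mr <- pmax(mr, 0)

  gtv <- binary_mask(lesion, g)
  ptv_member <- distance_from_mask(gtv)$values <= config$ptv_margin_mm &
    body$member
  ptv <- binary_mask(ptv_member, g)

  case <- structure(
    list(labels = label_map(labels, g),
         ct = volume(ct, g, unit = "HU"),
         mr = volume(mr, g, unit = "MR-arbitrary"),
         structures = list(body = body, gtv = gtv, ptv = ptv),
         plan = NULL, config = config),
    class = "phantom_case")
  case$plan <- make_plan(case, n_beams = n_beams,
                         prescription_gy = prescription_gy)
  case
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("phantom_case (%s, seed %d): GTV %.2f cm^3, PTV %.2f cm^3\n",
              x$config$group, x$config$seed,
              mask_volume_cm3(x$structures$gtv),
              mask_volume_cm3(x$structures$ptv)))
  print(x$ct$grid)
  invisible(x)
}

#' Generate a synthetic patient cohort
#'
#' Draws per-case GTV volumes uniformly within the group's clinical
#' range and builds each case with a seed derived from the master seed
#' (`seed * 1000 + case index`). Glioma cases use 2 mm slices and
#' metastasis cases 1 mm slices (times `spacing_scale`).
#'
#' @param n_glioma,n_metastasis group sizes (>= 0).
#' @param seed master seed.
#' @param spacing_scale voxel-spacing multiplier for desk-scale runs.
#' @param ... further arguments to [phantom_config()].
#' @return List of `phantom_case` objects (glioma cases first).
#' @export
generate_cohort <- function(n_glioma, n_metastasis, seed = 1,
                            spacing_scale = 1, ...) {
  stopifnot(n_glioma >= 0, n_metastasis >= 0)
  n <- n_glioma + n_metastasis
  if (n == 0) return(list())
  qs <- withr::with_seed(seed, runif(n))
  groups <- c(rep("glioma", n_glioma), rep("metastasis", n_metastasis))
  lapply(seq_len(n), function(i) {
    gr <- gtv_range(groups[i])
    vol <- gr[1] + qs[i] * diff(gr)
    cfg <- phantom_config(group = groups[i], lesion_volume_cm3 = vol,
                          spacing_scale = spacing_scale,
                          seed = (seed * 1000 + i) %% .Machine$integer.max,
                          ...)
    generate_case(cfg)
  })
}

#' Build an equally weighted coplanar beam plan
#'
#' Beams at evenly spaced gantry angles in the axial plane, aimed at the
#' PTV centroid, with a square field covering the PTV bounding box plus
#' a 5 mm margin on each side.
#'
#' @param case a `phantom_case` (or any list with `structures$ptv`).
#' @param n_beams number of beams (>= 1).
#' @param prescription_gy prescription dose in Gy (PTV median).
#' @param sad_mm source-axis distance (default 1000 mm).
#' @return An object of class `beam_plan`: `prescription_gy` plus a
#'   `beams` data.frame (gantry_deg, sad_mm, iso x/y/z, field_mm, weight).
#' @export
make_plan <- function(case, n_beams = 4, prescription_gy = 30,
                      sad_mm = 1000) {
  stopifnot(n_beams >= 1)
  ptv <- case$structures$ptv
  if (!any(ptv$member)) stop("empty PTV")
  g <- ptv$grid
  idx <- which(ptv$member, arr.ind = TRUE)
  world <- sweep(sweep(idx - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  iso <- colMeans(world)
  # snap to the nearest PTV voxel so the isocentre lies inside the PTV
  d2 <- rowSums(sweep(world, 2, iso)^2)
  iso <- unname(world[which.min(d2), ])
  bbox <- apply(world, 2, range)
  field <- max(bbox[2, ] - bbox[1, ] + g$spacing) + 2 * 5
  angles <- seq(0, 360, length.out = n_beams + 1)[seq_len(n_beams)]
  beams <- data.frame(
    gantry_deg = angles,
    sad_mm = sad_mm,
    iso_x = iso[1], iso_y = iso[2], iso_z = iso[3],
    field_mm = field,
    weight = 1 / n_beams)
  structure(list(prescription_gy = prescription_gy, beams = beams),
            class = "beam_plan")
}

#' @export
print.beam_plan <- function(x, ...) {
  cat(sprintf("beam_plan: %d beam(s), prescription %.1f Gy, field %.0f mm\n",
              nrow(x$beams), x$prescription_gy, x$beams$field_mm[1]))
  invisible(x)
}
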