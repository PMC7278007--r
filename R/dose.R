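#' HU to relative electron density calibration
#'
#' Piecewise-linear calibration curve, clamped at the end knots. The
#' default anchors air (-1000 HU -> 0.001), water (0 HU -> 1.000),
#' cortical bone (942 HU -> 1.512) and the scanner ceiling
#' (3071 HU -> 2.2).
#'
#' @param hu,density knot vectors; `hu` strictly increasing, `density`
#'   non-negative and non-decreasing.
#' @return An object of class `density_calibration`.
#' @export
density_calibration <- function(hu = c(-1000, 0, 942, 3071),
                                density = c(0.001, 1.0, 1.512, 2.2)) {
  stopifnot(length(hu) == length(density), length(hu) >= 2)
  if (any(diff(hu) <= 0)) stop("HU knots must be strictly increasing")
  if (any(density < 0) || any(diff(density) < 0)) {
    stop("densities must be non-negative and non-decreasing")
  }
  structure(list(hu = hu, density = density),
            class = "density_calibration")
}

#' Convert a HU volume to relative electron density
#'
#' @param vol HU [volume()].
#' @param cal a [density_calibration()].
#' @return [volume()] with unit "density".
#' @export
hu_to_density <- function(vol, cal = density_calibration()) {
  if (vol$unit != "HU") stop("hu_to_density expects a HU volume")
  d <- approx(cal$hu, cal$density, xout = as.numeric(vol$values),
              rule = 2)$y
  dim(d) <- vol$grid$shape
  volume(d, vol$grid, unit = "density")
}

#' Radiological depth along a ray
#'
#' Exact line integral of the density volume along the segment from
#' `source_mm` to `target_mm` (Siddon-style voxel traversal), in
#' density x mm (water-equivalent mm for relative densities).
#'
#' @param density [volume()] with unit "density".
#' @param source_mm,target_mm world points (mm).
#' @return Scalar line integral; 0 for a zero-length ray.
#' @export
radiological_depth <- function(density, source_mm, target_mm) {
  stopifnot(all(is.finite(source_mm)), all(is.finite(target_mm)))
  .ray_integral_cpp(as.numeric(density$values), density$grid$shape,
                    density$grid$spacing, density$grid$origin,
                    as.numeric(source_mm), as.numeric(target_mm))
}

#' Compute dose for a beam plan on a density volume
#'
#' Simplified 6 MV photon engine: for each beam, dose at voxel v is
#' `weight * exp(-mu_eff * d_rad(v)) * (SAD / r(v))^2 * penumbra(v)`,
#' with the radiological depth d_rad from the source to the voxel, the
#' inverse-square distance factor, and an error-function lateral
#' penumbra (sigma at the field edge, projected to the isocentre
#' plane). No buildup or scatter modelling. Dose is zero outside BODY.
#'
#' Normalisation: when `ptv` is given the output is scaled so its PTV
#' median equals `plan$prescription_gy`; when `norm_constant` is given
#' that scale is reused instead (plan copying onto another attenuation
#' volume). With neither, the raw engine output is returned.
#'
#' @param density [volume()] with unit "density".
#' @param plan a `beam_plan` from [make_plan()].
#' @param body BODY [binary_mask()] on the density grid.
#' @param ptv optional PTV [binary_mask()] for prescription scaling.
#' @param norm_constant optional fixed normalisation constant.
#' @param mu_eff effective linear attenuation, mm^-1 water-equivalent
#'   (default 0.0049 for 6 MV).
#' @param sigma_penumbra lateral penumbra sigma in mm (default 3).
#' @return [volume()] with unit "Gy" and attribute `norm_constant`.
#' @export
compute_dose <- function(density, plan, body, ptv = NULL,
                         norm_constant = NULL, mu_eff = 0.0049,
                         sigma_penumbra = 3) {
  stopifnot(inherits(plan, "beam_plan"))
  if (!grids_equal(density$grid, body$grid)) stop("grid mismatch")
  b <- plan$beams
  th <- b$gantry_deg * pi / 180
  src <- cbind(b$iso_x + b$sad_mm * sin(th),
               b$iso_y + b$sad_mm * cos(th),
               b$iso_z)
  beams <- cbind(src, b$iso_x, b$iso_y, b$iso_z, b$sad_mm, b$field_mm,
                 b$weight)
  if (any(b$field_mm <= 0)) stop("empty field")
  raw <- .compute_dose_cpp(as.numeric(density$values), density$grid$shape,
                           density$grid$spacing, density$grid$origin,
                           as.logical(body$member), beams,
                           mu_eff, sigma_penumbra)
  dim(raw) <- density$grid$shape
  scale <- 1
  if (!is.null(norm_constant)) {
    scale <- norm_constant
  } else if (!is.null(ptv)) {
    med <- median(raw[ptv$member])
    if (med <= 0) stop("no dose delivered to PTV; cannot normalise")
    scale <- plan$prescription_gy / med
  }
  out <- volume(raw * scale, density$grid, unit = "Gy")
  attr(out, "norm_constant") <- scale
  out
}

#' Recalculate a CT-based plan on the sCT (plan copy)
#'
#' Computes the CT-based dose normalised to the prescription at the PTV
#' median, then recomputes the identical plan on the sCT attenuation
#' data reusing the same normalisation constant, so any dose difference
#' reflects the attenuation data alone.
#'
#' @param ct,sct HU [volume()]s on the same reference grid.
#' @param plan a `beam_plan`.
#' @param body,ptv structure masks.
#' @param cal a [density_calibration()].
#' @param ... engine parameters passed to [compute_dose()].
#' @return List with `d_ct` and `d_sct` dose [volume()]s.
#' @export
recalculate_on_sct <- function(ct, sct, plan, body, ptv,
                               cal = density_calibration(), ...) {
  if (!grids_equal(ct$grid, sct$grid)) {
    stop("ct and sct must share a reference grid")
  }
  d_ct <- compute_dose(hu_to_density(ct, cal), plan, body, ptv = ptv, ...)
  d_sct <- compute_dose(hu_to_density(sct, cal), plan, body,
                        norm_constant = attr(d_ct, "norm_constant"), ...)
  list(d_ct = d_ct, d_sct = d_sct)
}
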