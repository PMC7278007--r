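#' Threshold a HU volume into a bone mask
#'
#' Voxels strictly above `threshold_hu` (default 300 HU) are bone, the
#' standard skull threshold for CT/sCT segmentation comparison. On a
#' piecewise-constant sCT only the 942 HU cortical-bone class exceeds
#' it, so the mask equals the bone class mask exactly.
#'
#' @param vol a [volume()] with unit "HU".
#' @param threshold_hu threshold (exceedance is strict).
#' @return A [binary_mask()].
#' @export
bone_mask <- function(vol, threshold_hu = 300) {
  if (vol$unit != "HU") stop("bone_mask expects a HU volume")
  binary_mask(vol$values > threshold_hu, vol$grid)
}

#' Dice similarity coefficient of two masks
#'
#' DSC = 2|A intersect B| / (|A| + |B|); 1 when both masks are empty.
#'
#' @param a,b [binary_mask()]s on the same grid.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!grids_equal(a$grid, b$grid)) stop("grid mismatch between masks")
  na <- sum(a$member)
  nb <- sum(b$member)
  if (na + nb == 0) return(1.0)
  2 * sum(a$member & b$member) / (na + nb)
}

#' Bone volume and per-slice voxel counts
#'
#' Counts member voxels per axial slice and converts the total to cm^3
#' via the voxel volume.
#'
#' @param mask a [binary_mask()].
#' @return List with `total_cm3` and integer `per_slice_counts` (one
#'   entry per axial slice).
#' @export
bone_volume <- function(mask) {
  counts <- apply(mask$member, 3, sum)
  list(total_cm3 = sum(counts) * voxel_volume_mm3(mask$grid) / 1000,
       per_slice_counts = as.integer(counts))
}

#' Relative volume difference in percent
#'
#' 100 x (V_sCT - V_CT) / V_CT; negative when the sCT underestimates.
#'
#' @param v_sct,v_ct volumes in cm^3; `v_ct` must be > 0.
#' @return Percentage.
#' @export
relative_volume_difference <- function(v_sct, v_ct) {
  if (v_ct <= 0) stop("v_ct must be > 0")
  100 * (v_sct - v_ct) / v_ct
}

#' Mean absolute HU error over a region
#'
#' @param ct,sct HU [volume()]s on the same grid.
#' @param region nonempty [binary_mask()] on the same grid.
#' @return Mean of |CT - sCT| over region voxels, in HU.
#' @export
mae_hu <- function(ct, sct, region) {
  if (!grids_equal(ct$grid, sct$grid) ||
      !grids_equal(ct$grid, region$grid)) {
    stop("grid mismatch")
  }
  if (!any(region$member)) stop("empty region")
  mean(abs(ct$values[region$member] - sct$values[region$member]))
}

#' Crown-to-cranial-base evaluation region
#'
#' The BODY mask restricted to axial slices from the superior-most BODY
#' slice down through a fraction of the head height (+z superior). Used
#' as the MAE evaluation region; no anatomical landmark detection is
#' attempted.
#'
#' @param body BODY [binary_mask()].
#' @param fraction kept fraction of head height from the crown
#'   (default 0.55).
#' @return A [binary_mask()].
#' @export
crown_region <- function(body, fraction = 0.55) {
  has <- apply(body$member, 3, any)
  if (!any(has)) stop("empty body mask")
  zmax <- max(which(has))
  zmin <- min(which(has))
  height <- zmax - zmin + 1
  zcut <- zmax - ceiling(fraction * height) + 1
  keep <- array(FALSE, body$grid$shape)
  keep[, , max(zcut, zmin):zmax] <- TRUE
  binary_mask(body$member & keep, body$grid)
}

#' Bone segmentation and HU agreement report for one case
#'
#' Bone masks at the 300 HU threshold on CT and sCT, their volumes,
#' relative volume difference, whole-skull DSC, and MAE over the
#' crown-to-cranial-base part of the BODY.
#'
#' @param ct,sct HU [volume()]s on one grid.
#' @param body BODY [binary_mask()].
#' @param threshold_hu bone threshold.
#' @param crown_fraction MAE region height fraction.
#' @return One-row data.frame: v_ct_cm3, v_sct_cm3, dv_pct, dsc, mae_hu.
#' @export
bone_report <- function(ct, sct, body, threshold_hu = 300,
                        crown_fraction = 0.55) {
  m_ct <- bone_mask(ct, threshold_hu)
  m_sct <- bone_mask(sct, threshold_hu)
  v_ct <- bone_volume(m_ct)$total_cm3
  v_sct <- bone_volume(m_sct)$total_cm3
  data.frame(
    v_ct_cm3 = v_ct,
    v_sct_cm3 = v_sct,
    dv_pct = if (v_ct > 0) relative_volume_difference(v_sct, v_ct) else NA_real_,
    dsc = dice(m_sct, m_ct),
    mae_hu = mae_hu(ct, sct, crown_region(body, crown_fraction)))
}
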