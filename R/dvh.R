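#' Ring of tissue around the PTV (the OAR surrogate)
#'
#' Voxels whose distance from the PTV is in (0, `distance_mm`\],
#' intersected with BODY and excluding the PTV itself: the shell of
#' normal tissue within 2 cm of the PTV outer edge.
#'
#' @param ptv nonempty PTV [binary_mask()].
#' @param body BODY [binary_mask()] on the same grid.
#' @param distance_mm shell thickness (default 20 mm).
#' @return A [binary_mask()].
#' @export
oar_ring <- function(ptv, body, distance_mm = 20) {
  if (!any(ptv$member)) stop("empty ptv")
  if (!grids_equal(ptv$grid, body$grid)) stop("grid mismatch")
  d <- distance_from_mask(ptv)$values
  binary_mask(d > 0 & d <= distance_mm & body$member, ptv$grid)
}

#' Cumulative DVH of a structure
#'
#' Exact empirical cumulative curve from the sorted member-voxel doses
#' (no binning): V(D) is the fraction of the structure receiving at
#' least D.
#'
#' @param dose dose [volume()] (unit "Gy").
#' @param mask nonempty structure [binary_mask()] on the same grid.
#' @param name structure name.
#' @return An object of class `dvh_curve`: `name`, `doses` (sorted
#'   decreasing), `voxel_volume_cm3`, and `V`, the cumulative
#'   volume-fraction function.
#' @export
cumulative_dvh <- function(dose, mask, name = "structure") {
  if (!grids_equal(dose$grid, mask$grid)) stop("grid mismatch")
  if (!any(mask$member)) stop("empty structure mask")
  doses <- sort(dose$values[mask$member], decreasing = TRUE)
  structure(list(
    name = name,
    doses = doses,
    voxel_volume_cm3 = voxel_volume_mm3(dose$grid) / 1000,
    V = function(D) vapply(D, function(d) mean(doses >= d), numeric(1))),
    class = "dvh_curve")
}

#' ICRU-83 style DVH parameters
#'
#' D_max is the maximum voxel dose; D_X\% is the minimum dose received
#' by the hottest X\% of the structure volume (linear interpolation
#' between voxel order statistics, i.e. the (1 - X/100) dose quantile);
#' D_0.1cc is the minimum dose of the hottest 0.1 cm^3 (the
#' ceil(0.1 / voxel volume)-th hottest voxel); D_mean is the arithmetic
#' mean. For structures smaller than 0.1 cm^3, D_0.1cc falls back to
#' D_max with a warning.
#'
#' @param curve a `dvh_curve`.
#' @return Named numeric vector: d_max, d_0.1cc, d_2pct, d_50pct,
#'   d_95pct, d_98pct, d_mean (Gy).
#' @export
dvh_parameters <- function(curve) {
  d <- curve$doses  # sorted decreasing
  n <- length(d)
  vox <- curve$voxel_volume_cm3
  d_hot_pct <- function(x) {
    unname(quantile(d, probs = 1 - x / 100, names = FALSE, type = 7))
  }
  if (n * vox < 0.1) {
    warning(sprintf(
      "structure '%s' smaller than 0.1 cm^3; D_0.1cc reported as D_max",
      curve$name))
    d01cc <- d[1]
  } else {
    d01cc <- d[ceiling(0.1 / vox)]
  }
  c(d_max = d[1],
    d_0.1cc = d01cc,
    d_2pct = d_hot_pct(2),
    d_50pct = d_hot_pct(50),
    d_95pct = d_hot_pct(95),
    d_98pct = d_hot_pct(98),
    d_mean = mean(d))
}

#' Relative dose difference in percent
#'
#' 100 x (D_sCT - D_CT) / D_CT for a DVH parameter value.
#'
#' @param d_sct,d_ct doses in Gy; `d_ct` must be > 0.
#' @return Percentage.
#' @export
relative_difference <- function(d_sct, d_ct) {
  if (any(d_ct <= 0)) stop("d_ct must be > 0")
  100 * (d_sct - d_ct) / d_ct
}

#' Per-structure DVH comparison table
#'
#' DVH parameters of the CT- and sCT-based doses for each structure and
#' their relative differences.
#'
#' @param d_ct,d_sct dose [volume()]s on one grid.
#' @param structures named list of [binary_mask()]s.
#' @return data.frame with columns structure, parameter, d_ct, d_sct,
#'   delta_pct.
#' @export
dvh_comparison <- function(d_ct, d_sct, structures) {
  rows <- lapply(names(structures), function(s) {
    p_ct <- dvh_parameters(cumulative_dvh(d_ct, structures[[s]], s))
    p_sct <- dvh_parameters(cumulative_dvh(d_sct, structures[[s]], s))
    data.frame(structure = s, parameter = names(p_ct),
               d_ct = unname(p_ct), d_sct = unname(p_sct),
               delta_pct = relative_difference(unname(p_sct),
                                               unname(p_ct)))
  })
  do.call(rbind, rows)
}
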