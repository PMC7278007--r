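#' Gamma analysis criteria
#'
#' Global gamma criteria: dose-difference percentage (of the maximum
#' reference dose), distance-to-agreement in mm, low-dose threshold as
#' a fraction of the maximum reference dose (voxels at or below it are
#' not evaluated), the gamma cap, and the search step as a fraction of
#' the DTA.
#'
#' @param dose_diff_pct dose criterion in percent (2 or 1 in routine use).
#' @param dta_mm distance-to-agreement in mm.
#' @param low_dose_threshold evaluation threshold fraction (default 0.10).
#' @param cap maximum reported gamma (default 2).
#' @param step_frac search-lattice step as a fraction of DTA
#'   (default 0.1).
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_diff_pct = 2, dta_mm = 2,
                           low_dose_threshold = 0.10, cap = 2,
                           step_frac = 0.1) {
  stopifnot(dose_diff_pct > 0, dta_mm > 0, low_dose_threshold > 0,
            cap >= 1, step_frac > 0)
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 low_dose_threshold = low_dose_threshold, cap = cap,
                 step_frac = step_frac, normalization = "global-max-reference"),
            class = "gamma_criteria")
}

#' Global 3D gamma index map
#'
#' For each reference voxel above the low-dose threshold, the gamma
#' index is the minimum over evaluated positions e of
#' sqrt((|e - r| / dta)^2 + ((D_e(e) - D_r(r)) / (dd% x max D_r))^2),
#' searched on a lattice of step `step_frac * dta` out to radius
#' `cap * dta` with trilinearly interpolated evaluated dose, then capped
#' at `cap`. Normalisation is global: the maximum of the reference
#' (CT-based) dose.
#'
#' @param reference,evaluated dose [volume()]s on the same grid
#'   (resample first if needed); reference is the CT-based plan.
#' @param crit a [gamma_criteria()].
#' @return An object of class `gamma_result`: `gamma` [volume()] (NA
#'   outside the evaluated region), `evaluated_mask` [binary_mask()],
#'   `pass_rate_pct`, and the criteria used.
#' @export
gamma_map <- function(reference, evaluated, crit = gamma_criteria()) {
  if (!grids_equal(reference$grid, evaluated$grid)) {
    stop("reference and evaluated doses must share a grid")
  }
  g <- reference$grid
  max_ref <- max(reference$values)
  if (max_ref <= 0) stop("no evaluable voxels: reference dose is all zero")
  dcrit <- crit$dose_diff_pct / 100 * max_ref
  thr <- crit$low_dose_threshold * max_ref
  mask <- reference$values > thr
  if (!any(mask)) stop("no evaluable voxels above the dose threshold")
  gam <- .gamma_map_cpp(as.numeric(reference$values),
                        as.numeric(evaluated$values),
                        g$shape, g$spacing, dcrit, crit$dta_mm, thr,
                        crit$cap, crit$step_frac * crit$dta_mm)
  dim(gam) <- g$shape
  gam_vol <- gam
  gam_vol[is.na(gam_vol)] <- 0  # outside evaluated region
  res <- structure(list(
    gamma = volume(gam_vol, g, unit = "gamma"),
    gamma_raw = gam,
    evaluated_mask = binary_mask(mask, g),
    criteria = crit), class = "gamma_result")
  res$pass_rate_pct <- gamma_pass_rate(res)
  res
}

#' Gamma pass rate in percent
#'
#' 100 x fraction of evaluated voxels (reference dose above threshold)
#' with gamma <= 1.
#'
#' @param result a `gamma_result`.
#' @return Percentage in \[0, 100\].
#' @export
gamma_pass_rate <- function(result) {
  gam <- result$gamma_raw[result$evaluated_mask$member]
  if (length(gam) == 0) stop("evaluated mask is empty")
  100 * mean(gam <= 1)
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "gamma_result: %g%%/%g mm, threshold %g x max(ref), cap %g -> pass %.1f%% (%d voxels)\n",
    x$criteria$dose_diff_pct, x$criteria$dta_mm,
    x$criteria$low_dose_threshold, x$criteria$cap, x$pass_rate_pct,
    sum(x$evaluated_mask$member)))
  invisible(x)
}

#' Brute-force gamma oracle (small grids)
#'
#' Independent reference implementation used to validate [gamma_map()]:
#' plain R, own trilinear interpolation, exhaustive offset lattice at a
#' fine step. The only search reductions are mathematically exact:
#' offsets beyond `cap * dta` cannot beat the cap, and offsets whose
#' pure distance term exceeds the zero-offset gamma cannot beat it
#' either. Intended for grids of about 16^3-30^3.
#'
#' @param reference,evaluated dose [volume()]s on one grid.
#' @param crit a [gamma_criteria()].
#' @param step_mm lattice step in mm (default 0.1 mm, finer than the
#'   fast path's dta/10 so the two searches use different lattices).
#' @return A `gamma_result` (without the fast path's step subsampling).
#' @export
gamma_brute_force <- function(reference, evaluated,
                              crit = gamma_criteria(), step_mm = 0.1) {
  if (!grids_equal(reference$grid, evaluated$grid)) {
    stop("reference and evaluated doses must share a grid")
  }
  g <- reference$grid
  if (prod(g$shape) > 32^3) {
    stop("gamma_brute_force is an oracle for small grids (<= ~30^3)")
  }
  max_ref <- max(reference$values)
  if (max_ref <= 0) stop("no evaluable voxels: reference dose is all zero")
  dcrit <- crit$dose_diff_pct / 100 * max_ref
  dta <- crit$dta_mm
  thr <- crit$low_dose_threshold * max_ref
  mask <- reference$values > thr
  if (!any(mask)) stop("no evaluable voxels above the dose threshold")

  radius <- crit$cap * dta
  m <- floor(radius / step_mm)
  off1 <- seq(-m, m) * step_mm
  offs <- expand.grid(dx = off1, dy = off1, dz = off1)
  rr <- sqrt(offs$dx^2 + offs$dy^2 + offs$dz^2)
  keep <- rr <= radius
  offs <- offs[keep, ]
  r2n_all <- (rr[keep] / dta)^2

  ev <- as.numeric(evaluated$values)
  nx <- g$shape[1]; ny <- g$shape[2]; nz <- g$shape[3]
  interp <- function(cx, cy, cz) {
    ok <- cx >= 0 & cy >= 0 & cz >= 0 & cx <= nx - 1 & cy <= ny - 1 &
      cz <= nz - 1
    out <- rep(NA_real_, length(cx))
    if (!any(ok)) return(out)
    cx <- cx[ok]; cy <- cy[ok]; cz <- cz[ok]
    x0 <- pmin(pmax(floor(cx), 0), nx - 2)
    y0 <- pmin(pmax(floor(cy), 0), ny - 2)
    z0 <- pmin(pmax(floor(cz), 0), nz - 2)
    fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
    at <- function(i, j, k) ev[1 + i + nx * (j + ny * k)]
    c00 <- at(x0, y0, z0) * (1 - fx) + at(x0 + 1, y0, z0) * fx
    c10 <- at(x0, y0 + 1, z0) * (1 - fx) + at(x0 + 1, y0 + 1, z0) * fx
    c01 <- at(x0, y0, z0 + 1) * (1 - fx) + at(x0 + 1, y0, z0 + 1) * fx
    c11 <- at(x0, y0 + 1, z0 + 1) * (1 - fx) + at(x0 + 1, y0 + 1, z0 + 1) * fx
    out[ok] <- (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
      (c01 * (1 - fy) + c11 * fy) * fz
    out
  }

  # offsets grouped into radial shells; within each voxel the shells are
  # scanned outward and the scan stops once the pure distance term of
  # the next shell cannot beat the best gamma so far (exact pruning)
  ord <- order(r2n_all)
  offs <- offs[ord, ]
  r2n_all <- r2n_all[ord]
  shell_w <- 0.25  # mm
  shell_id <- floor(sqrt(r2n_all) * dta / shell_w)
  shells <- split(seq_along(r2n_all), shell_id)
  shell_min_r2n <- vapply(shells, function(ii) r2n_all[ii[1]], numeric(1))

  gam <- array(NA_real_, g$shape)
  idx_eval <- which(mask)
  ijk <- arrayInd(idx_eval, g$shape)
  for (t in seq_along(idx_eval)) {
    i <- ijk[t, 1] - 1; j <- ijk[t, 2] - 1; k <- ijk[t, 3] - 1
    Dr <- reference$values[idx_eval[t]]
    best2 <- min((abs(ev[idx_eval[t]] - Dr) / dcrit)^2, crit$cap^2)
    for (s in seq_along(shells)) {
      if (shell_min_r2n[s] >= best2) break
      sel <- shells[[s]]
      De <- interp(i + offs$dx[sel] / g$spacing[1],
                   j + offs$dy[sel] / g$spacing[2],
                   k + offs$dz[sel] / g$spacing[3])
      g2 <- r2n_all[sel] + ((De - Dr) / dcrit)^2
      m2 <- suppressWarnings(min(g2, na.rm = TRUE))
      if (is.finite(m2) && m2 < best2) best2 <- m2
    }
    gam[idx_eval[t]] <- min(sqrt(best2), crit$cap)
  }
  gam_vol <- gam
  gam_vol[is.na(gam_vol)] <- 0
  res <- structure(list(
    gamma = volume(gam_vol, g, unit = "gamma"),
    gamma_raw = gam,
    evaluated_mask = binary_mask(mask, g),
    criteria = crit), class = "gamma_result")
  res$pass_rate_pct <- gamma_pass_rate(res)
  res
}
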