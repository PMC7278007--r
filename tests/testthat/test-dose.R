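test_that("HU to density calibration interpolates and clamps", {
  cal <- density_calibration()
  g <- grid3d(c(2, 2, 2), c(1, 1, 1))
  v <- volume(array(c(0, -1000, 471, 942, 3071, 2000, -1000, 0),
                    c(2, 2, 2)), g, unit = "HU")
  d <- hu_to_density(v, cal)
  expect_equal(d$values[1], 1.000)
  expect_equal(d$values[2], 0.001)
  expect_equal(d$values[3], (1.000 + 1.512) / 2)  # midpoint of 0..942
  expect_equal(d$values[4], 1.512)
  expect_equal(d$values[5], 2.2)
  expect_error(density_calibration(hu = c(0, 0), density = c(1, 1)),
               "strictly increasing")
  expect_error(density_calibration(hu = c(0, 1), density = c(1, 0.5)),
               "non-decreasing")
})

test_that("radiological depth is exact for homogeneous and empty media", {
  g <- grid3d(c(60, 30, 30), c(2, 2, 2), c(0, 0, 0))
  water <- volume(array(1, g$shape), g, unit = "density")
  # 100 mm segment fully inside the volume (x extent is [-1, 119] mm)
  expect_equal(radiological_depth(water, c(5, 30, 30), c(105, 30, 30)),
               100, tolerance = 1e-9)
  void <- volume(array(0, g$shape), g, unit = "density")
  expect_equal(radiological_depth(void, c(5, 30, 30), c(105, 30, 30)), 0)
  expect_equal(radiological_depth(water, c(5, 5, 5), c(5, 5, 5)), 0)
})

test_that("Siddon traversal agrees with dense quadrature on random media", {
  g <- grid3d(c(20, 20, 20), c(1.5, 2, 2.5), c(0, 0, 0))
  set.seed(8)
  dens <- volume(array(runif(8000, 0.5, 1.5), g$shape), g, unit = "density")
  for (i in 1:3) {
    src <- runif(3, 2, 8)
    dst <- runif(3, 25, 40)
    si <- radiological_depth(dens, src, dst)
    ts <- seq(0, 1, length.out = 40001)
    pts <- cbind(src[1] + ts * (dst[1] - src[1]),
                 src[2] + ts * (dst[2] - src[2]),
                 src[3] + ts * (dst[3] - src[3]))
    idx <- cbind(round(pts[, 1] / 1.5), round(pts[, 2] / 2),
                 round(pts[, 3] / 2.5)) + 1
    ok <- idx[, 1] >= 1 & idx[, 1] <= 20 & idx[, 2] >= 1 &
      idx[, 2] <= 20 & idx[, 3] >= 1 & idx[, 3] <= 20
    vals <- numeric(nrow(idx))
    vals[ok] <- dens$values[idx[ok, , drop = FALSE]]
    quad <- sum(vals) * sqrt(sum((dst - src)^2)) / (length(ts) - 1)
    expect_lt(abs(si - quad) / quad, 0.005)
  }
})

water_slab <- function() {
  g <- grid3d(c(41, 81, 41), c(2, 2, 2), c(-40, -80, -40))
  ptvm <- array(FALSE, g$shape)
  ptvm[19:23, 39:43, 19:23] <- TRUE
  list(g = g,
       dens = volume(array(1, g$shape), g, unit = "density"),
       body = binary_mask(array(TRUE, g$shape), g),
       case = list(structures = list(ptv = binary_mask(ptvm, g))))
}

test_that("central-axis falloff matches exp(-mu z) / r^2 within 1 percent", {
  w <- water_slab()
  plan <- make_plan(w$case, n_beams = 1, prescription_gy = 30)
  d <- compute_dose(w$dens, plan, w$body)
  ix <- which.min(abs(grid_coords(w$g, 1) - plan$beams$iso_x[1]))
  iz <- which.min(abs(grid_coords(w$g, 3) - plan$beams$iso_z[1]))
  y <- grid_coords(w$g, 2)
  cax <- d$values[ix, , iz]
  src_y <- plan$beams$iso_y[1] + plan$beams$sad_mm[1]
  depth <- (max(y) + 1) - y
  sel <- depth > 6 & depth < 150
  model <- exp(-0.0049 * depth[sel]) * (plan$beams$sad_mm[1] /
                                          (src_y - y[sel]))^2
  ratio <- cax[sel] / model
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.01)
  # monotone non-increasing with depth beyond the entrance (the source
  # sits at +y, so increasing depth means decreasing y index)
  expect_true(all(diff(rev(cax[sel])) <= 1e-12))
})

test_that("dose is deterministic, weight-normalisation invariant and linear", {
  w <- water_slab()
  plan <- make_plan(w$case, n_beams = 2, prescription_gy = 30)
  d1 <- compute_dose(w$dens, plan, w$body)
  d2 <- compute_dose(w$dens, plan, w$body)
  expect_identical(d1$values, d2$values)
  # doubling all weights then renormalising to sum 1 changes nothing
  plan2 <- plan
  plan2$beams$weight <- 2 * plan$beams$weight
  plan2$beams$weight <- plan2$beams$weight / sum(plan2$beams$weight)
  expect_equal(compute_dose(w$dens, plan2, w$body)$values, d1$values)
  # two-beam dose is the weighted sum of single beams
  b1 <- plan; b1$beams <- plan$beams[1, ]; b1$beams$weight <- 1
  b2 <- plan; b2$beams <- plan$beams[2, ]; b2$beams$weight <- 1
  da <- compute_dose(w$dens, b1, w$body)
  db <- compute_dose(w$dens, b2, w$body)
  expect_equal(d1$values, 0.5 * da$values + 0.5 * db$values,
               tolerance = 1e-12)
})

test_that("replacing bone with soft tissue raises the distal dose", {
  w <- water_slab()
  cal <- density_calibration()
  hu_bone <- array(0, w$g$shape)
  hu_bone[, 55:60, ] <- 942  # bone slab between source (at +y) and target
  ct_bone <- volume(hu_bone, w$g, unit = "HU")
  ct_soft <- volume(array(0, w$g$shape), w$g, unit = "HU")
  plan <- make_plan(w$case, n_beams = 1, prescription_gy = 30)
  d_bone <- compute_dose(hu_to_density(ct_bone, cal), plan, w$body)
  d_soft <- compute_dose(hu_to_density(ct_soft, cal), plan, w$body)
  ix <- 21; iz <- 21
  distal <- 1:50  # y indices beyond the slab, away from the source
  expect_true(all(d_soft$values[ix, distal, iz] >
                    d_bone$values[ix, distal, iz]))
})

test_that("plan copying reuses the CT normalisation on the sCT", {
  case <- noiseless_case()
  doses <- recalculate_on_sct(case$ct, case$ct, case$plan,
                              case$structures$body, case$structures$ptv)
  expect_identical(doses$d_ct$values, doses$d_sct$values)
  expect_equal(median(doses$d_ct$values[case$structures$ptv$member]),
               case$plan$prescription_gy, tolerance = 1e-9)
  expect_equal(attr(doses$d_ct, "norm_constant"),
               attr(doses$d_sct, "norm_constant"))
  expect_true(all(doses$d_ct$values[!case$structures$body$member] == 0))
})
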