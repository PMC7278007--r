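test_that("the OAR ring is the 2 cm shell and matches a brute-force scan", {
  g <- grid3d(c(45, 45, 45), c(1, 1, 1), c(0, 0, 0))
  ptvm <- array(FALSE, g$shape)
  ptvm[23, 23, 23] <- TRUE
  ptv <- binary_mask(ptvm, g)
  body <- binary_mask(array(TRUE, g$shape), g)
  ring <- oar_ring(ptv, body, 20)
  # brute force: all voxels with 0 < euclidean distance <= 20 mm
  co <- as.matrix(expand.grid(x = grid_coords(g, 1), y = grid_coords(g, 2),
                              z = grid_coords(g, 3)))
  dd <- sqrt(colSums((t(co) - c(22, 22, 22))^2))
  expect_equal(sum(ring$member), sum(dd > 0 & dd <= 20))
  expect_false(any(ring$member & ptv$member))
  expect_true(all(body$member[ring$member]))
  expect_false(any(oar_ring(ptv, body, 0)$member))
  expect_error(oar_ring(binary_mask(array(FALSE, g$shape), g), body),
               "empty ptv")
})

test_that("cumulative DVH is the exact empirical curve", {
  g <- grid3d(c(4, 4, 4), c(5, 5, 5))
  m <- array(FALSE, g$shape); m[1:2, 1, 1] <- TRUE
  dose <- volume(array(0, g$shape), g, unit = "Gy")
  dose$values[1, 1, 1] <- 1; dose$values[2, 1, 1] <- 3
  curve <- cumulative_dvh(dose, binary_mask(m, g))
  expect_equal(curve$V(2), 0.5)
  expect_equal(curve$V(0), 1)
  expect_equal(curve$V(3.5), 0)
  u <- volume(array(2, g$shape), g, unit = "Gy")
  cu <- cumulative_dvh(u, binary_mask(m, g))
  expect_equal(cu$V(1.99), 1)
  expect_equal(cu$V(2.01), 0)
  # area under V(D) equals the mean dose (numerical quadrature)
  set.seed(9)
  dr <- volume(array(runif(64, 0, 10), g$shape), g, unit = "Gy")
  mk <- binary_mask(array(TRUE, g$shape), g)
  cr <- cumulative_dvh(dr, mk)
  Ds <- seq(0, 10.001, by = 0.0005)
  area <- sum(cr$V(Ds)) * 0.0005
  expect_equal(area, mean(dr$values), tolerance = 1e-3)
})

test_that("DVH parameters match the order-statistic oracle on a ramp", {
  g <- grid3d(c(10, 10, 10), c(2, 2, 2.5))  # 0.01 cm^3 voxels
  dose <- volume(array(seq(0.001, 1, by = 0.001), g$shape), g, unit = "Gy")
  mask <- binary_mask(array(TRUE, g$shape), g)
  p <- dvh_parameters(cumulative_dvh(dose, mask))
  expect_equal(unname(p["d_max"]), 1.000)
  # hottest 0.1 cm^3 = 10 voxels -> 10th largest dose
  expect_equal(unname(p["d_0.1cc"]), 0.991)
  # interpolated order statistics, frozen from the closed form:
  # h = (n-1)(1-X/100)+1 over sorted ascending doses 0.001..1.000
  expect_equal(unname(p["d_50pct"]), 0.5005)
  expect_equal(unname(p["d_98pct"]), 0.02098, tolerance = 1e-9)
  expect_equal(unname(p["d_2pct"]), 0.98002, tolerance = 1e-9)
  expect_equal(unname(p["d_mean"]), mean(dose$values))
})

test_that("uniform dose collapses every DVH parameter to that dose", {
  g <- grid3d(c(8, 8, 8), c(2, 2, 2))
  dose <- volume(array(2, g$shape), g, unit = "Gy")
  mask <- binary_mask(array(TRUE, g$shape), g)
  p <- dvh_parameters(cumulative_dvh(dose, mask))
  expect_true(all(abs(p - 2) < 1e-12))
})

test_that("parameter ordering and voxel-order invariance hold", {
  # structure larger than 5 cm^3 so that the hottest 0.1 cm^3 is a
  # smaller (hence hotter) subvolume than the hottest 2%
  g <- grid3d(c(10, 10, 10), c(2, 2, 2.5))
  mask <- binary_mask(array(TRUE, g$shape), g)
  set.seed(10)
  for (i in 1:100) {
    vals <- rexp(1000, 1 / 30)
    p <- dvh_parameters(cumulative_dvh(volume(array(vals, g$shape), g,
                                              unit = "Gy"), mask))
    expect_true(p["d_max"] >= p["d_0.1cc"])
    expect_true(p["d_0.1cc"] >= p["d_2pct"])
    expect_true(p["d_2pct"] >= p["d_50pct"])
    expect_true(p["d_50pct"] >= p["d_95pct"])
    expect_true(p["d_95pct"] >= p["d_98pct"])
    expect_true(p["d_max"] >= p["d_mean"])
    expect_true(p["d_mean"] >= p["d_98pct"])
    if (i <= 5) {
      perm <- dvh_parameters(cumulative_dvh(
        volume(array(sample(vals), g$shape), g, unit = "Gy"), mask))
      expect_equal(p, perm)
      # d_mean is the plain voxel average to numerical precision
      expect_equal(unname(p["d_mean"]), mean(vals), tolerance = 1e-12)
    }
  }
})

test_that("sub-0.1 cm^3 structures fall back to D_max with a warning", {
  g <- grid3d(c(4, 4, 4), c(1, 1, 1))  # 0.001 cm^3 voxels
  m <- array(FALSE, g$shape); m[1:3, 1, 1] <- TRUE
  dose <- volume(array(seq_len(64) / 10, g$shape), g, unit = "Gy")
  expect_warning(p <- dvh_parameters(cumulative_dvh(dose, binary_mask(m, g))),
                 "0.1 cm")
  expect_equal(unname(p["d_0.1cc"]), unname(p["d_max"]))
})

test_that("relative dose difference follows the plan-copy convention", {
  expect_equal(relative_difference(60, 60), 0)
  expect_equal(relative_difference(59.4, 60), -1)
  # swapping the arguments flips the sign only approximately (1/(1+x))
  x <- relative_difference(62, 60)
  y <- relative_difference(60, 62)
  expect_gt(x, 0)
  expect_lt(y, 0)
  expect_gt(abs(x) - abs(y), 0)
  expect_lt(abs(x + y), 0.15)
  expect_error(relative_difference(1, 0), "> 0")
})

test_that("a globally scaled dose pair gives 100(c-1) for every parameter", {
  case <- noiseless_case()
  doses <- recalculate_on_sct(case$ct, case$ct, case$plan,
                              case$structures$body, case$structures$ptv)
  scaled <- volume(1.03 * doses$d_ct$values, doses$d_ct$grid, unit = "Gy")
  tab <- dvh_comparison(doses$d_ct, scaled,
                        list(PTV = case$structures$ptv))
  expect_true(all(abs(tab$delta_pct - 3) < 1e-9))
})

test_that("the OAR ring volume for a glioma-scale PTV is plausible", {
  # sphere-equivalent PTV of 267 cm^3 (r ~ 4 cm) plus a 2 cm shell
  g <- grid3d(c(60, 60, 60), c(3, 3, 3), c(-88.5, -88.5, -88.5))
  co <- as.matrix(expand.grid(x = grid_coords(g, 1), y = grid_coords(g, 2),
                              z = grid_coords(g, 3)))
  r <- sqrt(rowSums(co^2))
  ptv <- binary_mask(array(r <= 40, g$shape), g)
  body <- binary_mask(array(TRUE, g$shape), g)
  ring_v <- mask_volume_cm3(oar_ring(ptv, body, 20))
  expect_gt(ring_v, 400)
  expect_lt(ring_v, 700)
})
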