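test_that("grid and volume constructors enforce their invariants", {
  expect_error(grid3d(c(0, 4, 4), c(1, 1, 1)), "shape")
  expect_error(grid3d(c(4, 4, 4), c(1, -1, 1)), "spacing")
  g <- grid3d(c(4, 4, 4), c(1, 1, 2), c(-1, -1, -2))
  expect_equal(voxel_volume_mm3(g), 2)
  expect_equal(grid_coords(g, 3), c(-2, 0, 2, 4))
  expect_error(volume(array(NA_real_, c(4, 4, 4)), g), "finite")
  expect_error(volume(array(5000, c(4, 4, 4)), g, unit = "HU"),
               "\\[-1024, 3071\\]")
  expect_error(binary_mask(array(1, c(3, 3, 3)), g), "matching grid")
})

test_that("resampling onto the same grid is the identity", {
  g <- grid3d(c(8, 8, 8), c(1, 1, 2), c(0, 0, 0))
  set.seed(1)
  v <- volume(array(rnorm(512), c(8, 8, 8)), g)
  expect_equal(resample_to(v, g)$values, v$values)
  expect_equal(resample_to(v, g, mode = "nearest")$values, v$values)
})

test_that("trilinear resampling reproduces a constant and a linear ramp", {
  g <- grid3d(c(16, 16, 16), c(1, 1, 1), c(0, 0, 0))
  const <- volume(array(4.25, g$shape), g)
  tgt <- grid3d(c(7, 7, 7), c(1.7, 1.7, 1.7), c(1.1, 0.9, 1.3))
  expect_true(all(abs(resample_to(const, tgt)$values - 4.25) < 1e-12))

  # ramp f(x,y,z) = 2x - y + 0.5z evaluated at world coordinates is an
  # exact fixed point of trilinear interpolation
  co <- expand.grid(x = grid_coords(g, 1), y = grid_coords(g, 2),
                    z = grid_coords(g, 3))
  ramp <- volume(array(2 * co$x - co$y + 0.5 * co$z, g$shape), g)
  tgt2 <- grid3d(c(8, 8, 8), c(2, 2, 2), c(0.5, 0.5, 0.5))
  out <- resample_to(ramp, tgt2)
  co2 <- expand.grid(x = grid_coords(tgt2, 1), y = grid_coords(tgt2, 2),
                     z = grid_coords(tgt2, 3))
  inside <- co2$x <= 15 & co2$y <= 15 & co2$z <= 15
  expected <- 2 * co2$x - co2$y + 0.5 * co2$z
  expect_equal(as.numeric(out$values)[inside], expected[inside],
               tolerance = 1e-12)
})

test_that("nearest-neighbour resampling creates no new label values", {
  g <- grid3d(c(12, 12, 12), c(1.5, 1.5, 1.5), c(0, 0, 0))
  set.seed(2)
  labs <- sample(0:5, prod(g$shape), replace = TRUE)
  v <- volume(array(as.numeric(labs), g$shape), g)
  tgt <- grid3d(c(9, 9, 9), c(2.1, 2.1, 2.1), c(0.4, 0.2, 0.7))
  out <- resample_to(v, tgt, mode = "nearest")
  expect_true(all(out$values %in% 0:5))
})

test_that("resampling disjoint grids errors", {
  g <- grid3d(c(4, 4, 4), c(1, 1, 1), c(0, 0, 0))
  far <- grid3d(c(4, 4, 4), c(1, 1, 1), c(100, 100, 100))
  v <- volume(array(1, g$shape), g)
  expect_error(resample_to(v, far), "no spatial overlap")
})

test_that("NIfTI and MetaImage round trips are lossless", {
  g <- grid3d(c(16, 16, 16), c(1, 1, 2), c(-8, -8, -16))
  set.seed(3)
  v <- volume(array(rnorm(16^3), g$shape), g, unit = "Gy")
  for (ext in c("nii", "nii.gz", "mha", "mhd")) {
    path <- file.path(tempdir(), paste0("rt.", ext))
    write_volume(v, path)
    r1 <- read_volume(path)
    # float32 storage: a second round trip must be bitwise identical
    write_volume(r1, path)
    r2 <- read_volume(path)
    expect_identical(r1$values, r2$values)
    expect_true(max(abs(r1$values - v$values)) < 1e-5)  # float32 rounding
    expect_equal(r1$grid$spacing, g$spacing, tolerance = 1e-7)
    expect_equal(r1$grid$origin, g$origin, tolerance = 1e-7)
    expect_equal(r1$unit, "Gy")
  }
})

test_that("mask i/o stores uint8 and round trips exactly", {
  g <- grid3d(c(10, 10, 10), c(1, 1, 1), c(0, 0, 0))
  set.seed(4)
  m <- binary_mask(array(runif(1000) > 0.5, g$shape), g)
  for (ext in c("nii.gz", "mha")) {
    path <- file.path(tempdir(), paste0("mask.", ext))
    write_mask(m, path)
    expect_identical(read_mask(path)$member, m$member)
  }
})

test_that("volume reader rejects missing files and unknown extensions", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
  g <- grid3d(c(2, 2, 2), c(1, 1, 1))
  expect_error(write_volume(volume(array(0, c(2, 2, 2)), g),
                            file.path(tempdir(), "x.png")),
               "unknown volume file extension")
})

test_that("distance transform matches unit-step, Pythagoras and brute force", {
  g <- grid3d(c(10, 10, 10), c(1, 1, 1), c(0, 0, 0))
  m <- array(FALSE, g$shape)
  m[5, 5, 5] <- TRUE
  d <- distance_from_mask(binary_mask(m, g))$values
  expect_equal(d[6, 5, 5], 1)
  expect_equal(d[5, 5, 5], 0)
  expect_equal(d[8, 9, 5], 5)  # offset (3,4,0)

  # anisotropic random mask vs all-pairs brute force
  ga <- grid3d(c(12, 10, 8), c(1, 1.5, 2.5), c(0, 0, 0))
  set.seed(5)
  mm <- array(runif(prod(ga$shape)) > 0.97, ga$shape)
  mm[3, 3, 3] <- TRUE
  dt <- distance_from_mask(binary_mask(mm, ga))$values
  pts <- which(mm, arr.ind = TRUE)
  pw <- sweep(sweep(pts, 2, c(1, 1, 1)), 2, ga$spacing, "*")
  co <- as.matrix(expand.grid(x = grid_coords(ga, 1),
                              y = grid_coords(ga, 2),
                              z = grid_coords(ga, 3)))
  brute <- apply(co, 1, function(p) {
    sqrt(min(colSums((t(pw) - p)^2)))
  })
  expect_equal(as.numeric(dt), brute, tolerance = 1e-9)
  expect_true(all(dt[mm] == 0))
  expect_true(all(dt[!mm] > 0))
})

test_that("distance transform rejects an empty mask", {
  g <- grid3d(c(4, 4, 4), c(1, 1, 1))
  expect_error(distance_from_mask(binary_mask(array(FALSE, g$shape), g)),
               "empty mask")
})
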