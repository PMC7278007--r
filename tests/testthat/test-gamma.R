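gamma_grid <- function() grid3d(c(16, 16, 16), c(2, 2, 2), c(0, 0, 0))

test_that("identical dose pairs give gamma zero and a 100 percent pass", {
  g <- gamma_grid()
  ref <- volume(blob_field(g, 20, scale = 30), g, unit = "Gy")
  res <- gamma_map(ref, ref)
  m <- res$evaluated_mask$member
  expect_true(all(res$gamma_raw[m] == 0))
  expect_equal(res$pass_rate_pct, 100)
  # evaluated region is exactly the >10% of max reference voxels
  expect_identical(m, ref$values > 0.1 * max(ref$values))
})

test_that("a uniform +2 percent scaling saturates the dose axis exactly", {
  g <- gamma_grid()
  f <- blob_field(g, 21, scale = 1)
  ref <- volume(f / max(f) * 40, g, unit = "Gy")
  ev <- volume(1.02 * ref$values, g, unit = "Gy")
  res <- gamma_map(ref, ev, gamma_criteria(2, 2))
  m <- res$evaluated_mask$member
  expect_equal(res$pass_rate_pct, 100)
  # with a flat 2% offset the dose term at zero offset is D/max(D) <= 1;
  # the spatial search can only lower it, and only the max-dose voxel
  # can reach gamma ~ 1
  expect_true(all(res$gamma_raw[m] <= 1 + 1e-9))
  # the dose term alone would put the max-dose voxel exactly at 1; the
  # spatial search can shave a little off where the field has gradient
  expect_gt(max(res$gamma_raw[m]), 0.9)
})

test_that("a translation by exactly the DTA passes everywhere", {
  g <- gamma_grid()
  f <- blob_field(g, 22, scale = 30)
  ref <- volume(f, g, unit = "Gy")
  shifted <- f[c(1, 1:15), , ]  # +x shift by one 2 mm voxel
  ev <- volume(shifted, g, unit = "Gy")
  res <- gamma_map(ref, ev, gamma_criteria(2, 2))
  expect_equal(res$pass_rate_pct, 100)
})

test_that("pass rate counts only gamma <= 1 over the evaluated region", {
  g <- grid3d(c(4, 4, 4), c(1, 1, 1))
  gam <- array(NA_real_, g$shape)
  mask <- array(FALSE, g$shape)
  mask[1:32] <- TRUE
  gam[1:16] <- 0.5
  gam[17:32] <- 1.5
  res <- structure(list(gamma_raw = gam,
                        evaluated_mask = binary_mask(mask, g)),
                   class = "gamma_result")
  expect_equal(gamma_pass_rate(res), 50)
})

test_that("gamma is invariant when both doses share a global scale", {
  g <- gamma_grid()
  ref <- volume(blob_field(g, 23, scale = 30), g, unit = "Gy")
  ev <- volume(blob_field(g, 23, shift = c(0.5, 0.5, 0), scale = 31), g,
               unit = "Gy")
  r1 <- gamma_map(ref, ev)
  r2 <- gamma_map(volume(2.5 * ref$values, g, "Gy"),
                  volume(2.5 * ev$values, g, "Gy"))
  expect_equal(r1$gamma_raw, r2$gamma_raw, tolerance = 1e-12)
})

test_that("tightening the criteria never increases the pass rate", {
  g <- gamma_grid()
  set.seed(24)
  for (i in 1:4) {
    base <- blob_field(g, 30 + i, scale = 1)
    ref <- volume(base / max(base) * 30, g, unit = "Gy")
    ev <- volume(ref$values * runif(1, 1.005, 1.03) +
                   0.05 * array(rnorm(16^3), g$shape), g, unit = "Gy")
    loose <- gamma_map(ref, ev, gamma_criteria(2, 2))
    tight <- gamma_map(ref, ev, gamma_criteria(1, 1))
    expect_lte(tight$pass_rate_pct, loose$pass_rate_pct)
  }
})

test_that("gamma is capped exactly where the oracle is at or above the cap", {
  g <- gamma_grid()
  ref <- volume(blob_field(g, 26, scale = 30), g, unit = "Gy")
  ev <- volume(0.6 * ref$values, g, unit = "Gy")  # gross mismatch
  crit <- gamma_criteria(2, 2)
  fast <- gamma_map(ref, ev, crit)
  orac <- gamma_brute_force(ref, ev, crit, step_mm = 0.2)
  m <- fast$evaluated_mask$member
  capped <- orac$gamma_raw[m] >= crit$cap - 1e-9
  expect_gt(sum(capped), 0)
  expect_true(all(fast$gamma_raw[m][capped] == crit$cap))
  expect_true(all(fast$gamma_raw[m] >= 0))
})

test_that("fast search agrees with the fine brute-force oracle", {
  g <- gamma_grid()
  for (p in 1:2) {
    base <- blob_field(g, 40 + p, scale = 1)
    sc <- 30 / max(base)
    ref <- volume(base * sc, g, unit = "Gy")
    ev <- volume(blob_field(g, 40 + p, shift = c(0.8, -0.6, 0.7),
                            scale = sc * 1.010), g, unit = "Gy")
    fast <- gamma_map(ref, ev, gamma_criteria(2, 2))
    orac <- gamma_brute_force(ref, ev, gamma_criteria(2, 2),
                              step_mm = 0.07)
    m <- fast$evaluated_mask$member
    expect_lt(max(abs(fast$gamma_raw[m] - orac$gamma_raw[m])), 0.02)
  }
})

test_that("degenerate inputs raise the documented errors", {
  g <- gamma_grid()
  zero <- volume(array(0, g$shape), g, unit = "Gy")
  expect_error(gamma_map(zero, zero), "no evaluable voxels")
  small <- grid3d(c(8, 8, 8), c(2, 2, 2))
  big <- grid3d(c(40, 40, 40), c(2, 2, 2))
  expect_error(gamma_brute_force(volume(array(1, big$shape), big, "Gy"),
                                 volume(array(1, big$shape), big, "Gy")),
               "small grids")
  expect_error(gamma_map(volume(array(1, small$shape), small, "Gy"),
                         volume(array(1, g$shape), g, "Gy")),
               "share a grid")
})
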