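test_that("noiseless phantom is recovered exactly, voxel for voxel", {
  case <- noiseless_case()
  post <- segment_tissues(case$mr, seed = 5)
  masks <- masks_from_posteriors(post)
  lab <- masks_to_labels(masks, case$mr$grid)
  inside <- case$structures$body$member
  expect_true(all(lab[inside] == case$labels$labels[inside]))
})

test_that("posteriors are a probability partition at every voxel", {
  case <- realistic_case()
  post <- segment_tissues(case$mr, seed = 5)
  sums <- apply(post$prob, c(1, 2, 3), sum)
  expect_true(max(abs(sums - 1)) < 1e-6)
  expect_true(min(post$prob) >= 0)
})

test_that("classification stays above 95 percent at 5 percent MR noise", {
  wm_mean <- mr_class_means()[["wm"]]
  cfg <- phantom_config("glioma", spacing_scale = 3, seed = 31,
                        noise_sd_mr = 0.05 * wm_mean,
                        bias_field_amplitude = 0, contrast_enhancement = 1,
                        noise_sd_ct = 0, skull_hu_range = NULL,
                        pv_blur_voxels = 0)
  case <- generate_case(cfg)
  post <- segment_tissues(case$mr, seed = 5)
  lab <- masks_to_labels(masks_from_posteriors(post), case$mr$grid)
  acc <- mean((lab == case$labels$labels)[case$structures$body$member])
  expect_gt(acc, 0.95)
})

test_that("classification accuracy degrades monotonically with MR noise", {
  wm_mean <- mr_class_means()[["wm"]]
  acc_at <- function(noise_frac) {
    accs <- vapply(c(41, 42), function(s) {
      cfg <- phantom_config("glioma", spacing_scale = 4, seed = s,
                            noise_sd_mr = noise_frac * wm_mean,
                            bias_field_amplitude = 0,
                            contrast_enhancement = 1, noise_sd_ct = 0,
                            skull_hu_range = NULL, pv_blur_voxels = 0)
      case <- generate_case(cfg)
      post <- segment_tissues(case$mr, seed = 5)
      lab <- masks_to_labels(masks_from_posteriors(post), case$mr$grid)
      mean((lab == case$labels$labels)[case$structures$body$member])
    }, numeric(1))
    mean(accs)
  }
  a <- acc_at(0.01)
  b <- acc_at(0.05)
  c <- acc_at(0.12)
  expect_gte(a, b)
  expect_gte(b, c)
})

test_that("hard masks honour one-hot posteriors and the bone tie rule", {
  g <- grid3d(c(6, 6, 6), c(2, 2, 2), c(0, 0, 0))
  classes <- names(tissue_classes())
  # one-hot: alternating wm / csf
  prob <- array(0, c(g$shape, 6), dimnames = list(NULL, NULL, NULL, classes))
  pick <- array(rep(c("wm", "csf"), length.out = prod(g$shape)), g$shape)
  for (cl in classes) prob[, , , cl][pick == cl] <- 1
  post <- structure(list(prob = prob, classes = classes, grid = g),
                    class = "tissue_posteriors")
  masks <- masks_from_posteriors(post, min_component_cm3 = 0)
  expect_identical(masks$wm$member, pick == "wm")
  expect_identical(masks$csf$member, pick == "csf")

  # uniform posteriors: the fixed priority assigns every voxel to bone
  prob[] <- 1 / 6
  post$prob <- prob
  masks_u <- masks_from_posteriors(post)
  expect_true(all(masks_u$bone$member))

  # masks always partition the grid exactly once
  total <- Reduce(`+`, lapply(masks, function(m) m$member))
  expect_true(all(total == 1))
})

test_that("small bone or air speckles are reassigned to soft tissue", {
  g <- grid3d(c(8, 8, 8), c(2, 2, 2), c(0, 0, 0))
  classes <- names(tissue_classes())
  prob <- array(0, c(g$shape, 6), dimnames = list(NULL, NULL, NULL, classes))
  prob[, , , "soft"] <- 1
  # a single 8 mm^3 bone voxel (0.008 cm^3 < 0.05 cm^3 threshold)
  prob[4, 4, 4, ] <- 0
  prob[4, 4, 4, "bone"] <- 1
  post <- structure(list(prob = prob, classes = classes, grid = g),
                    class = "tissue_posteriors")
  masks <- masks_from_posteriors(post)
  expect_false(any(masks$bone$member))
  expect_true(masks$soft$member[4, 4, 4])
})

test_that("sCT assembly is a piecewise-constant HU lookup", {
  case <- noiseless_case()
  post <- segment_tissues(case$mr, seed = 5)
  masks <- masks_from_posteriors(post)
  sct <- assemble_sct(masks)
  expect_equal(sct$unit, "HU")
  expect_lte(length(unique(as.numeric(sct$values))), 6)
  expect_true(all(sct$values[masks$air$member] == -1000))
  expect_true(all(sct$values[masks$bone$member] == 942))
  # supplying the masks in a different order changes nothing
  sct2 <- assemble_sct(rev(masks))
  expect_identical(sct$values, sct2$values)
})

test_that("the full pipeline has the noiseless zero-error fixed point", {
  case <- noiseless_case()
  sct <- run_sct_pipeline(case$mr, seed = 42)
  expect_identical(dim(sct$values), dim(case$ct$values))
  expect_equal(max(abs(sct$values - case$ct$values)), 0)
  expect_gte(min(sct$values), -1000)
  expect_lte(max(sct$values), 942)
})

test_that("pipeline output onto a coarser reference grid stays six-valued", {
  case <- noiseless_case()
  ref <- grid3d(c(32, 32, 14), c(6, 6, 12), case$mr$grid$origin)
  sct <- run_sct_pipeline(case$mr, reference = ref, seed = 42)
  expect_true(all(sct$values %in% hu_table()))
})
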