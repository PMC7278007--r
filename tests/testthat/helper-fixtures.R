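# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# noiseless glioma case at desk scale: the exact-recovery limit
noiseless_case <- function() {
  fixture("noiseless_case", function() {
    generate_case(noiseless_config("glioma", spacing_scale = 3, seed = 7))
  })
}

# realistic glioma case at desk scale
realistic_case <- function() {
  fixture("realistic_case", function() {
    generate_case(phantom_config("glioma", spacing_scale = 3, seed = 11))
  })
}

# smooth dose-like field: sum of 3D Gaussian blobs, scaled to max_gy
blob_field <- function(g, seed, shift = c(0, 0, 0), scale = 1,
                       n_blobs = 4, sigma_range = c(30, 55)) {
  set.seed(seed)
  co <- expand.grid(x = grid_coords(g, 1), y = grid_coords(g, 2),
                    z = grid_coords(g, 3))
  f <- 0
  for (i in seq_len(n_blobs)) {
    c0 <- runif(3, 0, 30) + shift
    s <- runif(1, sigma_range[1], sigma_range[2])
    f <- f + exp(-((co$x - c0[1])^2 + (co$y - c0[2])^2 +
                     (co$z - c0[3])^2) / (2 * s^2))
  }
  array(f * scale, g$shape)
}

# label argmax of the six class masks as a label array
masks_to_labels <- function(masks, grid) {
  cls <- tissue_classes()
  lab <- array(0L, grid$shape)
  for (cl in names(cls)) lab[masks[[cl]]$member] <- cls[[cl]]
  lab
}
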