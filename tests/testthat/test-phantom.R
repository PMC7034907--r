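test_that("an empty spec gives a uniform background volume", {
  sp <- phantom_spec(c(16, 16, 16), 50, background = list(mu = 0.18))
  vol <- generate_phantom(sp, 146.1)
  expect_true(all(vol$mu == 0.18))
  expect_true(all(vol$labels == 0L))
})

test_that("noiseless unblurred primitives carry exactly their material attenuation", {
  vol <- sphere_phantom(centers = c(20, 20, 20), radii = 6)
  inside <- vol$labels == 1L
  expect_gt(sum(inside), 500)
  mu_true <- linear_attenuation(halite_mat(), 146.1)
  expect_true(all(vol$mu[inside] == mu_true))
  expect_true(all(vol$mu[!inside] == 0.18))
  expect_equal(vol$ground_truth$true_mu, mu_true)
})

test_that("later primitives overwrite earlier ones on overlap", {
  sp <- phantom_spec(c(24, 24, 24), 50, background = list(mu = 0.1),
                     shapes = list(
                       list(type = "box", center = c(12, 12, 12),
                            radii = c(6, 6, 6), material = "halite"),
                       list(type = "box", center = c(12, 12, 12),
                            radii = c(3, 3, 3), material = "nahcolite")))
  vol <- generate_phantom(sp, 146.1)
  expect_identical(vol$labels[12, 12, 12], 2L)
  expect_identical(vol$labels[7, 12, 12], 1L)
})

test_that("shapes outside the grid are rejected at spec time", {
  expect_error(phantom_spec(c(16, 16, 16), 50, background = list(mu = 0.1),
                            shapes = list(list(type = "ellipsoid",
                                               center = c(15, 8, 8),
                                               radii = c(4, 4, 4),
                                               material = "halite"))),
               "outside the grid")
})

test_that("phantom generation is deterministic in the seed", {
  sp <- mummy_phantom_spec(seed = 7, dim = c(48, 48, 48), n_inclusions = 5)
  v1 <- generate_phantom(sp, 146.1)
  v2 <- generate_phantom(sp, 146.1)
  expect_identical(v1$mu, v2$mu)
  sp2 <- mummy_phantom_spec(seed = 8, dim = c(48, 48, 48), n_inclusions = 5)
  expect_false(identical(generate_phantom(sp2, 146.1)$mu, v1$mu))
})

test_that("degrade with zero sigmas is the identity and preserves labels", {
  vol <- sphere_phantom(centers = c(20, 20, 20), radii = 6)
  d0 <- degrade(vol, 0, 0)
  expect_identical(d0$mu, vol$mu)
  d1 <- degrade(vol, 1.2, 0.02, seed = 3)
  expect_identical(d1$labels, vol$labels)
  expect_identical(d1$ground_truth, vol$ground_truth)
})

test_that("gaussian blur conserves the volume mean to 1e-6", {
  vol <- sphere_phantom(centers = c(12, 25, 30), radii = 7)
  for (sigma in c(0.7, 1.5, 3)) {
    b <- degrade(vol, sigma, 0)
    expect_equal(mean(b$mu), mean(vol$mu), tolerance = 1e-6)
    expect_lt(max(b$mu), max(vol$mu) + 1e-12)  # blur cannot create new extremes
  }
})

test_that("noise-only degradation has the requested standard deviation", {
  sp <- phantom_spec(c(100, 100, 100), 50, background = list(mu = 0.2))
  vol <- generate_phantom(sp, 146.1)
  nz <- degrade(vol, 0, 0.01, seed = 11)
  res <- nz$mu - vol$mu
  expect_equal(sd(res), 0.01, tolerance = 0.05)
  expect_equal(mean(res), 0, tolerance = 1e-4)
})

test_that("degradation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(degrade(sphere_phantom(centers = c(20, 20, 20), radii = 5),
                    0.7, 0.01, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("flat-field phase retrieval recovers a uniform thickness", {
  mu <- 0.5  # cm^-1
  t0 <- 2    # cm
  intensity <- matrix(exp(-mu * t0), 64, 64)
  t_hat <- paganin_retrieve(intensity, delta_beta = 500, distance_m = 4,
                            energy_keV = 146.1, pixel_um = 24.37, mu = mu)
  expect_equal(t_hat, matrix(t0, 64, 64), tolerance = 1e-10)
})

test_that("zero delta/beta or zero distance reduces to Beer-Lambert", {
  set.seed(4)
  img <- matrix(exp(rnorm(32 * 32, -1, 0.2)), 32, 32)
  mu <- 0.3
  bl <- -log(img) / mu
  expect_equal(paganin_retrieve(img, 0, 4, 146.1, 24.37, mu), bl,
               tolerance = 1e-10)
  expect_equal(paganin_retrieve(img, 500, 0, 146.1, 24.37, mu), bl,
               tolerance = 1e-10)
})

test_that("the retrieval filter is a low-pass: output variance never exceeds input", {
  set.seed(8)
  mu <- 0.3
  for (i in 1:5) {
    img <- matrix(exp(rnorm(48 * 48, -0.5, 0.1)), 48, 48)
    t_in <- -log(img) / mu
    t_out <- paganin_retrieve(img, 300, 2.6, 110, 6.37, mu)
    expect_lte(var(c(t_out)), var(c(t_in)) + 1e-12)
  }
  expect_error(paganin_retrieve(matrix(c(-1, 1, 1, 1), 2), 300, 2.6, 110,
                                6.37, mu), "positive|> 0")
})

test_that("volumes round-trip through TIFF stacks with their sidecar", {
  vol <- sphere_phantom(centers = c(20, 20, 20), radii = 6,
                        psf = 0.7, noise = 0.01, seed = 2)
  f <- file.path(tempdir(), "vol_roundtrip.tif")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_equal(back$mu, vol$mu, tolerance = 1e-6)
  expect_identical(back$labels, vol$labels)
  expect_equal(back$voxel_size_um, vol$voxel_size_um)
  expect_equal(back$energy_keV, vol$energy_keV)
  expect_equal(back$ground_truth$true_mu, vol$ground_truth$true_mu)
  expect_error(read_volume(file.path(tempdir(), "missing.tif")), "sidecar")
})
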