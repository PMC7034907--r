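test_that("a single noiseless sphere is found with its exact attenuation", {
  vol <- sphere_phantom(centers = c(20, 20, 20), radii = 6)
  seg <- segment_inclusions(vol, threshold = 0.25)
  expect_equal(seg$summary$n_inclusions, 1L)
  mu_true <- linear_attenuation(halite_mat(), 146.1)
  expect_equal(seg$stats$mean_mu, mu_true, tolerance = 1e-6)
  expect_equal(seg$stats$max_mu, mu_true)
  expect_equal(c(seg$stats$cx, seg$stats$cy, seg$stats$cz), c(20, 20, 20),
               tolerance = 0.05)
})

test_that("a threshold above the global maximum yields an empty result, not an error", {
  vol <- sphere_phantom(centers = c(20, 20, 20), radii = 6)
  seg <- segment_inclusions(vol, threshold = 10)
  expect_equal(seg$summary$n_inclusions, 0L)
  expect_true(all(seg$labels == 0L))
})

test_that("component counts match a brute-force flood-fill oracle", {
  # disjoint spheres -> 2 components; overlapping -> merged into 1
  two <- sphere_phantom(centers = rbind(c(12, 12, 12), c(28, 28, 28)),
                        radii = 5)
  merged <- sphere_phantom(centers = rbind(c(16, 20, 20), c(22, 20, 20)),
                           radii = 5)
  for (vol in list(two, merged)) {
    seg <- segment_inclusions(vol, threshold = 0.25, min_size = 1)
    oracle <- flood_fill_components(vol$mu > 0.25)
    expect_equal(seg$summary$n_inclusions, max(oracle))
    # voxel partition agrees, up to label permutation
    for (k in seq_len(max(oracle))) {
      expect_equal(length(unique(seg$labels[oracle == k])), 1L)
    }
  }
})

test_that("components below min_size are discarded", {
  vol <- sphere_phantom(centers = rbind(c(10, 10, 10), c(28, 28, 28)),
                        radii = c(1.5, 6))
  seg_all <- segment_inclusions(vol, threshold = 0.25, min_size = 1)
  expect_equal(seg_all$summary$n_inclusions, 2L)
  seg <- segment_inclusions(vol, threshold = 0.25, min_size = 27)
  expect_equal(seg$summary$n_inclusions, 1L)
  expect_gte(min(seg$stats$voxels), 27)
})

test_that("raising the threshold never grows any component", {
  vol <- sphere_phantom(centers = rbind(c(12, 12, 12), c(28, 28, 28)),
                        radii = 6, psf = 1.0, noise = 0, seed = 1)
  t1 <- segment_inclusions(vol, threshold = 0.22, min_size = 1)
  t2 <- segment_inclusions(vol, threshold = 0.27, min_size = 1)
  # every high-threshold component sits inside one low-threshold component
  for (k in seq_len(t2$summary$n_inclusions)) {
    parents <- unique(t1$labels[t2$labels == k])
    expect_length(parents, 1L)
    expect_gt(parents, 0L)
    expect_lte(sum(t2$labels == k), sum(t1$labels == parents))
  }
})

test_that("erosion suppresses the partial-volume rim under blur", {
  vol <- sphere_phantom(centers = c(20, 20, 20), radii = 7, psf = 0.7)
  mu_true <- linear_attenuation(halite_mat(), 146.1)
  seg_er <- segment_inclusions(vol, threshold = 0.25, erode = TRUE)
  seg_no <- segment_inclusions(vol, threshold = 0.25, erode = FALSE)
  expect_lt(abs(seg_er$stats$mean_mu - mu_true),
            abs(seg_no$stats$mean_mu - mu_true))
  # a tiny component falls back to full-component statistics when erosion
  # would empty it
  tiny <- sphere_phantom(centers = c(20, 20, 20), radii = 2)
  seg_tiny <- segment_inclusions(tiny, threshold = 0.25, min_size = 5)
  expect_equal(seg_tiny$summary$n_inclusions, 1L)
  expect_true(is.finite(seg_tiny$stats$mean_mu))
})

test_that("noiseless recovery is perfect and matching is geometric", {
  vol <- sphere_phantom(centers = rbind(c(10, 10, 10), c(28, 12, 28),
                                        c(14, 30, 20)),
                        radii = c(5, 4, 6),
                        materials = c("halite", "nahcolite", "halite"))
  seg <- segment_inclusions(vol, threshold = 0.25)
  rep <- recovery_report(seg, vol$ground_truth)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$per_material$bias, c(0, 0), tolerance = 1e-9)
  expect_equal(rep$per_material$rmse, c(0, 0), tolerance = 1e-9)
  # permuting truth rows (label shuffling) leaves the metrics unchanged
  shuffled <- vol$ground_truth[c(3, 1, 2), ]
  rep2 <- recovery_report(seg, shuffled)
  expect_equal(rep2$precision, rep$precision)
  expect_equal(rep2$recall, rep$recall)
})

test_that("false positives lower precision; misses lower recall", {
  vol <- sphere_phantom(centers = rbind(c(10, 10, 10), c(28, 28, 28)),
                        radii = 5)
  seg <- segment_inclusions(vol, threshold = 0.25)
  # drop one truth row: the orphaned segmentation becomes a false positive
  rep_fp <- recovery_report(seg, vol$ground_truth[1, , drop = FALSE])
  expect_equal(rep_fp$precision, 0.5)
  expect_equal(rep_fp$recall, 1)
  # extra truth entry nobody found: recall drops
  ghost <- vol$ground_truth[1, ]
  ghost$label <- 99L; ghost$cx <- 35; ghost$cy <- 10; ghost$cz <- 35
  rep_miss <- recovery_report(seg, rbind(vol$ground_truth, ghost))
  expect_equal(rep_miss$precision, 1)
  expect_equal(rep_miss$recall, 2 / 3)
})
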