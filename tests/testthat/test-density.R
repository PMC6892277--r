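test_that("regional density map handles the limiting cases", {
  d <- c(4, 8, 8)
  tissue <- array(TRUE, d)
  regions <- chunk_region_labels(d, c(2, 2))
  all_vessel <- density_map(tissue, tissue, regions)
  expect_true(all(all_vessel$density_pct == 100))

  none <- density_map(array(FALSE, d), tissue, regions)
  expect_true(all(none$density_pct == 0))

  # a region without tissue is flagged, not zero-filled
  part <- array(FALSE, d); part[, 1:4, 1:4] <- TRUE
  dm <- density_map(array(FALSE, d), part, regions)
  expect_true(is.na(dm$density_pct[dm$n_tissue == 0][1]))

  # conservation: vessel voxels partition over regions
  set.seed(2)
  v <- array(runif(prod(d)) < 0.2, d) & tissue
  dm2 <- density_map(v, tissue, regions)
  expect_equal(sum(dm2$n_vessel), sum(v))
})

test_that("phantom regional densities match ground truth within 0.5 pp", {
  ph <- default_phantom()
  seg <- segment_volume(ph$volume, find_thresholds(ph$volume))
  regions <- chunk_region_labels(dim(ph$volume$voxels), c(10, 10))
  est <- density_map(seg$vessel_mask, seg$tissue_mask, regions)
  truth <- density_map(ph$truth$vessel_mask, ph$truth$tissue_mask, regions)
  both <- !is.na(est$density_pct) & !is.na(truth$density_pct)
  expect_lt(max(abs(est$density_pct[both] - truth$density_pct[both])), 0.5)
})

test_that("chunked density map equals the whole-volume map", {
  ph <- generate_volume_phantom(
    phantom_spec_3d(shape = c(20, 64, 64), disc_radius_vox = 28,
                    disc_thickness_vox = 16, target_density = 0.05,
                    seed = 5))
  th <- find_thresholds(ph$volume)
  seg <- segment_volume(ph$volume, th)
  whole <- density_map(seg$vessel_mask, seg$tissue_mask,
                       chunk_region_labels(dim(ph$volume$voxels), c(4, 4)))
  chunked <- density_map_chunked(ph$volume, th, grid = c(4, 4), halo = 7)
  expect_identical(whole$n_tissue, chunked$n_tissue)
  expect_identical(whole$n_vessel, chunked$n_vessel)
  expect_equal(whole$density_pct, chunked$density_pct)
})

test_that("radial profile aggregates, conserves and flags correctly", {
  # all-vessel disc: every supported bin reads 100%
  mask2d <- disc_mask(41, 16)
  tissue <- array(rep(mask2d, each = 6), c(6, 41, 41))
  g <- compute_distance_map(mask2d, c(21, 21))
  prof <- radial_profile(tissue, tissue, g)
  expect_true(all(prof$density_pct[prof$n_tissue > 0] == 100))
  expect_true(all(is.na(prof$density_pct[prof$n_tissue == 0])))

  # voxel-weighted profile mean equals the global density
  ph <- default_phantom()
  th <- find_thresholds(ph$volume)
  seg <- segment_volume(ph$volume, th)
  geom <- compute_distance_map(
    max_intensity_projection(ph$volume) >= th$tissue_threshold,
    ph$truth$cord_point)
  prof2 <- radial_profile(seg$vessel_mask, seg$tissue_mask, geom)
  wm <- 100 * sum(prof2$n_vessel) / sum(prof2$n_tissue)
  expect_equal(wm, global_density(seg$vessel_mask, seg$tissue_mask),
               tolerance = 1e-9)
  expect_equal(sum(prof2$n_vessel), sum(seg$vessel_mask))
})

test_that("a constructed linear gradient gives a strong negative trend", {
  R <- 60; n <- 131
  mask2d <- disc_mask(n, R, centre = 66)
  tissue <- array(rep(mask2d, each = 10), c(10, n, n))
  yy <- matrix(1:n, n, n); xx <- t(yy)
  p2d <- pmax(0, 0.3 * (1 - sqrt((yy - 66)^2 + (xx - 66)^2) / R))
  set.seed(14)
  vessel <- array(runif(length(tissue)) < rep(p2d, each = 10), dim(tissue)) &
    tissue
  g <- compute_distance_map(mask2d, c(66, 66))
  prof <- radial_profile(vessel, tissue, g)
  keep <- prof$n_tissue > 50
  ct <- suppressWarnings(cor.test(prof$bin[keep], prof$density_pct[keep],
                                  method = "spearman"))
  expect_lt(unname(ct$estimate), -0.9)
})

test_that("homogeneous profiles are flat relative to replicate noise", {
  R <- 60; n <- 131
  mask2d <- disc_mask(n, R, centre = 66)
  tissue <- array(rep(mask2d, each = 10), c(10, n, n))
  g <- compute_distance_map(mask2d, c(66, 66))
  set.seed(31)
  profs <- sapply(1:8, function(i) {
    vessel <- array(runif(length(tissue)) < 0.1, dim(tissue)) & tissue
    radial_profile(vessel, tissue, g)$density_pct
  })
  n_tissue <- radial_profile(tissue, tissue, g)$n_tissue
  # compare bins of comparable support: the innermost annuli hold a handful
  # of voxel columns and would dominate both the range and the noise scale
  support <- n_tissue >= 2000 & (0:99) >= 5 & (0:99) <= 95
  mean_prof <- rowMeans(profs[support, ])
  mc_sd <- mean(apply(profs[support, ], 1, sd))
  expect_lte(max(mean_prof) - min(mean_prof), 2 * mc_sd)
})

test_that("block density uses the basal-third region of interest", {
  base <- array(10L, c(30, 40, 40))
  tissue_z <- 4:27
  base[tissue_z, , ] <- 100L
  # vessels only in the bottom (basal) third, 10% of tissue voxels
  set.seed(7)
  roi <- 20:27
  sel <- array(FALSE, dim(base))
  sel[roi, , ] <- runif(length(roi) * 1600) < 0.10
  withv <- base; withv[sel] <- 220L
  bd <- block_density(volume_image(withv, 13.5), threshold_pair(55, 160))
  expect_equal(bd$roi_slices, roi)
  expect_lt(abs(bd$density_pct - 10), 1)

  # no vessels at all
  bd0 <- block_density(volume_image(base, 13.5), threshold_pair(55, 160))
  expect_equal(bd0$density_pct, 0)

  # uniform vessel fraction: basal third matches the whole block
  unif <- base
  selu <- array(FALSE, dim(base))
  selu[tissue_z, , ] <- runif(length(tissue_z) * 1600) < 0.10
  unif[selu] <- 220L
  seg <- segment_volume(unif, threshold_pair(55, 160))
  whole <- global_density(seg$vessel_mask, seg$tissue_mask)
  bdu <- block_density(volume_image(unif, 13.5), threshold_pair(55, 160))
  expect_lt(abs(bdu$density_pct - whole), 0.5)

  # tissue thinner than 3 slices is an error
  thin <- array(10L, c(30, 40, 40)); thin[5:6, , ] <- 100L
  expect_error(block_density(volume_image(thin, 13.5),
                             threshold_pair(55, 160)), "3 slices")
})
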