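test_that("volume phantom handles trivial specs and is deterministic", {
  spec0 <- phantom_spec_3d(shape = c(20, 80, 80), disc_radius_vox = 32,
                           disc_thickness_vox = 14, n_trees = 0, seed = 4)
  ph0 <- generate_volume_phantom(spec0)
  expect_false(any(ph0$truth$vessel_mask))
  bins <- ph0$truth$density_by_bin
  expect_true(all(bins$density_pct[bins$n_tissue > 0] == 0))

  spec <- phantom_spec_3d(shape = c(20, 80, 80), disc_radius_vox = 32,
                          disc_thickness_vox = 14, n_trees = 6,
                          root_radius_vox = 1.5, seed = 9)
  a <- generate_volume_phantom(spec)
  b <- generate_volume_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$vessel_mask, b$truth$vessel_mask)

  # vessels inside tissue; masks consistent with rendered voxels
  expect_true(all(a$truth$tissue_mask[a$truth$vessel_mask]))
  contrast <- spec$grey_levels[3]
  expect_gt(mean(a$volume$voxels[a$truth$vessel_mask]), 0.9 * contrast)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec_3d(root_radius_vox = 40, disc_thickness_vox = 30),
               "cannot fit")
  expect_error(phantom_spec_3d(fill_fraction = 1.5), "fill_fraction")
  expect_error(phantom_spec_3d(grey_levels = c(100, 50, 220)), "increasing")
  expect_error(phantom_spec_3d(disc_radius_vox = 200), "field of view")
})

test_that("a straight axial tree renders the analytic cylinder volume", {
  spec <- phantom_spec_3d(shape = c(60, 64, 64), disc_radius_vox = 28,
                          disc_thickness_vox = 56, n_trees = 1,
                          branch_generations = 0, root_radius_vox = 3,
                          root_length_vox = 50, fill_fraction = 1, seed = 2)
  ph <- generate_volume_phantom(spec)
  analytic <- pi * 3^2 * 50
  expect_lt(abs(sum(ph$truth$vessel_mask) - analytic) / analytic, 0.10)
})

test_that("ground-truth bin densities equal a brute-force recount", {
  ph <- generate_volume_phantom(
    phantom_spec_3d(shape = c(16, 64, 64), disc_radius_vox = 26,
                    disc_thickness_vox = 10, n_trees = 10,
                    root_radius_vox = 1.5, seed = 3))
  d <- dim(ph$truth$tissue_mask)
  centre <- c(ph$truth$disc$cy, ph$truth$disc$cx)
  R <- ph$truth$disc$R
  # independent oracle: loop over voxels, analytic normalised distance
  nv <- nt <- rep(0L, 100)
  for (x in seq_len(d[3])) {
    for (y in seq_len(d[2])) {
      r <- sqrt((y - centre[1])^2 + (x - centre[2])^2)
      if (r > R) next
      b <- min(99L, as.integer(floor(100 * r / R)))
      nt[b + 1L] <- nt[b + 1L] + sum(ph$truth$tissue_mask[, y, x])
      nv[b + 1L] <- nv[b + 1L] + sum(ph$truth$vessel_mask[, y, x])
    }
  }
  expect_identical(ph$truth$density_by_bin$n_tissue, as.numeric(nt))
  expect_identical(ph$truth$density_by_bin$n_vessel, as.numeric(nv))
})

test_that("homogeneous phantoms have no radial trend, gradient phantoms do", {
  profile_rs <- function(ph) {
    b <- ph$truth$density_by_bin
    keep <- b$n_tissue >= 3000 & b$bin <= 97
    suppressWarnings(cor(b$bin[keep], b$density_pct[keep],
                         method = "spearman"))
  }
  rs_flat <- vapply(1:8, function(s) {
    profile_rs(generate_volume_phantom(
      phantom_spec_3d(seed = s, target_density = 0.05)))
  }, numeric(1))
  expect_lt(abs(mean(rs_flat)), 0.3)

  rs_grad <- vapply(1:3, function(s) {
    profile_rs(generate_volume_phantom(
      phantom_spec_3d(seed = s, n_trees = 150, density_gradient = 1)))
  }, numeric(1))
  expect_true(all(rs_grad < -0.8))
})
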