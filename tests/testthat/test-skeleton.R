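test_that("a cylinder thins to its axis line", {
  cyl <- make_cylinder(4, 60)
  sk <- skeletonise(cyl$mask)
  expect_true(all(cyl$mask[sk$coords]))
  zs <- sk$coords[, 1]
  expect_gte(diff(range(zs)) + 1, 56) # 60 +/- 4 with cap shortening
  expect_lte(diff(range(zs)) + 1, 64)
  # away from the ends the skeleton lies exactly on the axis
  interior <- zs > min(zs) + 4 & zs < max(zs) - 4
  off <- sqrt((sk$coords[, 2] - cyl$centre)^2 +
                (sk$coords[, 3] - cyl$centre)^2)
  expect_lte(max(off[interior]), 1.5)
})

test_that("degenerate masks skeletonise sensibly", {
  empty <- array(FALSE, c(5, 5, 5))
  expect_equal(nrow(skeletonise(empty)$coords), 0)

  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  sk <- skeletonise(single)
  expect_equal(unname(sk$coords[1, ]), c(3L, 3L, 3L))
})

test_that("skeletonisation is idempotent", {
  cyl <- make_cylinder(3, 40)
  sk <- skeletonise(cyl$mask)
  skmask <- array(FALSE, dim(cyl$mask))
  skmask[sk$coords] <- TRUE
  sk2 <- skeletonise(skmask)
  expect_equal(nrow(sk2$coords), nrow(sk$coords))
  expect_true(all(skmask[sk2$coords]))
})

test_that("a Y-shaped tube yields exactly one branch voxel after pruning", {
  sk <- prune_skeleton(skeletonise(make_y_tube()), min_length = 5)
  expect_equal(sum(skeleton_degrees(sk) > 2), 1)
  expect_equal(length(unique(sk$component_id)), 1)
})

test_that("centreline radii recover cylinder radii within voxelisation", {
  for (r in c(2, 3, 4, 6, 8)) {
    cyl <- make_cylinder(r, 40)
    sk <- measure_radius(skeletonise(cyl$mask), cyl$mask)
    expect_lt(abs(median(sk$radius_vox) - r), 0.7)
  }
  # one-voxel vessel
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  sk1 <- measure_radius(skeletonise(single), single)
  expect_lte(sk1$radius_vox, 1)
  # micrometre conversion
  cyl <- make_cylinder(3, 30)
  sk <- measure_radius(skeletonise(cyl$mask), cyl$mask, voxel_size_um = 116.5)
  expect_equal(sk$radius_um, sk$radius_vox * 116.5)
})

test_that("a tapering cone has monotone decreasing radius along its axis", {
  cone <- make_cone(8, 2, 60)
  sk <- measure_radius(skeletonise(cone$mask), cone$mask)
  zs <- sk$coords[, 1]
  interior <- zs > min(zs) + 8 & zs < max(zs) + 0 - 8
  ct <- suppressWarnings(cor.test(zs[interior], sk$radius_vox[interior],
                                  method = "spearman"))
  expect_lt(unname(ct$estimate), -0.95)
})

test_that("large-vessel exclusion removes thick vessels and keeps thin ones", {
  thick <- make_cylinder(8, 80)
  sk <- measure_radius(skeletonise(thick$mask), thick$mask)
  filtered <- exclude_large_vessels(thick$mask, sk, 6)
  expect_lte(sum(filtered) / sum(thick$mask), 0.05) # boundary residue only

  thin <- make_cylinder(3, 80)
  sk3 <- measure_radius(skeletonise(thin$mask), thin$mask)
  kept <- exclude_large_vessels(thin$mask, sk3, 6)
  expect_gte(sum(kept) / sum(thin$mask), 0.95)

  empty <- array(FALSE, c(4, 4, 4))
  expect_identical(exclude_large_vessels(empty, sk3, 6), empty)
  expect_error(exclude_large_vessels(thin$mask, sk3, 0), "positive")
})

test_that("exclusion is monotone in the radius threshold", {
  cyl <- make_cylinder(5, 50)
  sk <- measure_radius(skeletonise(cyl$mask), cyl$mask)
  f4 <- exclude_large_vessels(cyl$mask, sk, 4)
  f6 <- exclude_large_vessels(cyl$mask, sk, 6)
  expect_true(all(f6[f4])) # raising the threshold never removes more
})
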